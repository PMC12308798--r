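## Motif discovery: t-SNE + HDBSCAN on the SSIM similarity matrix, PCA
## validation, and characterisation of the recovered clusters into the
## four-motif taxonomy.

#' Embed a similarity matrix and cluster it
#'
#' Converts similarity to dissimilarity (`1 - s`), embeds to 2D with t-SNE
#' (random initialisation under `seed`), clusters the embedding with HDBSCAN,
#' and computes an independent 2D PCA embedding of the same dissimilarities
#' for validation of the (stochastic) t-SNE layout.
#'
#' @param similarity symmetric similarity matrix (unit diagonal).
#' @param perplexity t-SNE perplexity (default 100).
#' @param early_exaggeration t-SNE early exaggeration (default 4).
#' @param min_cluster_size HDBSCAN minimum cluster size (default 50).
#' @param seed integer seed for the embedding initialisation.
#' @param n_iter t-SNE iterations (default 750).
#' @return object of class `cluster_result`: `embedding` (n x 2), `labels`
#'   (0-based, noise = -1), `pca_embedding` (n x 2), `n_clusters`.
#' @export
embed_and_cluster <- function(similarity, perplexity = 100,
                              early_exaggeration = 4, min_cluster_size = 50,
                              seed = 1L, n_iter = 750) {
  stopifnot(nrow(similarity) == ncol(similarity))
  D <- 1 - similarity
  diag(D) <- 0
  D[D < 0] <- 0
  Y <- tsne_embed(D, perplexity = perplexity,
                  early_exaggeration = early_exaggeration,
                  n_iter = n_iter, seed = seed)
  hd <- hdbscan_fit(Y, min_cluster_size = min_cluster_size)
  pca <- stats::prcomp(D, rank. = 2, center = TRUE, scale. = FALSE)
  structure(list(embedding = Y, labels = hd$labels,
                 pca_embedding = pca$x[, 1:2, drop = FALSE],
                 n_clusters = hd$n_clusters, hdbscan = hd),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$labels), " samples, ", x$n_clusters,
      " clusters (+", sum(x$labels == -1), " noise)\n", sep = "")
  invisible(x)
}

#' Mean silhouette width of a labelled embedding
#'
#' Standard silhouette over Euclidean distances: for each point,
#' `(b - a) / max(a, b)` where `a` is the mean within-cluster distance and
#' `b` the smallest mean distance to another cluster. Used to confirm that
#' clusters found on one embedding remain separated on an independent one.
#'
#' @param X points (rows).
#' @param labels cluster labels (no noise points).
#' @return mean silhouette width in \[-1, 1\].
#' @export
cluster_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  d <- as.matrix(stats::dist(X))
  lv <- unique(labels)
  if (length(lv) < 2) stop("need >= 2 clusters for a silhouette", call. = FALSE)
  s <- vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(lv, labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

## Integration windows over the fingerprint grid, fixed from ideal rotamer
## geometry (1.53 A bonds, 111 deg angles): the 3rd-neighbour shell splits
## into trans (r ~ 3.9 A) and gauche (r ~ 3.0 A) peaks; density in the
## 4-6 A band away from the chain axis (|cos| < 0.5) reflects inter-tail
## packing.
G3_WINDOWS <- list(trans = c(3.6, 4.2), gauche = c(2.7, 3.4),
                   packing = c(4, 6), packing_cos = 0.5)

g3_window_mass <- function(h, r_lim, cos_abs_max = NULL) {
  re <- attr(h, "r_edges")
  ce <- attr(h, "cos_edges")
  rc <- (re[-1] + re[-length(re)]) / 2
  cc <- (ce[-1] + ce[-length(ce)]) / 2
  rows <- rc >= r_lim[1] & rc <= r_lim[2]
  cols <- if (is.null(cos_abs_max)) rep(TRUE, length(cc)) else abs(cc) < cos_abs_max
  sum(h[rows, cols])
}

#' Characterise clusters into conformational motifs
#'
#' Averages the fingerprints per non-noise cluster and scores each average
#' on two axes: chain order (mass in the trans third-neighbour shell over
#' mass in the gauche shell) and intramolecular tail packing (mass in the
#' 4-6 Angstrom inter-tail band away from the chain axis). Clusters above
#' the across-cluster median packing are closed, the rest splayed; above the
#' median order ratio, ordered. The four quadrants map onto motif ids
#' 0 (closed, less ordered), 1 (closed, ordered), 2 (splayed, disordered),
#' 3 (splayed, ordered). Per-system label fractions (including noise) are
#' reported in percent.
#'
#' @param result a [embed_and_cluster()] result.
#' @param histograms the fingerprint array used to build the similarity
#'   matrix (`nr x na x n` with grid attributes).
#' @param system optional per-sample system labels (default one system).
#' @return list: `avg_histograms` (per cluster), `scores` (data frame with
#'   `cluster`, `tg_ratio`, `packing`, `motif`), `motif_map`, `fractions`
#'   (data frame `system`, `label`, `pct`; per-system sums are 100).
#' @export
characterize_clusters <- function(result, histograms, system = NULL) {
  labels <- result$labels
  ids <- sort(unique(labels[labels >= 0]))
  if (length(ids) == 0) stop("all points are noise; nothing to characterise",
                             call. = FALSE)
  system <- system %||% rep("all", length(labels))
  attrs <- attributes(histograms)[c("r_edges", "cos_edges")]
  avg <- list()
  scores <- data.frame(cluster = ids, tg_ratio = NA_real_,
                       packing = NA_real_)
  for (k in seq_along(ids)) {
    m <- apply(histograms[, , labels == ids[k], drop = FALSE], c(1, 2), mean)
    attributes(m)[c("r_edges", "cos_edges")] <- attrs
    avg[[as.character(ids[k])]] <- m
    tr <- g3_window_mass(m, G3_WINDOWS$trans)
    ga <- g3_window_mass(m, G3_WINDOWS$gauche)
    scores$tg_ratio[k] <- tr / max(ga, 1e-9)
    scores$packing[k] <- g3_window_mass(m, G3_WINDOWS$packing,
                                        G3_WINDOWS$packing_cos)
  }
  closed <- scores$packing >= stats::median(scores$packing)
  ordered <- scores$tg_ratio >= stats::median(scores$tg_ratio)
  scores$motif <- ifelse(closed, ifelse(ordered, 1L, 0L),
                         ifelse(ordered, 3L, 2L))
  motif_map <- stats::setNames(scores$motif, scores$cluster)
  lab_motif <- ifelse(labels < 0, "noise",
                      as.character(motif_map[as.character(labels)]))
  fr <- as.data.frame(table(system = system,
                            label = factor(lab_motif,
                                           c("0", "1", "2", "3", "noise"))))
  fr$pct <- 100 * fr$Freq / as.vector(table(system)[fr$system])
  list(avg_histograms = avg, scores = scores, motif_map = motif_map,
       fractions = fr[, c("system", "label", "pct")])
}
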