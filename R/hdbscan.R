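## HDBSCAN*: hierarchical density-based clustering with noise. Mutual
## reachability distances -> minimum spanning tree -> single-linkage
## dendrogram -> condensed tree at the minimum cluster size -> cluster
## selection by excess of mass. Quadratic in n, which is fine at the
## embedding sizes this package clusters.

#' HDBSCAN clustering
#'
#' @param X numeric matrix of points (rows), e.g. a 2D embedding.
#' @param min_cluster_size smallest cluster size considered real (>= 2).
#' @param min_samples neighbourhood size for core distances (defaults to
#'   `min_cluster_size`).
#' @param allow_single_cluster permit the root cluster to be selected, so a
#'   homogeneous data set yields one cluster rather than all noise
#'   (default `TRUE`).
#' @return list: `labels` (0-based cluster ids, noise = -1), `n_clusters`,
#'   `cluster_sizes`, `core_distances`.
#' @export
hdbscan_fit <- function(X, min_cluster_size = 50,
                        min_samples = min_cluster_size,
                        allow_single_cluster = TRUE) {
  stopifnot(min_cluster_size >= 2)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < min_cluster_size) {
    return(list(labels = rep(-1L, n), n_clusters = 0L,
                cluster_sizes = integer(0), core_distances = rep(NA_real_, n)))
  }
  d <- as.matrix(stats::dist(X))
  k <- min(min_samples, n)
  core <- apply(d, 1, function(r) sort(r, partial = k)[k])
  mr <- pmax(d, outer(core, rep(1, n)), outer(rep(1, n), core))
  diag(mr) <- 0

  ## Prim MST on the mutual reachability graph
  in_tree <- logical(n)
  dist_to <- rep(Inf, n)
  edge_from <- integer(n)
  in_tree[1] <- TRUE
  dist_to <- mr[1, ]
  edge_from[] <- 1L
  dist_to[1] <- Inf
  ea <- eb <- integer(n - 1); ew <- numeric(n - 1)
  for (e in seq_len(n - 1)) {
    j <- which.min(dist_to)
    ea[e] <- edge_from[j]; eb[e] <- j; ew[e] <- dist_to[j]
    in_tree[j] <- TRUE
    dist_to[j] <- Inf
    upd <- !in_tree & mr[j, ] < dist_to
    dist_to[upd] <- mr[j, upd]
    edge_from[upd] <- j
  }

  ## single-linkage dendrogram via union-find over ascending edges
  o <- order(ew)
  parent_uf <- seq_len(2L * n - 1L)
  find <- function(x) {
    while (parent_uf[x] != x) {
      parent_uf[x] <<- parent_uf[parent_uf[x]]
      x <- parent_uf[x]
    }
    x
  }
  comp_node <- seq_len(n)              # union-find root -> dendrogram node
  children <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  size <- c(rep(1L, n), integer(n - 1))
  nxt <- n
  for (e in o) {
    ra <- find(ea[e]); rb <- find(eb[e])
    nxt <- nxt + 1L
    children[nxt - n, ] <- c(comp_node[ra], comp_node[rb])
    height[nxt - n] <- ew[e]
    size[nxt] <- size[comp_node[ra]] + size[comp_node[rb]]
    parent_uf[ra] <- rb
    comp_node[rb] <- nxt
  }
  top <- 2L * n - 1L

  collect_leaves <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      t <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (t <= n) out <- c(out, t) else stack <- c(stack, children[t - n, ])
    }
    out
  }
  lam <- function(h) 1 / max(h, 1e-10)

  ## condensed tree
  cc_birth <- numeric(0); cc_stab <- numeric(0)
  cc_parent <- integer(0); cc_size <- integer(0)
  ev_cc <- integer(n); ev_cc[] <- NA_integer_
  new_cc <- function(birth, parent, sz) {
    cc_birth[length(cc_birth) + 1L] <<- birth
    cc_stab[length(cc_stab) + 1L] <<- 0
    cc_parent[length(cc_parent) + 1L] <<- parent
    cc_size[length(cc_size) + 1L] <<- sz
    length(cc_birth)
  }
  root_cc <- new_cc(lam(height[top - n]), 0L, n)
  stack <- list(list(node = top, cc = root_cc))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    t <- fr$node; cc <- fr$cc
    while (t > n) {
      ch <- children[t - n, ]
      s1 <- size[ch[1]]; s2 <- size[ch[2]]
      ls <- lam(height[t - n])
      big <- ch[c(s1, s2) >= min_cluster_size]
      if (length(big) == 2L) {
        cc_stab[cc] <- cc_stab[cc] + (s1 + s2) * (ls - cc_birth[cc])
        c1 <- new_cc(ls, cc, s1)
        c2 <- new_cc(ls, cc, s2)
        stack[[length(stack) + 1L]] <- list(node = ch[1], cc = c1)
        t <- ch[2]; cc <- c2
      } else if (length(big) == 1L) {
        runt <- setdiff(ch, big)
        pts <- collect_leaves(runt)
        cc_stab[cc] <- cc_stab[cc] + length(pts) * (ls - cc_birth[cc])
        ev_cc[pts] <- cc
        t <- big
      } else {
        pts <- collect_leaves(t)
        cc_stab[cc] <- cc_stab[cc] + length(pts) * (ls - cc_birth[cc])
        ev_cc[pts] <- cc
        t <- 0L  # done with this branch
      }
    }
    if (t >= 1L && t <= n) ev_cc[t] <- cc   # isolated leaf continuation
  }

  n_cc <- length(cc_birth)
  cc_children <- split(seq_len(n_cc)[-1], cc_parent[-1])
  sel <- logical(n_cc); sel_stab <- numeric(n_cc)
  for (cc in rev(seq_len(n_cc))) {
    kids <- cc_children[[as.character(cc)]]
    if (is.null(kids)) {
      sel[cc] <- TRUE; sel_stab[cc] <- cc_stab[cc]
    } else {
      kid_sum <- sum(sel_stab[kids])
      if (cc_stab[cc] >= kid_sum &&
          (cc != root_cc || allow_single_cluster)) {
        sel[cc] <- TRUE; sel_stab[cc] <- cc_stab[cc]
      } else {
        sel[cc] <- FALSE; sel_stab[cc] <- kid_sum
      }
    }
  }
  ## final clusters: selected with no selected ancestor
  final <- logical(n_cc)
  for (cc in seq_len(n_cc)) {
    p <- cc_parent[cc]; blocked <- FALSE
    while (p > 0L) {
      if (sel[p]) { blocked <- TRUE; break }
      p <- cc_parent[p]
    }
    final[cc] <- sel[cc] && !blocked
  }
  final_ids <- which(final)
  label_of_cc <- rep(NA_integer_, n_cc)
  for (i in seq_along(final_ids)) label_of_cc[final_ids[i]] <- i - 1L
  labels <- rep(-1L, n)
  for (p in seq_len(n)) {
    cc <- ev_cc[p]
    while (!is.na(cc) && cc > 0L) {
      if (!is.na(label_of_cc[cc])) { labels[p] <- label_of_cc[cc]; break }
      cc <- cc_parent[cc]
    }
  }
  sizes <- if (length(final_ids)) as.integer(table(factor(
    labels[labels >= 0], levels = 0:(length(final_ids) - 1)))) else integer(0)
  list(labels = labels, n_clusters = length(final_ids),
       cluster_sizes = sizes, core_distances = core)
}
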