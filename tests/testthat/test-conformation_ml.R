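test_that("g3 equals the exhaustive triple-loop oracle cell-for-cell", {
  set.seed(41)
  for (k in 1:4) {
    n_at <- sample(5:30, 1)
    tp <- chain_topology(n_at)
    frames <- lapply(1:3, function(f) generate_chain(n_at, runif(1)) +
                       matrix(rnorm(3 * n_at, sd = 0.05), ncol = 3))
    tr <- traj_from_coords(frames, tp, 1)
    h <- compute_g3(tr, 1)
    o <- g3_oracle(frames)
    expect_equal(unclass(h), o, ignore_attr = TRUE, tolerance = 1e-12)
    expect_true(all(h >= 0))
    expect_equal(sum(h), 1, tolerance = 1e-12)
    expect_equal(dim(h), c(201L, 101L))
  }
})

test_that("g3 geometry: equilateral triangle and cutoff exclusion", {
  tp <- chain_topology(3)
  ## equilateral triangle, side 2: every C-deposit at (2, cos60) or (2, 1)
  d <- 2
  tri <- rbind(c(0, 0, 0), c(d, 0, 0), c(d / 2, d * sqrt(3) / 2, 0))
  h <- compute_g3(traj_from_coords(tri, tp, 1), 1)
  re <- attr(h, "r_edges"); ce <- attr(h, "cos_edges")
  nz <- which(h > 0, arr.ind = TRUE)
  rlo <- re[nz[, 1]]; rhi <- re[nz[, 1] + 1]
  expect_true(all(rlo < d & d <= rhi))            # all deposits at r = 2
  cmid <- (ce[nz[, 2]] + ce[nz[, 2] + 1]) / 2
  expect_true(all(abs(cmid - 0.5) < 0.02 | cmid > 0.98))
  ## an atom beyond the cutoff never appears as C
  far <- rbind(c(0, 0, 0), c(1.53, 0, 0), c(20, 0, 0))
  h2 <- compute_g3(traj_from_coords(far, tp, 1), 1)
  rehi <- re[which(rowSums(unclass(h2)) > 0) + 1]
  expect_true(all(rehi < 16))
  expect_error(compute_g3(traj_from_coords(tri, tp, 1), 1,
                          selection = c("C1", "C2")), ">= 3")
})

test_that("SSIM satisfies its identities and the flat-shift closed form", {
  set.seed(43)
  x <- matrix(runif(201 * 101), 201, 101)
  expect_equal(ssim_score(x, x), 1)
  a <- matrix(0.4, 50, 50)
  expect_equal(ssim_score(a, a + 0), 1)
  ## flat images differing by a constant: only the luminance term remains
  c0 <- 0.2; L <- 1
  b <- a + c0
  C1 <- (0.01 * L)^2
  lum <- (2 * 0.4 * 0.6 + C1) / (0.4^2 + 0.6^2 + C1)
  expect_equal(ssim_score(a, b, dynamic_range = L), lum, tolerance = 1e-12)
  ## symmetry
  y <- matrix(runif(201 * 101), 201, 101)
  expect_equal(ssim_score(x, y), ssim_score(y, x), tolerance = 1e-12)
  expect_error(ssim_score(x, matrix(0, 10, 10)), "mismatch")
})

test_that("SSIM agrees with an independent reference implementation", {
  set.seed(47)
  x <- matrix(runif(60 * 40), 60, 40)
  y <- matrix(runif(60 * 40), 60, 40)
  dir <- withr::local_tempdir()
  write.table(x, file.path(dir, "x.tsv"), row.names = FALSE, col.names = FALSE)
  write.table(y, file.path(dir, "y.tsv"), row.names = FALSE, col.names = FALSE)
  script <- file.path(dir, "ssim.py")
  writeLines(c(
    "import sys, numpy as np",
    "from skimage.metrics import structural_similarity as ssim",
    "x = np.loadtxt(sys.argv[1]); y = np.loadtxt(sys.argv[2])",
    "print(float(ssim(x, y, win_size=7, gaussian_weights=False, data_range=1.0)))"
  ), script)
  out <- system2("python", c(script, file.path(dir, "x.tsv"),
                             file.path(dir, "y.tsv")), stdout = TRUE)
  ref <- as.numeric(out[length(out)])
  expect_equal(ssim_score(x, y, dynamic_range = 1), ref, tolerance = 1e-9)
})

test_that("similarity matrices are symmetric with unit diagonal", {
  set.seed(51)
  hs <- lapply(1:5, function(k) matrix(runif(201 * 101), 201, 101))
  S <- build_similarity_matrix(hs)
  expect_equal(S, t(S), tolerance = 1e-12)
  expect_equal(diag(S), rep(1, 5))
  expect_equal(S[1, 2], ssim_score(hs[[1]], hs[[2]],
                                   dynamic_range = max(unlist(hs)) -
                                     min(unlist(hs))), tolerance = 1e-12)
  ident <- build_similarity_matrix(list(hs[[1]], hs[[1]], hs[[1]]))
  expect_equal(ident, matrix(1, 3, 3))
})

## A reduced-scale motif recovery shared by several checks below
motif_recovery_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sm <- generate_membrane_trajectory(synthetic_system_spec(
        n_per_leaflet = 100, n_frames = 8, seed = 55))
      h <- compute_g3_all(sm$traj)
      S <- build_similarity_matrix(h)
      cl <- embed_and_cluster(S, perplexity = 30, min_cluster_size = 20,
                              seed = 1)
      cache <<- list(sm = sm, h = h, S = S, cl = cl)
    }
    cache
  }
})

test_that("well-separated motif families are recovered from the embedding", {
  x <- motif_recovery_small()
  expect_equal(x$cl$n_clusters, 4)
  ari <- mclust::adjustedRandIndex(x$cl$labels, x$sm$motif)
  expect_gte(ari, 0.9)
  ## within-family similarity exceeds between-family similarity
  same <- outer(x$sm$motif, x$sm$motif, `==`)
  diag(same) <- NA
  expect_gt(mean(x$S[which(same)]), mean(x$S[which(!same)]))
  ## PCA validation: clusters separated in t-SNE stay separated in PCA space
  lab <- x$cl$labels
  keep <- lab >= 0
  sil <- cluster_silhouette(x$cl$pca_embedding[keep, , drop = FALSE],
                            lab[keep])
  expect_gt(sil, 0)
})

test_that("degenerate clustering inputs follow the contracts", {
  ## too few points for the perplexity
  S <- diag(10)
  expect_error(embed_and_cluster(S, perplexity = 100), "perplexity")
  ## 40 points with min_cluster_size 50 -> all noise
  set.seed(57)
  X <- matrix(rnorm(80), 40, 2)
  hd <- hdbscan_fit(X, min_cluster_size = 50)
  expect_true(all(hd$labels == -1L))
  ## near-identical histograms -> a single non-noise cluster
  base <- matrix(runif(201 * 101), 201, 101)
  hs <- array(0, c(201, 101, 200))
  set.seed(58)
  for (k in 1:200) hs[, , k] <- base + matrix(rnorm(201 * 101, sd = 1e-4),
                                              201, 101)
  S1 <- build_similarity_matrix(hs)
  cl1 <- embed_and_cluster(S1, perplexity = 30, min_cluster_size = 50,
                           seed = 2)
  expect_equal(cl1$n_clusters, 1)
  expect_gt(mean(cl1$labels == 0), 0.9)
})

test_that("permuting the inputs permutes the labels consistently", {
  x <- motif_recovery_small()
  set.seed(59)
  perm <- sample(nrow(x$S))
  clp <- embed_and_cluster(x$S[perm, perm], perplexity = 30,
                           min_cluster_size = 20, seed = 1)
  ## same partition up to label names: compare against permuted originals
  expect_equal(mclust::adjustedRandIndex(clp$labels, x$cl$labels[perm]), 1,
               tolerance = 0.05)
})

test_that("cluster characterisation recovers the motif taxonomy", {
  x <- motif_recovery_small()
  ch <- characterize_clusters(x$cl, x$h)
  sc <- ch$scores
  ## which planted motif dominates each cluster
  planted <- vapply(sc$cluster, function(cl) {
    as.integer(names(which.max(table(x$sm$motif[x$cl$labels == cl]))))
  }, integer(1))
  expect_equal(sc$motif, planted)
  ## tightly closed all-trans family: highest order ratio and packing
  expect_equal(sc$cluster[which.max(sc$packing)],
               sc$cluster[planted == 1])
  ## disordered splayed family: lowest trans/gauche ratio
  expect_equal(sc$cluster[which.min(sc$tg_ratio)],
               sc$cluster[planted == 2])
  ## planted 25/25/25/25 -> fractions 25 +- 5 for each motif
  fr <- ch$fractions
  for (m in as.character(0:3)) {
    expect_lt(abs(fr$pct[fr$label == m] - 25), 5)
  }
  expect_equal(sum(fr$pct), 100, tolerance = 1e-9)
  noise_only <- x$cl
  noise_only$labels <- rep(-1L, length(x$cl$labels))
  expect_error(characterize_clusters(noise_only, x$h), "noise")
})
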