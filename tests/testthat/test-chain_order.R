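test_that("order parameter hits its analytic limits", {
  tp <- chain_topology(10)
  ## all-trans chain, zigzag axis exactly along z: C-H perpendicular -> -1/2
  chz <- trans_chain_along(10, c(0, 0, 1))
  s <- scd_profile(traj_from_coords(chz, tp, 1))
  expect_equal(s$scd, rep(-0.5, 8), tolerance = 1e-12)
  ## isotropically oriented rigid chains -> 0 within Monte-Carlo error
  set.seed(5)
  n_or <- 1e4
  frames <- lapply(seq_len(n_or), function(k) {
    M <- matrix(rnorm(9), 3, 3); Q <- qr.Q(qr(M))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    chz %*% t(Q)
  })
  si <- scd_profile(traj_from_coords(frames, tp, 1), n_blocks = 1)
  expect_lt(max(abs(si$scd)), 0.01)
  ## axis at 90 deg to z, uniformly spin-averaged -> +1/4
  chx <- trans_chain_along(10, c(1, 0, 0))
  nspin <- 360
  frames90 <- lapply(seq_len(nspin), function(k) {
    th <- 2 * pi * (k - 1) / nspin
    R <- diag(3)
    R[2, 2] <- cos(th); R[2, 3] <- -sin(th)
    R[3, 2] <- sin(th); R[3, 3] <- cos(th)
    chx %*% t(R)
  })
  s90 <- scd_profile(traj_from_coords(frames90, tp, 1), n_blocks = 1)
  expect_equal(s90$scd, rep(0.25, 8), tolerance = 1e-6)
})

test_that("order parameter bounds hold on arbitrary chains", {
  tp <- chain_topology(12)
  set.seed(9)
  for (k in 1:10) {
    frames <- lapply(1:3, function(f) generate_chain(12, runif(1)))
    s <- scd_profile(traj_from_coords(frames, tp, 1))
    expect_true(all(s$scd >= -0.5 - 1e-12 & s$scd <= 1 + 1e-12))
  }
  expect_error(scd_profile(traj_from_coords(generate_chain(12, 0),
                                            tp, 1),
                           tails = list(t = c("C1", "C2"))), "chain too short")
})

test_that("tilt angles are leaflet-aware and folded", {
  tp <- lipid_topology("TLT", c("C7", "C20", "O1"), tail1_atoms = c("C7", "C20", "O1"),
                       tail2_atoms = character(0), headgroup_atoms = "O1",
                       splay_vertex = "C7", glycerol_vector_atoms = c("C7", "C20"))
  mk <- function(v, z0) {
    ## C20 at z0, C7 = C20 + v (tail vector is terminal -> first)
    xyz <- rbind(c(10, 10, z0) + v, c(10, 10, z0), c(10, 10, z0 + 2))
    xyz
  }
  ## lipid 1 in lower leaflet (outward -z): vector (0,0,-1) -> 0 deg
  ## lipid 2 in upper leaflet: vector (0,0,1) -> 0 deg
  xyz <- rbind(mk(c(0, 0, -5), 20), mk(c(0, 0, 5), 80))
  tr <- traj_from_coords(xyz, tp, 2, box = c(50, 50, 100))
  leaf <- assign_leaflets(tr, 2, marker_atom = "O1")
  td <- tilt_distribution(tr, leaf, vectors = list(t = c("C20", "C7")))
  expect_equal(attr(td$t, "mode"), 0.25)     # first 0.5-degree bin
  ## 45-degree vector in the upper leaflet
  xyz45 <- rbind(mk(c(0, 0, -5), 20), mk(c(5, 0, 5), 80))
  tr45 <- traj_from_coords(xyz45, tp, 2, box = c(50, 50, 100))
  t45 <- tilt_distribution(tr45, assign_leaflets(tr45, 2, "O1"),
                           vectors = list(t = c("C20", "C7")))
  expect_true(any(abs(t45$t$angle[t45$t$prob > 0] - 45) < 0.5))
  expect_equal(sum(td$t$prob), 1, tolerance = 1e-9)
})

test_that("splay and head-tail angles follow vector geometry", {
  tp <- lipid_topology("SPL", c("C9", "C5", "C22", "C1", "C3", "C20", "C35"),
                       tail1_atoms = c("C9", "C20", "C5"),
                       tail2_atoms = c("C22", "C35"),
                       headgroup_atoms = c("C1", "C3"), splay_vertex = "C5",
                       glycerol_vector_atoms = c("C1", "C3"))
  mk <- function(v9, v22) {
    c5 <- c(25, 25, 25)
    rbind(c5 + v9, c5, c5 + v22, c5 + c(0, 0, 3), c5 + c(0, 0, 5),
          c5 + c(0, 0, -8), c5 + c(0, 1, -8))
  }
  ang_of <- function(v9, v22) {
    tr <- traj_from_coords(mk(v9, v22), tp, 1)
    d <- splay_distribution(tr, c("C9", "C5", "C22"))
    attr(d, "mode")
  }
  ## orthogonal: exactly 90 degrees falls in the right-closed (89, 90] bin
  expect_equal(ang_of(c(3, 0, 0), c(0, 3, 0)), 89.5)
  expect_equal(ang_of(c(3, 0, 0), c(2, 0, 0)), 0.5)     # parallel
  expect_equal(ang_of(c(3, 0, 0), c(-2, 0, 0)), 179.5)  # antiparallel
  expect_error(splay_distribution(traj_from_coords(mk(c(0, 0, 0), c(1, 0, 0)),
                                                   tp, 1)), "coincident")
  ## head-tail: head vector along +z (C1->C3 = +2z), tail C5->C20 = -8z
  tr <- traj_from_coords(mk(c(3, 0, 0), c(0, 3, 0)), tp, 1)
  ht <- head_tail_angle(tr, tail_vectors = list(t1 = c("C5", "C20")))
  expect_equal(attr(ht$t1, "mode"), 179.5)              # antiparallel
  ht2 <- head_tail_angle(tr, head_vector = c("C1", "C3"),
                         tail_vectors = list(t2 = c("C5", "C35")))
  ## C5->C35 has z = -8, |xy| = 1: close to antiparallel but not exact
  expect_gt(attr(ht2$t2, "mode"), 170)
})

test_that("splay-1 distribution of a pure-motif ensemble peaks at the target", {
  sm <- generate_membrane_trajectory(synthetic_system_spec(
    n_per_leaflet = 60, n_frames = 5, motif_fractions = c(0, 1, 0, 0),
    seed = 17))
  d <- splay_distribution(sm$traj, c("C9", "C5", "C22"))
  expect_lt(abs(attr(d, "mode") - 95), 1)
  expect_equal(sum(d$prob), 1, tolerance = 1e-9)
})

test_that("vector ACF matches the brute-force double loop to 1e-10", {
  sm <- generate_membrane_trajectory(synthetic_system_spec(
    n_per_leaflet = 8, n_frames = 40, frame_dt = 50, seed = 19,
    tail_resample = FALSE))
  ac <- vector_acf(sm$traj, c("C1", "C3"), max_lag = 19)
  fi <- atom_indices(sm$traj, "C1"); ti <- atom_indices(sm$traj, "C3")
  U <- lapply(seq_len(40), function(f) {
    v <- sm$traj$coords[ti, , f] - sm$traj$coords[fi, , f]
    v / sqrt(rowSums(v^2))
  })
  bf <- vapply(0:19, function(L) {
    acc <- 0; m <- 0
    for (tau in seq_len(40 - L)) {
      acc <- acc + sum(U[[tau]] * U[[tau + L]])
      m <- m + nrow(U[[1]])
    }
    acc / m
  }, numeric(1))
  expect_lt(max(abs(ac$acf - bf / bf[1])), 1e-10)
})

test_that("vector ACF limits: static = 1, re-randomised = 0, diffusion = exp", {
  tp <- chain_topology(3)
  ## static
  xyz <- generate_chain(3, 0)
  trs <- traj_from_coords(list(xyz, xyz, xyz, xyz, xyz), tp, 1)
  acs <- vector_acf(trs, c("C1", "C3"))
  expect_equal(acs$acf, rep(1, length(acs$acf)))
  ## independently re-randomised isotropic vectors
  set.seed(23)
  n <- 400; F <- 40
  frames <- lapply(seq_len(F), function(f) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    xyz <- matrix(0, 3 * n, 3)
    xyz[seq(1, 3 * n, by = 3) + 1, ] <- matrix(runif(3 * n, 10, 40), ncol = 3)
    base <- xyz[seq(1, 3 * n, by = 3) + 1, ]
    xyz[seq(1, 3 * n, by = 3), ] <- base - u
    xyz[seq(1, 3 * n, by = 3) + 2, ] <- base + u
    xyz
  })
  trr <- traj_from_coords(frames, tp, n)
  acr <- vector_acf(trr, c("C1", "C3"))
  n_eff <- n * (F - max(1, 1))
  expect_lt(max(abs(acr$acf[-1])), 3 / sqrt(n * (F / 2)))
  ## rotational diffusion: P1 ACF = exp(-2 D t)
  D <- 0.02   # 1/ps
  dt <- 1
  sm <- generate_membrane_trajectory(synthetic_system_spec(
    n_per_leaflet = 300, n_frames = 60, frame_dt = dt,
    headgroup_tau1 = 1 / (2 * D), headgroup_tau2 = 1 / (2 * D),
    headgroup_a1 = 0.5, headgroup_a2 = 0.5, tail_resample = FALSE,
    seed = 29))
  ac <- glycerol_acf(sm$traj, max_lag = 25)
  tsel <- ac$lag <= 1 / D
  expect_lt(max(abs(ac$acf[tsel] - exp(-2 * D * ac$lag[tsel]))), 0.05)
})

test_that("2D RDF: lattice peak, isolated pair, Poisson flatness", {
  tp <- chain_topology(3)
  ## square lattice of single-atom-ish lipids (3 coincident atoms per lipid)
  d <- 5; m <- 8
  g <- expand.grid(x = (0:(m - 1)) * d + d / 2, y = (0:(m - 1)) * d + d / 2)
  xyz <- do.call(rbind, lapply(seq_len(nrow(g)), function(i)
    rbind(c(g$x[i], g$y[i], 10), c(g$x[i], g$y[i], 10.5),
          c(g$x[i], g$y[i], 9.5))))
  tr <- traj_from_coords(xyz, tp, nrow(g), box = c(m * d, m * d, 40))
  leaf <- list(leaflet = matrix(1L, nrow(g), 1), outer = TRUE, n_leaflets = 1L)
  class(leaf) <- "leaflet_assignment"
  r <- rdf_2d(tr, leaf, c("C1", "C2", "C3"), r_max = 15, n_bins = 60,
              which_leaflets = 1L)
  expect_equal(r$r[which(r$g > 0)[1]], d, tolerance = 0.3)
  ## two points 5 A apart in a large box -> a single nonzero bin at 5
  xyz2 <- rbind(c(10, 10, 10), c(10, 10, 10), c(10, 10, 10),
                c(15, 10, 10), c(15, 10, 10), c(15, 10, 10))
  tr2 <- traj_from_coords(xyz2, tp, 2, box = c(60, 60, 60))
  leaf2 <- structure(list(leaflet = matrix(1L, 2, 1), outer = TRUE,
                          n_leaflets = 1L), class = "leaflet_assignment")
  r2 <- rdf_2d(tr2, leaf2, c("C1", "C2", "C3"), r_max = 20, n_bins = 40,
               which_leaflets = 1L)
  nz <- which(r2$g > 0)
  expect_length(nz, 1)
  expect_equal(r2$r[nz], 5, tolerance = 0.25)
  ## Poisson points: g ~ 1 beyond 1 A
  set.seed(31)
  np <- 600
  pts <- cbind(runif(np, 0, 60), runif(np, 0, 60), 10)
  xyz3 <- pts[rep(seq_len(np), each = 3), ]
  tr3 <- traj_from_coords(xyz3, tp, np, box = c(60, 60, 40))
  leaf3 <- structure(list(leaflet = matrix(1L, np, 1), outer = TRUE,
                          n_leaflets = 1L), class = "leaflet_assignment")
  r3 <- rdf_2d(tr3, leaf3, c("C1", "C2", "C3"), r_max = 25, n_bins = 25,
               which_leaflets = 1L)
  rho <- (np - 1) / 3600
  ann <- pi * (seq(1, 25)^2 - seq(0, 24)^2)
  expn <- np * rho * ann / 2            # unordered pair count per bin
  sel <- r3$r > 1
  expect_true(all(abs(r3$g[sel] - 1) <= 4 / sqrt(expn[sel])))
  expect_error(rdf_2d(tr3, leaf3, c("C1"), r_max = 40), "half")
})
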