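test_that("hydrogen-bond detector reproduces the geometric truth table", {
  ## inside both cutoffs
  hb1 <- detect_hbonds(hbond_pair_traj(2.9, 10))
  expect_equal(sum(hb1$acceptor == 8), 1)
  expect_equal(hb1$class[hb1$acceptor == 8], "inter")
  ## distance fails
  expect_equal(sum(detect_hbonds(hbond_pair_traj(3.6, 5))$acceptor == 8), 0)
  ## angle fails
  expect_equal(sum(detect_hbonds(hbond_pair_traj(3.0, 35))$acceptor == 8), 0)
  ## boundary geometry is inclusive
  expect_equal(sum(detect_hbonds(hbond_pair_traj(3.5, 30))$acceptor == 8), 1)
})

test_that("detection is invariant under rigid rotation and translation", {
  tr <- hbond_pair_traj(2.9, 20)
  base <- detect_hbonds(tr)
  R <- rot_onto(c(0, 0, 1), c(1, 1, 1) / sqrt(3))
  moved <- tr
  for (f in seq_len(tr$n_frames)) {
    moved$coords[, , f] <- tr$coords[, , f] %*% t(R) +
      rep(c(3, -2, 4), each = tr$n_atoms)
  }
  got <- detect_hbonds(moved)
  expect_equal(got[, c("donor", "acceptor", "class")],
               base[, c("donor", "acceptor", "class")])
})

test_that("per-molecule statistics are plain arithmetic over the counts", {
  ## 10 single-donor lipids; plant exactly 7 inter bonds
  tp <- lipid_topology("HBT", c("O1", "HO1", "O2", "C1", "C3"),
                       tail1_atoms = c("C1", "C3", "O2"),
                       tail2_atoms = character(0), headgroup_atoms = "O1",
                       donors = list(c("O1", "HO1")), acceptors = c("O2"),
                       splay_vertex = "C1", glycerol_vector_atoms = c("C1", "C3"))
  n <- 10
  xyz <- matrix(0, 5 * n, 3)
  for (i in seq_len(n)) {
    base <- c(10 * i, 10, 10)
    rows <- (i - 1) * 5 + 1:5
    xyz[rows, ] <- rbind(base, base + c(0.97, 0, 0), base + c(0, 30, 0),
                         base + c(0, 40, 0), base + c(0, 40, 2))
  }
  ## bonds: donor i's O1-H aimed at acceptor O2 of lipid i+1, for i in 1..7;
  ## move those acceptors next to the donors
  for (i in 1:7) {
    arow <- i * 5 + 3                 # O2 of lipid i+1
    xyz[arow, ] <- c(10 * i + 2.9, 10, 10)
  }
  tr <- traj_from_coords(xyz, tp, n, box = c(120, 60, 40))
  st <- hbond_statistics(tr)
  expect_equal(st$inter$mean, 0.7)
  expect_equal(st$intra$mean, 0)
  ## no water present -> all water columns zero
  expect_true(all(st$water_by_group$mean == 0))
})

test_that("group-resolved lipid-water bonds are booked to the right oxygen", {
  ## full topology lipid with three waters bonded to O5-H of three lipids
  spec <- synthetic_system_spec(n_per_leaflet = 5, n_frames = 1, seed = 61)
  sm <- generate_membrane_trajectory(spec)
  tr <- sm$traj
  ## append 3 waters positioned as acceptors of lipid O5-H donors
  nw <- 3
  co <- array(0, c(tr$n_atoms + 3 * nw, 3, 1))
  co[seq_len(tr$n_atoms), , 1] <- tr$coords[, , 1]
  for (k in seq_len(nw)) {
    o5 <- tr$coords[atom_indices(tr, "O5")[k], , 1]
    ho5 <- tr$coords[atom_indices(tr, "HO5")[k], , 1]
    dir <- (ho5 - o5) / sqrt(sum((ho5 - o5)^2))
    ow <- o5 + 2.9 * dir
    rows <- tr$n_atoms + (k - 1) * 3 + 1:3
    co[rows, , 1] <- rbind(ow, ow + c(10, 0, 0) * 0.096, ow + c(0, 10, 0) * 0.096)
  }
  tw <- membrane_trajectory(
    co, tr$box[1, ], tr$times[1], tr$topology, tr$n_lipids,
    c(tr$atom_names, rep(c("OW", "HW1", "HW2"), nw)),
    c(tr$resnames, rep("SOL", 3 * nw)))
  st <- hbond_statistics(tw)
  expect_equal(st$water_by_group$mean[st$water_by_group$group == "O5-H"],
               nw / tr$n_lipids)
  expect_equal(st$water_by_group$mean[st$water_by_group$group == "O2"], 0)
})

test_that("intermittent bond ACF: permanence, independence, Markov kinetics", {
  tp <- lipid_topology("HBT", c("O1", "HO1", "O2", "C1", "C3"),
                       tail1_atoms = c("C1", "C3", "O2"),
                       tail2_atoms = character(0), headgroup_atoms = "O1",
                       donors = list(c("O1", "HO1")), acceptors = c("O2"),
                       splay_vertex = "C1", glycerol_vector_atoms = c("C1", "C3"))
  mk_frames <- function(bonded) {        # logical matrix pairs x frames
    n <- nrow(bonded)
    lapply(seq_len(ncol(bonded)), function(f) {
      xyz <- matrix(0, 5 * n, 3)
      for (i in seq_len(n)) {
        base <- c(12 * i, 10, 10)
        rows <- (i - 1) * 5 + 1:5
        d <- if (bonded[i, f]) 2.9 else 6
        xyz[rows, ] <- rbind(base, base + c(0.97, 0, 0), base + c(d, 0, 0),
                             base + c(0, 5, 0), base + c(0, 5, 2))
      }
      xyz
    })
  }
  n <- 40; F <- 60
  ## permanently bonded: raw C(t) = 1 for all t
  perm <- matrix(TRUE, n, F)
  trp <- traj_from_coords(mk_frames(perm), tp, n, box = c(12 * n + 20, 40, 40))
  acp <- hbond_acf(trp, correction = FALSE)
  expect_equal(acp$acf, rep(1, length(acp$acf)))
  expect_equal(attr(hbond_acf(trp, correction = TRUE), "plateau"), 1)
  ## independently re-randomised with probability p: C ~ p, corrected ~ 0
  set.seed(67)
  p <- 0.4
  rnd <- matrix(runif(n * F) < p, n, F)
  trr <- traj_from_coords(mk_frames(rnd), tp, n, box = c(12 * n + 20, 40, 40))
  acr_raw <- hbond_acf(trr, correction = FALSE)
  expect_lt(max(abs(acr_raw$acf[-1] - p)), 0.08)
  acr <- hbond_acf(trr, correction = TRUE)
  expect_lt(max(abs(acr$acf[-1])), 0.25)
  expect_lt(mean(abs(acr$acf[-1])), 0.08)
  ## two-state Markov bond: C(t) decays as exp(-(kon + koff) t) toward p_eq
  set.seed(71)
  kon <- 0.10; koff <- 0.15                       # per frame
  mk_chain <- function() {
    s <- logical(F); s[1] <- runif(1) < kon / (kon + koff)
    for (f in 2:F) {
      s[f] <- if (s[f - 1]) runif(1) > koff else runif(1) < kon
    }
    s
  }
  mar <- t(replicate(300, mk_chain()))
  trm <- traj_from_coords(mk_frames(mar), tp, 300,
                          box = c(12 * 300 + 20, 40, 40))
  acm <- hbond_acf(trm, correction = FALSE, max_lag = 25)
  peq <- kon / (kon + koff)
  pred <- peq + (1 - peq) * exp(-(kon + koff) * (0:25))
  expect_lt(max(abs(acm$acf - pred)), 0.05)
})

test_that("no bonds in the window is an error", {
  tr <- hbond_pair_traj(6, 5)
  tr2 <- traj_from_coords(list(tr$coords[, , 1], tr$coords[, , 1]),
                          tr$topology, 2, box = c(60, 60, 60))
  expect_error(hbond_acf(tr2), "no hydrogen bonds")
})

test_that("double-exponential fits recover reference-scale parameters", {
  lags <- seq(0, 600, by = 0.2)                   # ns; resolves the fast mode
  ## interdigitated-system parameter set, noiseless: within 1 percent
  truth <- c(a1 = 0.13, tau1 = 6.6, a2 = 0.13, tau2 = 104.4)
  cv <- generate_decay_curve(truth["a1"], truth["tau1"], truth["a2"],
                             truth["tau2"], b = 0.74, noise_sd = 0,
                             lags = lags)
  f <- fit_double_exponential(cv)
  expect_lt(abs(f$a1 - truth["a1"]) / truth["a1"], 0.01)
  expect_lt(abs(f$tau1 - truth["tau1"]) / truth["tau1"], 0.01)
  expect_lt(abs(f$a2 - truth["a2"]) / truth["a2"], 0.01)
  expect_lt(abs(f$tau2 - truth["tau2"]) / truth["tau2"], 0.01)
  expect_lt(abs(f$b - 0.74), 0.01 * 0.74)
  expect_true(f$tau1 <= f$tau2)
  ## with measurement noise sd 0.01: within 10 percent
  cvn <- generate_decay_curve(truth["a1"], truth["tau1"], truth["a2"],
                              truth["tau2"], b = 0.74, noise_sd = 0.01,
                              lags = lags, seed = 73)
  fn <- fit_double_exponential(cvn)
  expect_lt(abs(fn$tau1 - truth["tau1"]) / truth["tau1"], 0.10)
  expect_lt(abs(fn$tau2 - truth["tau2"]) / truth["tau2"], 0.10)
  ## pure constant: amplitudes vanish, offset recovered
  flat <- generate_decay_curve(0, 1, 0, 1, b = 0.37, noise_sd = 0,
                               lags = lags)
  ff <- fit_double_exponential(flat)
  expect_lt(ff$a1 + ff$a2, 1e-4)
  expect_equal(ff$b, 0.37, tolerance = 1e-6)
  ## single exponential input: flagged degenerate
  se <- generate_decay_curve(0.4, 20, 0, 20, b = 0.6, noise_sd = 0,
                             lags = lags)
  fs <- fit_double_exponential(se)
  expect_true(fs$degenerate)
})

test_that("fits are invariant to lag-unit rescaling", {
  lags <- seq(0, 500, by = 1)
  cv <- generate_decay_curve(0.2, 5, 0.1, 80, b = 0.7, noise_sd = 0,
                             lags = lags)
  f1 <- fit_double_exponential(cv)
  cv_ms <- cv
  cv_ms$lag <- cv$lag * 1000                      # change units
  f2 <- fit_double_exponential(cv_ms)
  expect_equal(f2$tau1 / 1000, f1$tau1, tolerance = 1e-4)
  expect_equal(f2$tau2 / 1000, f1$tau2, tolerance = 1e-4)
  expect_equal(f2$a1, f1$a1, tolerance = 1e-5)
  expect_equal(f2$a2, f1$a2, tolerance = 1e-5)
})

test_that("static headgroups give a unit glycerol ACF", {
  sm <- generate_membrane_trajectory(synthetic_system_spec(
    n_per_leaflet = 10, n_frames = 20, headgroup_a1 = 0, headgroup_a2 = 0,
    tail_resample = FALSE, seed = 79))
  ac <- glycerol_acf(sm$traj)
  expect_equal(ac$acf, rep(1, length(ac$acf)), tolerance = 1e-12)
})

test_that("equal time constants reduce to a single-exponential decay", {
  sm <- generate_membrane_trajectory(synthetic_system_spec(
    n_per_leaflet = 150, n_frames = 80, frame_dt = 100,
    headgroup_tau1 = 2000, headgroup_tau2 = 2000,
    headgroup_a1 = 0.25, headgroup_a2 = 0.25, tail_resample = FALSE,
    seed = 83))
  ac <- glycerol_acf(sm$traj, max_lag = 40)
  pred <- 0.5 * exp(-ac$lag / 2000) + 0.5
  expect_lt(max(abs(ac$acf - pred)), 0.06)
})
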