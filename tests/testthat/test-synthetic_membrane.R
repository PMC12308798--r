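dihedrals_deg <- function(ch) {
  n <- nrow(ch)
  vapply(seq_len(n - 3), function(i) {
    b1 <- ch[i + 1, ] - ch[i, ]; b2 <- ch[i + 2, ] - ch[i + 1, ]
    b3 <- ch[i + 3, ] - ch[i + 2, ]
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    acos(min(1, max(-1, sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))))) * 180 / pi
  }, numeric(1))
}

test_that("rotamer chains have exact bonds, angles and dihedral statistics", {
  ch <- generate_chain(20, 0, seed = 1)
  bonds <- sqrt(rowSums(diff(ch)^2))
  expect_equal(bonds, rep(1.53, 19), tolerance = 1e-12)
  angles <- vapply(2:19, function(i) {
    a <- ch[i - 1, ] - ch[i, ]; b <- ch[i + 1, ] - ch[i, ]
    acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  }, numeric(1))
  expect_equal(angles, rep(111, 18), tolerance = 1e-9)
  ## all-trans: every dihedral at 180
  expect_equal(dihedrals_deg(ch), rep(180, 17), tolerance = 1e-6)
  ## gauche_prob = 1: every dihedral gauche (60)
  chg <- generate_chain(20, 1, seed = 2)
  expect_equal(abs(180 - dihedrals_deg(chg)) > 90, rep(TRUE, 17))
  expect_equal(dihedrals_deg(chg), rep(60, 17), tolerance = 1e-6)
})

test_that("gauche fraction follows the binomial at gauche_prob = 0.3", {
  set.seed(10)
  n_dih <- 0L; n_g <- 0L
  while (n_dih < 1e4) {
    ch <- generate_chain(103, 0.3)
    d <- dihedrals_deg(ch)
    n_g <- n_g + sum(abs(d - 180) > 60)
    n_dih <- n_dih + length(d)
  }
  frac <- n_g / n_dih
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n_dih))
})

test_that("chain generation is bit-identical under a fixed seed", {
  expect_identical(generate_chain(15, 0.25, seed = 99),
                   generate_chain(15, 0.25, seed = 99))
  s <- synthetic_system_spec(n_per_leaflet = 6, n_frames = 3, seed = 31)
  expect_identical(generate_membrane_trajectory(s)$traj$coords,
                   generate_membrane_trajectory(s)$traj$coords)
})

test_that("generated lipids echo the splay target and face the water", {
  m1 <- default_motifs()[["1"]]
  m1$gauche_prob <- 0
  set.seed(3)
  for (k in 1:5) {
    lip <- generate_lipid(m1, leaflet_direction = 1)
    v1 <- lip["C9", ] - lip["C5", ]; v2 <- lip["C22", ] - lip["C5", ]
    sp <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_lt(abs(sp - 95), 0.5)
    expect_gt(lip["O1", 3], mean(lip[paste0("C", 7:35), 3]))
  }
  lip_dn <- generate_lipid(m1, leaflet_direction = -1)
  expect_lt(lip_dn["O1", 3], mean(lip_dn[paste0("C", 7:35), 3]))
})

test_that("disordered motif chains are less ordered than tight motif chains", {
  mk <- function(mid) {
    fr <- c(0, 0, 0, 0); fr[mid + 1] <- 1
    sm <- generate_membrane_trajectory(synthetic_system_spec(
      n_per_leaflet = 20, n_frames = 4, motif_fractions = fr, seed = 8))
    scd_profile(sm$traj)
  }
  s1 <- mk(1); s2 <- mk(2)
  expect_lt(mean(abs(s2$scd)), mean(abs(s1$scd)))
})

test_that("membrane construction hits the APL target and orderings", {
  sm <- generate_membrane_trajectory(synthetic_system_spec(
    n_per_leaflet = 100, n_frames = 2, apl_target = 40,
    motif_fractions = c(0, 1, 0, 0), seed = 12))
  expect_lt(abs(apl_xy(sm$traj, 100)$mean - 40), 1)
  ## interdigitated stack is thinner than the double bilayer at matched
  ## composition (realistic per-arrangement areas)
  dims <- lapply(c(double_bilayer = "double_bilayer",
                   interdigitated = "interdigitated"), function(arr) {
    apl <- if (arr == "interdigitated") 72.0 else 41.2
    sm <- generate_membrane_trajectory(synthetic_system_spec(
      arrangement = arr, n_per_leaflet = 36, n_frames = 2, apl_target = apl,
      seed = 13))
    prof <- density_profile(sm$traj, weighting = "electron", n_blocks = 2)
    thickness_from_profile(prof, "overall")$thickness
  })
  expect_lt(dims$interdigitated, dims$double_bilayer)
  expect_error(generate_membrane_trajectory(synthetic_system_spec(
    n_per_leaflet = 10, apl_target = 26)), NA)
  expect_error(synthetic_system_spec(motif_fractions = c(0.5, 0.5, 0.1, 0)),
               "sum to 1")
  expect_error(generate_membrane_trajectory(synthetic_system_spec(
    n_per_leaflet = 10, apl_target = 10)), "packing error")
})

test_that("hbond_fraction = 0 leaves no planted lipid-lipid bonds", {
  sm <- generate_membrane_trajectory(synthetic_system_spec(
    n_per_leaflet = 16, n_frames = 2, hbond_fraction = 0, seed = 21))
  hb <- detect_hbonds(sm$traj, 1)
  expect_equal(nrow(sm$planted_hbonds), 0)
  ## no *inter* lipid bonds by construction on the jittered lattice
  expect_equal(sum(hb$class == "inter"), 0)
})

test_that("planted hydrogen-bond pairs satisfy the geometric criterion", {
  sm <- generate_membrane_trajectory(synthetic_system_spec(
    n_per_leaflet = 20, n_frames = 3, hbond_fraction = 0.3, seed = 22))
  expect_gt(nrow(sm$planted_hbonds), 0)
  for (f in 1:3) {
    hb <- detect_hbonds(sm$traj, f)
    inter <- hb[hb$class == "inter", ]
    got <- paste(inter$donor_mol, inter$acceptor_mol)
    want <- paste(sm$planted_hbonds$donor, sm$planted_hbonds$acceptor)
    expect_true(all(want %in% got))
  }
})

test_that("decay curves take the double-exponential form", {
  lags <- seq(0, 200, by = 1)
  ## reference single-bilayer parameters; value at t = 0 is a1 + a2 + b = 1
  cv <- generate_decay_curve(0.23, 2.1, 0.12, 57.3, b = 1 - 0.23 - 0.12,
                             noise_sd = 0, lags = lags)
  expect_equal(cv$value[1], 1)
  expect_true(all(diff(cv$value) < 0))
  flat <- generate_decay_curve(0, 1, 0, 1, b = 0.5, noise_sd = 0, lags = lags)
  expect_equal(flat$value, rep(0.5, length(lags)))
})
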