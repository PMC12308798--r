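## Synthetic planar lamellar membranes with controlled conformational motifs,
## chain order, headgroup rotational dynamics and hydrogen-bond geometry.
## Chains are pure rotamer models (fixed 1.53 A bonds, 111 deg angles,
## trans/gauche dihedrals); the generator emulates statistical structure,
## not physics -- no energetics, no excluded-volume relaxation.

BOND_CC <- 1.53          # A
ANGLE_CCC <- 111 * pi / 180
MIN_APL <- 25            # A^2; below this two tails cannot pack without overlap

#' Specify a conformational motif
#'
#' The four-motif taxonomy of gel-phase two-tailed lipids: closed vs splayed
#' tails crossed with ordered vs disordered chains. A motif is parameterised
#' by its per-dihedral gauche probability, the splay-1 angle (vertex angle at
#' the branching carbon between the second tail carbons), the lateral
#' distance the distal tail segments settle at, and the tilt of the tail
#' axes from the membrane normal.
#'
#' @param motif_id 0 (closed, less ordered), 1 (tightly closed, ordered),
#'   2 (splayed, at least one tail disordered), 3 (splayed, ordered).
#' @param gauche_prob probability that an internal dihedral is gauche.
#' @param splay1_target degrees, in (0, 180).
#' @param tail_separation Angstrom between the distal tail axes.
#' @param tilt_mean,tilt_sd degrees; tail-axis tilt draw.
#' @return object of class `motif_spec`.
#' @export
motif_spec <- function(motif_id, gauche_prob, splay1_target, tail_separation,
                       tilt_mean, tilt_sd) {
  stopifnot(motif_id %in% 0:3, gauche_prob >= 0, gauche_prob <= 1,
            splay1_target > 0, splay1_target < 180,
            tail_separation > 0, tilt_sd >= 0)
  structure(list(motif_id = as.integer(motif_id), gauche_prob = gauche_prob,
                 splay1_target = splay1_target,
                 tail_separation = tail_separation,
                 tilt_mean = tilt_mean, tilt_sd = tilt_sd),
            class = "motif_spec")
}

#' Canonical motif set
#'
#' Default parameterisation of the four structural motifs, chosen so that the
#' families are geometrically distinct in the way the taxonomy describes:
#' motifs 0/1 closed (small tail separation), 2/3 splayed; motif 2 strongly
#' disordered (high gauche fraction), 1 the tightest and most ordered.
#' @return named list of four [motif_spec()]s (`"0"` .. `"3"`).
#' @export
default_motifs <- function() {
  list(
    "0" = motif_spec(0L, gauche_prob = 0.12, splay1_target = 95,
                     tail_separation = 5.2, tilt_mean = 8, tilt_sd = 3),
    "1" = motif_spec(1L, gauche_prob = 0.02, splay1_target = 95,
                     tail_separation = 4.3, tilt_mean = 7, tilt_sd = 2),
    "2" = motif_spec(2L, gauche_prob = 0.40, splay1_target = 120,
                     tail_separation = 8.5, tilt_mean = 12, tilt_sd = 4),
    "3" = motif_spec(3L, gauche_prob = 0.05, splay1_target = 120,
                     tail_separation = 8.5, tilt_mean = 8, tilt_sd = 3)
  )
}

#' Generate a rotameric alkyl chain
#'
#' Sequential construction with fixed bond length 1.53 A and bond angle
#' 111 degrees; each internal dihedral is trans (180 deg) with probability
#' `1 - gauche_prob`, otherwise gauche (+60 or -60, equiprobable).
#'
#' @param n_carbons number of carbons (>= 3).
#' @param gauche_prob per-dihedral gauche probability.
#' @param seed optional integer; if given, output is reproducible.
#' @return `n_carbons x 3` coordinate matrix (Angstrom).
#' @export
generate_chain <- function(n_carbons, gauche_prob, seed = NULL) {
  stopifnot(n_carbons >= 3, gauche_prob >= 0, gauche_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(0, n_carbons, 3)
  x[2, ] <- c(BOND_CC, 0, 0)
  x[3, ] <- x[2, ] + BOND_CC * c(cos(pi - ANGLE_CCC), sin(pi - ANGLE_CCC), 0)
  if (n_carbons > 3) {
    n_dih <- n_carbons - 3
    is_g <- stats::runif(n_dih) < gauche_prob
    sgn <- sample(c(-1, 1), n_dih, replace = TRUE)
    phi <- ifelse(is_g, sgn * 60, 180) * pi / 180
    for (i in 4:n_carbons) {
      x[i, ] <- place_next_atom(x[i - 3, ], x[i - 2, ], x[i - 1, ],
                                BOND_CC, ANGLE_CCC, phi[i - 3])
    }
  }
  x
}

## NERF placement: position D from A-B-C with bond |CD|, angle BCD, dihedral
## ABCD.
place_next_atom <- function(a, b, c, bond, theta, phi) {
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  c + cbind(bc, m, n) %*% d2
}

## Rigid transform: rotate `x` (rows) so that unit(x[k,]-x[1,]) maps onto
## `target`, after moving x[1,] to the origin; then spin about target by a
## random angle and translate to `anchor`.
orient_chain <- function(x, k, target, anchor, spin = stats::runif(1, 0, 2 * pi)) {
  x <- sweep(x, 2, x[1, ])
  v <- unit(x[k, ])
  target <- unit(target)
  ax <- pracma_cross(v, target)
  if (sqrt(sum(ax^2)) < 1e-12) {
    R <- if (sum(v * target) > 0) diag(3) else rotation_matrix(perp_unit(v), pi)
  } else {
    R <- rotation_matrix(ax, acos(min(1, max(-1, sum(v * target)))))
  }
  x <- x %*% t(R)
  x <- x %*% t(rotation_matrix(target, spin))
  sweep(x, 2, anchor, `+`)
}

#' Generate one lipid conformation
#'
#' Builds a 43-atom two-tailed lipid (see [mmg_topology()]) with the
#' branching carbon C5 at the origin. The initial tail segments leave C5 so
#' that the measured splay-1 angle (C9-C5-C22 vertex angle) equals
#' `splay1_target` exactly for all-trans chains; the distal segments run
#' along a common tilted axis, with tail 2 steered so the distal tails settle
#' near `tail_separation`. The headgroup (C1-C4, C6, O1-O5, hydroxyl
#' hydrogens) is stacked on the water-facing side, with the primary hydroxyl
#' O1 outermost.
#'
#' @param motif a [motif_spec()].
#' @param leaflet_direction +1 if water lies toward +z, -1 toward -z.
#' @param seed optional integer seed.
#' @param glycerol_dir optional unit 3-vector: current orientation of the
#'   C3->C1 glycerol vector (drawn isotropically if `NULL`).
#' @return 43 x 3 coordinate matrix with atom-name rownames, C5 at origin.
#' @export
generate_lipid <- function(motif, leaflet_direction = 1, seed = NULL,
                           glycerol_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- c(0, 0, sign(leaflet_direction))        # water side
  tilt <- abs(stats::rnorm(1, motif$tilt_mean, motif$tilt_sd)) * pi / 180
  d0 <- rotation_matrix(perp_unit(w), tilt) %*% (-w)   # shared distal axis
  d0 <- drop(d0)
  d0 <- drop(rotation_matrix(w, stats::runif(1, 0, 2 * pi)) %*% d0)
  p <- perp_unit(d0)
  p <- drop(rotation_matrix(d0, stats::runif(1, 0, 2 * pi)) %*% p)
  half <- motif$splay1_target / 2 * pi / 180
  u1 <- cos(half) * d0 + sin(half) * p
  u2 <- cos(half) * d0 - sin(half) * p

  c5 <- c(0, 0, 0)
  ## initial tail stubs anchored at C5: rows 2.. are the first tail atoms.
  ## Tail 1 stub is C7-C8-C9 with the C5->C9 direction aligned on u1; tail 2
  ## stub is C21-C22 with C5->C22 on u2, so the measured splay-1 angle
  ## (C9-C5-C22) equals the target exactly for all-trans stubs.
  s1 <- orient_chain(generate_chain(4, 0), 4, u1, c5)
  t1_init <- s1[2:4, , drop = FALSE]           # C7, C8, C9
  s2 <- orient_chain(generate_chain(3, 0), 3, u2, c5)
  t2_init <- s2[2:3, , drop = FALSE]           # C21, C22

  ## distal tail 1: carbons C10..C20 (11 atoms) continuing from C9 along d0
  e1 <- unit(d0 + 0.03 * stats::rnorm(3))
  q1 <- generate_chain(11, motif$gauche_prob)
  q1 <- orient_chain(q1, 11, e1, t1_init[3, ] + BOND_CC * e1)
  tail1 <- rbind(t1_init, q1)                  # C7..C20 (14)

  ## distal tail 2: steer toward a line parallel to tail 1 at the target
  ## separation, measured at mid-tail.
  a2 <- t1_init[3, ]                           # C9 anchor on tail-1 axis
  rel <- t2_init[2, ] - a2
  perp2 <- rel - sum(rel * e1) * e1
  perp2 <- if (sqrt(sum(perp2^2)) < 1e-9) perp_unit(e1) else unit(perp2)
  lh <- 8                                      # A, half the distal length
  aim <- a2 + motif$tail_separation * perp2 + lh * e1
  d2 <- unit(aim - t2_init[2, ])
  q2 <- generate_chain(13, motif$gauche_prob)
  q2 <- orient_chain(q2, 13, d2, t2_init[2, ] + BOND_CC * d2)
  tail2 <- rbind(t2_init, q2)                  # C21..C35 (15)

  ## headgroup stack toward water
  ph <- perp_unit(w)
  ph <- drop(rotation_matrix(w, stats::runif(1, 0, 2 * pi)) %*% ph)
  c4 <- c5 + BOND_CC * unit(w + 0.35 * ph)
  o2 <- c4 + 1.23 * unit(pracma_cross(w, ph))
  o4 <- c4 + 1.43 * unit(w - 0.35 * ph)
  c3 <- o4 + 1.43 * unit(w + 0.35 * ph)
  c2 <- c3 + BOND_CC * unit(w - 0.30 * ph)
  v <- glycerol_dir %||% unit(stats::rnorm(3))
  c1 <- c3 + 2.5 * v                           # C1 = C3 + |C1-C3| * dir
  o1 <- c1 + 1.43 * w
  ho1 <- o1 + 0.97 * w
  ## hydroxyl hydrogens all point toward the water side so undirected
  ## neighbours never satisfy the donor-angle criterion by accident
  o3 <- c2 + 1.43 * ph
  ho3 <- o3 + 0.97 * w
  c6 <- c5 + BOND_CC * unit(-ph + 0.3 * w)
  o5 <- c6 + 1.43 * w
  ho5 <- o5 + 0.97 * w

  out <- rbind(c1, c2, c3, c4, c5, c6, tail1, tail2,
               o1, o2, o3, o4, o5, ho1, ho3, ho5)
  rownames(out) <- c(paste0("C", 1:35), paste0("O", 1:5), "HO1", "HO3", "HO5")
  out
}

#' Specify a synthetic lamellar system
#'
#' Defaults describe a gel-phase single bilayer at the reference study
#' conditions: 500 lipids per leaflet, 39.8 A^2 area per lipid, headgroup
#' rotational modes at 2.1/57.3 ns with amplitudes 0.23/0.12.
#'
#' @param arrangement `"single_bilayer"`, `"double_bilayer"` or
#'   `"interdigitated"`.
#' @param n_per_leaflet lipids per leaflet.
#' @param motif_fractions weights over motifs 0..3, summing to 1.
#' @param apl_target area per lipid, A^2.
#' @param headgroup_tau1,headgroup_tau2 ps; fast/slow rotational times.
#' @param headgroup_a1,headgroup_a2 amplitudes of the two modes (the
#'   remaining `1 - a1 - a2` fraction of headgroups is rotationally frozen,
#'   producing the offset of the decay).
#' @param hbond_fraction fraction of outer-leaflet lipids planted in
#'   donor-acceptor hydrogen-bond geometry with a lattice neighbour.
#' @param n_frames,frame_dt frame count and spacing (ps).
#' @param seed master seed.
#' @param n_water number of three-site water molecules in the water slabs.
#' @param tail_resample logical; re-draw chain conformations each frame
#'   (default) or keep tails frozen (cheap mode for headgroup-dynamics runs).
#' @param motifs motif parameter set, default [default_motifs()].
#' @return object of class `synthetic_system_spec`.
#' @export
synthetic_system_spec <- function(arrangement = c("single_bilayer",
                                                  "double_bilayer",
                                                  "interdigitated"),
                                  n_per_leaflet = 500,
                                  motif_fractions = c(0.25, 0.25, 0.25, 0.25),
                                  apl_target = 39.8,
                                  headgroup_tau1 = 2100,
                                  headgroup_tau2 = 57300,
                                  headgroup_a1 = 0.23,
                                  headgroup_a2 = 0.12,
                                  hbond_fraction = 0,
                                  n_frames = 11,
                                  frame_dt = 100,
                                  seed = 1L,
                                  n_water = 0,
                                  tail_resample = TRUE,
                                  motifs = default_motifs()) {
  arrangement <- match.arg(arrangement)
  stopifnot(n_per_leaflet >= 1, apl_target > 0,
            headgroup_tau1 > 0, headgroup_tau2 > 0,
            headgroup_a1 >= 0, headgroup_a2 >= 0,
            headgroup_a1 + headgroup_a2 <= 1,
            hbond_fraction >= 0, hbond_fraction <= 1,
            n_frames >= 1, frame_dt > 0)
  if (abs(sum(motif_fractions) - 1) > 1e-9) {
    stop("motif_fractions must sum to 1", call. = FALSE)
  }
  structure(list(arrangement = arrangement, n_per_leaflet = n_per_leaflet,
                 motif_fractions = motif_fractions, apl_target = apl_target,
                 headgroup_tau1 = headgroup_tau1,
                 headgroup_tau2 = headgroup_tau2,
                 headgroup_a1 = headgroup_a1, headgroup_a2 = headgroup_a2,
                 hbond_fraction = hbond_fraction, n_frames = n_frames,
                 frame_dt = frame_dt, seed = as.integer(seed),
                 n_water = n_water, tail_resample = tail_resample,
                 motifs = motifs),
            class = "synthetic_system_spec")
}

## Leaflet C5-plane heights and water-facing directions per arrangement.
leaflet_planes <- function(arrangement, tail_len = 18, head_h = 8, gap = 4) {
  switch(arrangement,
    single_bilayer = data.frame(z0 = c(-tail_len, tail_len), dir = c(-1, 1)),
    double_bilayer = {
      c0 <- tail_len + head_h + gap / 2
      data.frame(z0 = c(-c0 - tail_len, -c0 + tail_len,
                        c0 - tail_len, c0 + tail_len),
                 dir = c(-1, 1, -1, 1))
    },
    interdigitated = {
      hs <- tail_len / 2 + 1                  # shared-slab half-height
      c0 <- hs + head_h + gap / 2
      data.frame(z0 = c(-c0 - hs, -c0 + hs, c0 - hs, c0 + hs),
                 dir = c(-1, 1, -1, 1))
    })
}

#' Generate a synthetic membrane trajectory with ground truth
#'
#' Lipids are placed on a jittered square lattice at the target area per
#' lipid; the interdigitated arrangement interleaves the two leaflets of each
#' unit on offset lattices inside one shared tail slab. Over frames, tail
#' conformations are re-drawn from the motif's rotamer statistics (unless
#' `tail_resample = FALSE`) and the glycerol C1-C3 vector of each lipid
#' evolves by rotational diffusion in three pools (fast `a1`, slow `a2`,
#' frozen `1-a1-a2`), so the population-average orientational
#' autocorrelation is `a1*exp(-t/tau1) + a2*exp(-t/tau2) + b`. A fraction of
#' outer-leaflet neighbour pairs is placed in O-H...O hydrogen-bond geometry
#' (2.9 A, aligned within the 3.5 A / 30 degree criterion).
#'
#' @param spec a [synthetic_system_spec()].
#' @return object of class `synthetic_membrane`: list with `traj`
#'   (a [membrane_trajectory()]), `motif` and `leaflet` ground-truth integer
#'   vectors per lipid, `planted_hbonds` (data frame of donor/acceptor lipid
#'   ids), and `spec`.
#' @export
generate_membrane_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_system_spec"))
  if (spec$apl_target < MIN_APL) {
    stop("packing error: apl_target ", spec$apl_target,
         " A^2 is below the two-tail excluded-volume floor (", MIN_APL,
         " A^2)", call. = FALSE)
  }
  set.seed(stage_seed(spec$seed, "generator"))
  topo <- mmg_topology()
  planes <- leaflet_planes(spec$arrangement)
  n_leaf <- nrow(planes)
  n_lip <- n_leaf * spec$n_per_leaflet
  Lx <- Ly <- sqrt(spec$n_per_leaflet * spec$apl_target)
  zmax <- max(abs(planes$z0)) + 12
  Lz <- 2 * zmax + 24

  ## lattice sites per leaflet (jittered); interdigitated leaflet pairs are
  ## offset by half a lattice spacing so their tails interleave in the slab
  m <- ceiling(sqrt(spec$n_per_leaflet))
  a <- Lx / m
  base <- expand.grid(ix = seq_len(m) - 1, iy = seq_len(m) - 1)
  base <- base[seq_len(spec$n_per_leaflet), ]
  sites <- lapply(seq_len(n_leaf), function(li) {
    off <- if (spec$arrangement == "interdigitated" && li %% 2 == 0) a / 2 else 0
    cbind(x = (base$ix + 0.5) * a + off + stats::runif(nrow(base), -.08, .08) * a,
          y = (base$iy + 0.5) * a + stats::runif(nrow(base), -.08, .08) * a)
  })

  ## ground truth: motif per lipid (deterministic counts, shuffled), leaflet
  counts <- floor(spec$motif_fractions * n_lip)
  rem <- n_lip - sum(counts)
  if (rem > 0) counts[order(spec$motif_fractions * n_lip - counts,
                            decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(spec$motif_fractions * n_lip - counts,
                   decreasing = TRUE)[seq_len(rem)]] + 1
  motif_of <- sample(rep(0:3, counts))
  leaflet_of <- rep(seq_len(n_leaf), each = spec$n_per_leaflet)

  ## headgroup dynamic pools: deterministic counts
  n_fast <- round(spec$headgroup_a1 * n_lip)
  n_slow <- round(spec$headgroup_a2 * n_lip)
  pool <- sample(rep(c("fast", "slow", "static"),
                     c(n_fast, n_slow, n_lip - n_fast - n_slow)))
  sigma <- c(fast = sqrt(2 * spec$frame_dt / spec$headgroup_tau1),
             slow = sqrt(2 * spec$frame_dt / spec$headgroup_tau2),
             static = 0)

  gly_dir <- t(apply(matrix(stats::rnorm(3 * n_lip), n_lip, 3), 1, unit))

  n_wat_atoms <- 3L * spec$n_water
  n_atoms <- n_lip * topo$atoms_per_lipid + n_wat_atoms
  coords <- array(NA_real_, c(n_atoms, 3, spec$n_frames))

  build_frame <- function(gdirs, lipid_xyz = NULL) {
    out <- if (is.null(lipid_xyz)) {
      xyz <- matrix(NA_real_, n_lip * topo$atoms_per_lipid, 3)
      for (i in seq_len(n_lip)) {
        li <- leaflet_of[i]
        site_i <- (i - 1) %% spec$n_per_leaflet + 1
        lip <- generate_lipid(spec$motifs[[as.character(motif_of[i])]],
                              leaflet_direction = planes$dir[li],
                              glycerol_dir = gdirs[i, ])
        lip <- sweep(lip, 2, c(sites[[li]][site_i, ], planes$z0[li]), `+`)
        xyz[((i - 1) * topo$atoms_per_lipid + 1):(i * topo$atoms_per_lipid), ] <- lip
      }
      xyz
    } else lipid_xyz
    out
  }

  ## frame 1 (full build)
  frame_xyz <- build_frame(gly_dir)

  ## plant hydrogen-bond pairs between outer-leaflet lattice neighbours
  planted <- data.frame(donor = integer(), acceptor = integer())
  if (spec$hbond_fraction > 0) {
    outer_leafs <- c(1L, n_leaf)
    for (li in outer_leafs) {
      ids <- which(leaflet_of == li)
      n_hb <- round(spec$hbond_fraction * length(ids))
      if (n_hb == 0) next
      don <- sample(ids, n_hb)
      for (d in don) {
        site_i <- (d - 1) %% spec$n_per_leaflet + 1
        ## neighbour on the lattice (next site index, wrapping)
        acc <- ids[(site_i %% length(ids)) + 1]
        if (acc == d) next
        oi <- function(l, nm) (l - 1) * topo$atoms_per_lipid + topo$name_map[[nm]]
        o1d <- frame_xyz[oi(d, "O1"), ]
        dir_xy <- unit(c(stats::rnorm(2), 0))
        ## acceptor O3 placed 2.9 A from donor O1; donor H aligned exactly
        frame_xyz[oi(acc, "O3"), ] <- o1d + 2.9 * dir_xy
        frame_xyz[oi(d, "HO1"), ] <- o1d + 0.97 * dir_xy
        planted <- rbind(planted, data.frame(donor = d, acceptor = acc))
      }
    }
  }

  ## water block (three-site, placed in the slabs beyond the outer leaflets)
  water_xyz <- NULL
  if (spec$n_water > 0) {
    zw <- ifelse(stats::runif(spec$n_water) < 0.5,
                 stats::runif(spec$n_water, zmax + 2, Lz / 2 - 2),
                 -stats::runif(spec$n_water, zmax + 2, Lz / 2 - 2))
    ow <- cbind(stats::runif(spec$n_water, 0, Lx),
                stats::runif(spec$n_water, 0, Ly), zw)
    water_xyz <- matrix(NA_real_, n_wat_atoms, 3)
    for (i in seq_len(spec$n_water)) {
      d1 <- unit(stats::rnorm(3)); d2 <- unit(stats::rnorm(3))
      water_xyz[(3 * i - 2):(3 * i), ] <- rbind(ow[i, ], ow[i, ] + 0.96 * d1,
                                                ow[i, ] + 0.96 * d2)
    }
  }

  gly_rows <- lapply(c("C1", "O1", "HO1"), function(nm)
    (seq_len(n_lip) - 1) * topo$atoms_per_lipid + topo$name_map[[nm]])
  c3_rows <- (seq_len(n_lip) - 1) * topo$atoms_per_lipid + topo$name_map[["C3"]]

  gd <- gly_dir
  for (fi in seq_len(spec$n_frames)) {
    if (fi > 1) {
      ## rotational diffusion step for every non-static headgroup vector:
      ## rotate v about a random axis perpendicular to v by N(0, sigma)
      mob <- which(pool != "static")
      if (length(mob) > 0) {
        v <- gd[mob, , drop = FALSE]
        g <- matrix(stats::rnorm(3 * length(mob)), ncol = 3)
        g <- g - rowSums(g * v) * v
        k <- g / sqrt(rowSums(g^2))
        th <- stats::rnorm(length(mob), 0, sigma[pool[mob]])
        kxv <- cbind(k[, 2] * v[, 3] - k[, 3] * v[, 2],
                     k[, 3] * v[, 1] - k[, 1] * v[, 3],
                     k[, 1] * v[, 2] - k[, 2] * v[, 1])
        vn <- v * cos(th) + kxv * sin(th)   # k.v = 0, so no parallel term
        gd[mob, ] <- vn / sqrt(rowSums(vn^2))
      }
      if (spec$tail_resample) {
        frame_xyz <- build_frame(gd)
        if (nrow(planted) > 0) {
          ## keep planted bond geometry stable across frames
          for (r in seq_len(nrow(planted))) {
            d <- planted$donor[r]; acc <- planted$acceptor[r]
            oi <- function(l, nm) (l - 1) * topo$atoms_per_lipid + topo$name_map[[nm]]
            o1d <- frame_xyz[oi(d, "O1"), ]
            dir_xy <- unit(c(stats::rnorm(2), 0))
            frame_xyz[oi(acc, "O3"), ] <- o1d + 2.9 * dir_xy
            frame_xyz[oi(d, "HO1"), ] <- o1d + 0.97 * dir_xy
          }
        }
      } else {
        ## cheap update: re-point C1 (and O1/HO1 stack) from the new vector
        w_per <- planes$dir[leaflet_of]
        c1 <- frame_xyz[c3_rows, ] + 2.5 * gd
        frame_xyz[gly_rows[[1]], ] <- c1
        frame_xyz[gly_rows[[2]], ] <- c1 + cbind(0, 0, 1.43 * w_per)
        frame_xyz[gly_rows[[3]], ] <- c1 + cbind(0, 0, 2.40 * w_per)
      }
    }
    coords[, , fi] <- rbind(frame_xyz, water_xyz)
  }

  atom_names <- c(rep(topo$atom_names, n_lip),
                  if (spec$n_water > 0) rep(c("OW", "HW1", "HW2"), spec$n_water))
  resnames <- c(rep(topo$lipid_name, n_lip * topo$atoms_per_lipid),
                if (spec$n_water > 0) rep("SOL", n_wat_atoms))
  traj <- membrane_trajectory(
    coords, matrix(rep(c(Lx, Ly, Lz), each = spec$n_frames), ncol = 3),
    times = (seq_len(spec$n_frames) - 1) * spec$frame_dt,
    topology = topo, n_lipids = n_lip,
    atom_names = atom_names, resnames = resnames)
  structure(list(traj = traj, motif = motif_of, leaflet = leaflet_of,
                 planted_hbonds = planted, spec = spec),
            class = "synthetic_membrane")
}

#' @export
print.synthetic_membrane <- function(x, ...) {
  cat("<synthetic_membrane> ", x$spec$arrangement, ", ",
      x$traj$n_lipids, " lipids, ", x$traj$n_frames, " frames; motifs ",
      paste(table(factor(x$motif, 0:3)), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Generate a noisy double-exponential decay curve
#'
#' `y(t) = a1*exp(-t/tau1) + a2*exp(-t/tau2) + b + N(0, noise_sd)`, the
#' reference shape of rotational autocorrelation decays.
#'
#' @param a1,tau1,a2,tau2,b curve parameters (times in the unit of `lags`).
#' @param noise_sd Gaussian noise standard deviation.
#' @param lags time points.
#' @param seed optional integer seed.
#' @return a `profile_series` data frame with columns `lag`, `value`.
#' @export
generate_decay_curve <- function(a1, tau1, a2, tau2, b = 1 - a1 - a2,
                                 noise_sd = 0, lags, seed = NULL) {
  stopifnot(tau1 > 0, tau2 > 0)
  if (!is.null(seed)) set.seed(seed)
  y <- a1 * exp(-lags / tau1) + a2 * exp(-lags / tau2) + b
  if (noise_sd > 0) y <- y + stats::rnorm(length(lags), 0, noise_sd)
  structure(data.frame(lag = lags, value = y),
            class = c("profile_series", "data.frame"),
            kind = "decay_curve")
}
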