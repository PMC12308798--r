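## Membrane geometry: area per lipid (box and Voronoi), density profiles
## along z, and electron-density peak-to-peak thickness. Membranes are
## treated as planar with the normal along z.

#' Area per lipid from box dimensions
#'
#' `APL_xy = Lx * Ly / n_per_leaflet` per frame, with mean and standard
#' deviation over frames.
#'
#' @param traj a `mem_traj`.
#' @param n_per_leaflet lipids per leaflet.
#' @return list with `per_frame` (A^2), `mean`, `sd`.
#' @export
apl_xy <- function(traj, n_per_leaflet) {
  stopifnot(n_per_leaflet > 0)
  per_frame <- traj$box[, 1] * traj$box[, 2] / n_per_leaflet
  list(per_frame = per_frame, mean = mean(per_frame),
       sd = stats::sd(per_frame) %||% 0)
}

## Sutherland-Hodgman clip of polygon `poly` (k x 2) by the half-plane
## {x : dot(x - p0, nrm) <= off}; returns clipped polygon.
clip_halfplane <- function(poly, nrm, off) {
  k <- nrow(poly)
  val <- poly %*% nrm - off
  keep <- val <= 1e-12
  if (all(keep)) return(poly)
  if (!any(keep)) return(poly[0, , drop = FALSE])
  out <- matrix(0, 0, 2)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    if (keep[i]) out <- rbind(out, poly[i, ])
    if (xor(keep[i], keep[j])) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

polygon_area <- function(poly) {
  if (nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Periodic 2D Voronoi cell areas
#'
#' Cell areas of `sites` in a periodic `Lx` x `Ly` rectangle, computed by
#' half-plane clipping against the perpendicular bisectors of all 8-image
#' replicated neighbours. Exact up to floating point; cell areas sum to the
#' box area.
#'
#' @param sites n x 2 matrix of xy positions.
#' @param Lx,Ly box edges (Angstrom).
#' @return numeric vector of per-site areas (A^2).
#' @export
voronoi_areas_2d <- function(sites, Lx, Ly) {
  n <- nrow(sites)
  if (n < 3) stop("need at least 3 sites per leaflet", call. = FALSE)
  sites <- cbind(sites[, 1] %% Lx, sites[, 2] %% Ly)
  shifts <- as.matrix(expand.grid(dx = c(-Lx, 0, Lx), dy = c(-Ly, 0, Ly)))
  all_pts <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k)
    sweep(sites, 2, shifts[k, ], `+`)))
  areas <- numeric(n)
  half <- max(Lx, Ly)
  sq <- cbind(c(-half, half, half, -half), c(-half, -half, half, half))
  for (i in seq_len(n)) {
    s <- sites[i, ]
    rel <- sweep(all_pts, 2, s)
    d2 <- rowSums(rel^2)
    ord <- order(d2)
    ord <- ord[d2[ord] > 1e-18]          # drop the site's own central copy
    poly <- sweep(sq, 2, s, `+`)
    for (j in ord) {
      dj <- sqrt(d2[j])
      rmax2 <- max(rowSums(sweep(poly, 2, s)^2))
      if (dj * dj / 4 > rmax2) break     # no further neighbour can cut
      poly <- clip_halfplane(poly, rel[j, ],
                             sum(rel[j, ] * (s + all_pts[j, ]) / 2))
      if (nrow(poly) < 3) break
    }
    areas[i] <- polygon_area(poly)
  }
  areas
}

#' Area per lipid by periodic Voronoi tessellation
#'
#' Projects per-lipid headgroup centres of mass of the water-facing
#' (outer) leaflets onto the xy plane, tessellates each leaflet per frame
#' with periodic images, and aggregates the per-lipid cell areas. The
#' distribution mode is located on a 0.5 A^2 histogram.
#'
#' @param traj a `mem_traj`.
#' @param leaflets a [assign_leaflets()] result.
#' @param site_atoms atom names whose (mass-weighted) centre of mass defines
#'   each lipid's site; default the topology headgroup.
#' @param frames frame indices (default all).
#' @return list: `areas` (all per-lipid areas pooled over outer leaflets and
#'   frames), `mean`, `median`, `mode`, `by_frame_leaflet_sum` (for the area
#'   conservation check).
#' @export
apl_voronoi <- function(traj, leaflets, site_atoms = NULL,
                        frames = seq_len(traj$n_frames)) {
  site_atoms <- site_atoms %||% traj$topology$headgroup_atoms
  outer_ids <- which(leaflets$outer)
  areas <- list()
  sums <- numeric(0)
  for (fi in frames) {
    com <- lipid_com(traj, fi, site_atoms)
    for (li in outer_ids) {
      sel <- which(leaflets$leaflet[, fi] == li)
      if (length(sel) < 3) {
        stop("tessellation error: fewer than 3 sites in leaflet ", li,
             call. = FALSE)
      }
      a <- voronoi_areas_2d(com[sel, 1:2, drop = FALSE],
                            traj$box[fi, 1], traj$box[fi, 2])
      areas[[length(areas) + 1L]] <- a
      sums <- c(sums, sum(a))
    }
  }
  pooled <- unlist(areas)
  br <- seq(floor(min(pooled)), ceiling(max(pooled)) + 0.5, by = 0.5)
  h <- graphics::hist(pooled, breaks = br, plot = FALSE)
  list(areas = pooled, mean = mean(pooled), median = stats::median(pooled),
       mode = h$mids[which.max(h$counts)],
       by_frame_leaflet_sum = sums,
       box_area = traj$box[frames, 1] * traj$box[frames, 2])
}

## mass-weighted centre of mass of named atoms, per lipid, one frame
lipid_com <- function(traj, frame, atom_names) {
  within <- resolve_atoms(traj$topology, atom_names)
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
              S = 32.06)
  el <- toupper(substr(gsub("^[0-9]+", "", atom_names), 1, 1))
  m <- unname(masses[el])
  apl <- traj$topology$atoms_per_lipid
  xyz <- traj$coords[, , frame, drop = TRUE]
  out <- matrix(0, traj$n_lipids, 3)
  for (k in seq_along(within)) {
    idx <- (seq_len(traj$n_lipids) - 1L) * apl + within[k]
    out <- out + m[k] * xyz[idx, , drop = FALSE]
  }
  out / sum(m)
}

#' Density profile along the membrane normal
#'
#' Histogram of selected atoms along z, weighted by electron count (atomic
#' number minus an optional partial charge), mass, or 1 (number density),
#' averaged over frames and normalised per bin volume. Also stores per-block
#' profiles for block-averaged thickness estimation.
#'
#' @param traj a `mem_traj`.
#' @param selection atom names (resolved per lipid) or global atom indices;
#'   default all atoms.
#' @param weighting `"electron"`, `"mass"` or `"number"`.
#' @param n_bins number of z bins (>= 10).
#' @param charges optional per-atom partial charges (same order/length as the
#'   selection's global indices) subtracted from atomic numbers for electron
#'   weighting; default zero.
#' @param n_blocks number of contiguous frame blocks stored for block
#'   analysis (default 5).
#' @return object of class `density_profile`: data frame `z`, `value`
#'   (per A^3), with attributes `block_values` (bins x blocks), `weighting`,
#'   `peaks`, `bin_width`, `box_area`.
#' @export
density_profile <- function(traj, selection = NULL,
                            weighting = c("electron", "mass", "number"),
                            n_bins = 100, charges = NULL, n_blocks = 5) {
  weighting <- match.arg(weighting)
  stopifnot(n_bins >= 10)
  idx <- if (is.null(selection)) {
    seq_len(traj$n_atoms)
  } else if (is.character(selection)) {
    as.vector(vapply(selection, function(nm) atom_indices(traj, nm),
                     integer(traj$n_lipids)))
  } else as.integer(selection)
  if (length(idx) == 0) stop("empty selection", call. = FALSE)
  names_sel <- traj$atom_names[idx]
  w <- switch(weighting,
    number = rep(1, length(idx)),
    mass = {
      masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
                  S = 32.06)
      unname(masses[toupper(substr(gsub("^[0-9]+", "", names_sel), 1, 1))])
    },
    electron = electrons_for_name(names_sel) - (charges %||% 0))
  z_all <- traj$coords[idx, 3, , drop = FALSE]
  zr <- range(z_all)
  zr <- zr + c(-1e-9, 1e-9)
  edges <- seq(zr[1], zr[2], length.out = n_bins + 1)
  dz <- diff(edges)[1]
  area <- mean(traj$box[, 1] * traj$box[, 2])
  n_blocks <- min(n_blocks, traj$n_frames)
  block_of <- ceiling(seq_len(traj$n_frames) / (traj$n_frames / n_blocks))
  block_vals <- matrix(0, n_bins, n_blocks)
  for (fi in seq_len(traj$n_frames)) {
    b <- findInterval(z_all[, 1, fi], edges, rightmost.closed = TRUE)
    acc <- vapply(seq_len(n_bins), function(k) sum(w[b == k]), numeric(1))
    block_vals[, block_of[fi]] <- block_vals[, block_of[fi]] + acc
  }
  frames_per_block <- tabulate(block_of, n_blocks)
  block_vals <- sweep(block_vals, 2, frames_per_block * dz * area, `/`)
  value <- as.vector(block_vals %*% (frames_per_block / traj$n_frames))
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  pk <- find_profile_peaks(centers, value)
  structure(data.frame(z = centers, value = value),
            class = c("density_profile", "data.frame"),
            block_values = block_vals, weighting = weighting,
            peaks = pk, bin_width = dz, box_area = area)
}

## Local maxima with quadratic sub-bin refinement. The profile is smoothed
## with a short boxcar first so single-bin sampling noise does not spawn
## shoulder peaks; boundary bins count as candidates (delta-like layers can
## sit in the first/last bin).
find_profile_peaks <- function(z, v, min_frac = 0.2, smooth = 5) {
  n <- length(v)
  if (n < 3) return(numeric(0))
  if (smooth > 1 && n > smooth) {
    k <- rep(1 / smooth, smooth)
    v <- as.vector(stats::filter(c(rep(v[1], smooth), v, rep(v[n], smooth)),
                                 k, sides = 2))[(smooth + 1):(smooth + n)]
  }
  vp <- c(-Inf, v, -Inf)
  thr <- min_frac * max(v)
  cand <- which(vp[2:(n + 1)] > vp[1:n] & vp[2:(n + 1)] >= vp[3:(n + 2)] &
                  vp[2:(n + 1)] >= thr)
  if (length(cand) == 0) return(numeric(0))
  dz <- z[2] - z[1]
  pos <- vapply(cand, function(i) {
    if (i == 1L || i == n) return(z[i])
    denom <- v[i - 1] - 2 * v[i] + v[i + 1]
    off <- if (abs(denom) > 1e-12) 0.5 * (v[i - 1] - v[i + 1]) / denom else 0
    z[i] + max(-0.5, min(0.5, off)) * dz
  }, numeric(1))
  ## distinct density peaks (leaflet layers) are several Angstrom apart;
  ## shoulders within min_sep of a taller peak are sampling noise
  min_sep <- 4
  keep <- numeric(0)
  for (i in order(v[cand], decreasing = TRUE)) {
    if (all(abs(pos[i] - keep) >= min_sep)) keep <- c(keep, pos[i])
  }
  sort(keep)
}

#' Membrane thickness from density-profile peaks
#'
#' Peak-to-peak distances computed per frame block and averaged: `overall`
#' is the separation of the two outermost peaks (whole membrane stack);
#' `per_bilayer` is the mean distance from each outer peak to the central
#' peak (individual bilayer thickness in multilamellar configurations).
#'
#' @param profile a [density_profile()] (its block profiles are used).
#' @param mode `"overall"` or `"per_bilayer"`.
#' @return list: `thickness` (block mean, A), `sd` (over blocks),
#'   `per_block`, `mode`.
#' @export
thickness_from_profile <- function(profile, mode = c("overall", "per_bilayer")) {
  mode <- match.arg(mode)
  bv <- attr(profile, "block_values")
  z <- profile$z
  per_block <- vapply(seq_len(ncol(bv)), function(b) {
    pk <- find_profile_peaks(z, bv[, b])
    if (length(pk) < 2) {
      stop("peak-detection error: block ", b, " has ", length(pk),
           " resolvable peak(s); need >= 2", call. = FALSE)
    }
    if (mode == "overall") {
      max(pk) - min(pk)
    } else {
      if (length(pk) < 3) {
        stop("peak-detection error: per_bilayer mode needs >= 3 peaks, block ",
             b, " has ", length(pk), call. = FALSE)
      }
      mid <- (max(pk) + min(pk)) / 2
      central <- pk[which.min(abs(pk - mid))]
      mean(c(max(pk) - central, central - min(pk)))
    }
  }, numeric(1))
  list(thickness = mean(per_block), sd = stats::sd(per_block) %||% 0,
       per_block = per_block, mode = mode)
}
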