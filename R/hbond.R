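## Hydrogen bonding at the lipid-water interface: geometric detection
## (donor-acceptor distance and acceptor-donor-hydrogen angle), per-molecule
## statistics, and intermittent bond autocorrelation.

## donor table (rows: oxygen id, hydrogen id, molecule, group tag) and
## acceptor table for lipids + three-site water
hbond_sites <- function(traj) {
  topo <- traj$topology
  apl <- topo$atoms_per_lipid
  don <- list(); acc <- list()
  for (dpair in topo$donors) {
    o <- resolve_atoms(topo, dpair[1]); h <- resolve_atoms(topo, dpair[2])
    ids <- (seq_len(traj$n_lipids) - 1L) * apl
    don[[length(don) + 1L]] <- data.frame(
      o = ids + o, h = ids + h, mol = seq_len(traj$n_lipids),
      group = paste0(dpair[1], "-H"), water = FALSE)
  }
  for (anm in topo$acceptors) {
    a <- resolve_atoms(topo, anm)
    ids <- (seq_len(traj$n_lipids) - 1L) * apl
    acc[[length(acc) + 1L]] <- data.frame(
      a = ids + a, mol = seq_len(traj$n_lipids), group = anm, water = FALSE)
  }
  ow <- which(traj$atom_names == "OW")
  if (length(ow) > 0) {
    wmol <- traj$n_lipids + seq_along(ow)
    for (hoff in 1:2) {
      don[[length(don) + 1L]] <- data.frame(
        o = ow, h = ow + hoff, mol = wmol, group = "water", water = TRUE)
    }
    acc[[length(acc) + 1L]] <- data.frame(
      a = ow, mol = wmol, group = "water", water = TRUE)
  }
  list(donors = do.call(rbind, don), acceptors = do.call(rbind, acc))
}

#' Detect hydrogen bonds in one frame
#'
#' A bond exists when the donor and acceptor oxygens are within `d_cut` and
#' the acceptor-donor-hydrogen angle (vertex at the donor) is at most
#' `angle_cut`; the minimum-image convention is applied in all three box
#' dimensions. Donor-hydrogen pairing comes from the topology (hydroxyl
#' groups donate and accept; carbonyl/ester oxygens only accept); water is
#' included when `OW/HW1/HW2` atoms are present. Water-water pairs are not
#' reported.
#'
#' @param traj a `mem_traj`.
#' @param frame frame index.
#' @param d_cut donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cut acceptor-donor-hydrogen angle cutoff, degrees
#'   (default 30).
#' @return data frame (one row per bond): `frame`, `donor`, `hydrogen`,
#'   `acceptor` (global atom ids), `donor_mol`, `acceptor_mol`, `class`
#'   (`"intra"`, `"inter"`, `"lipid-water"`), `donor_group`,
#'   `acceptor_group`.
#' @export
detect_hbonds <- function(traj, frame = 1, d_cut = 3.5, angle_cut = 30) {
  sites <- hbond_sites(traj)
  D <- sites$donors; A <- sites$acceptors
  if (is.null(D) || nrow(D) == 0) {
    stop("topology error: no donor groups with hydrogen pairing", call. = FALSE)
  }
  xyz <- traj$coords[, , frame, drop = TRUE]
  L <- traj$box[frame, ]
  out <- list()
  chunk <- 512L
  cos_cut <- cos(angle_cut * pi / 180)
  for (s in seq(1, nrow(D), by = chunk)) {
    di <- s:min(s + chunk - 1L, nrow(D))
    dO <- xyz[D$o[di], , drop = FALSE]
    dH <- xyz[D$h[di], , drop = FALSE]
    for (dim3 in 1:3) {
      dx <- min_image(outer(xyz[A$a, dim3], dO[, dim3], `-`), L[dim3])
      if (dim3 == 1) { d2 <- dx^2; dxs <- list(dx) } else {
        d2 <- d2 + dx^2; dxs[[dim3]] <- dx
      }
    }
    hit <- which(d2 <= d_cut^2 & d2 > 1e-6, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    ai <- hit[, 1]; dj <- hit[, 2]
    ## acceptor-donor-hydrogen angle at the donor oxygen
    da <- cbind(dxs[[1]][hit], dxs[[2]][hit], dxs[[3]][hit])
    dh <- dH[dj, , drop = FALSE] - dO[dj, , drop = FALSE]
    for (dim3 in 1:3) dh[, dim3] <- min_image(dh[, dim3], L[dim3])
    ca <- rowSums(da * dh) / (sqrt(rowSums(da^2)) * sqrt(rowSums(dh^2)))
    ok <- ca >= cos_cut
    if (!any(ok)) next
    ai <- ai[ok]; dj <- dj[ok]
    dmol <- D$mol[di][dj]; amol <- A$mol[ai]
    dwat <- D$water[di][dj]; awat <- A$water[ai]
    keep <- !(dwat & awat) & !(D$o[di][dj] == A$a[ai])
    if (!any(keep)) next
    cls <- ifelse(dwat[keep] | awat[keep], "lipid-water",
                  ifelse(dmol[keep] == amol[keep], "intra", "inter"))
    out[[length(out) + 1L]] <- data.frame(
      frame = frame, donor = D$o[di][dj][keep], hydrogen = D$h[di][dj][keep],
      acceptor = A$a[ai][keep], donor_mol = dmol[keep],
      acceptor_mol = amol[keep], class = cls,
      donor_group = D$group[di][dj][keep], acceptor_group = A$group[ai][keep])
  }
  if (length(out) == 0) {
    data.frame(frame = integer(0), donor = integer(0), hydrogen = integer(0),
               acceptor = integer(0), donor_mol = integer(0),
               acceptor_mol = integer(0), class = character(0),
               donor_group = character(0), acceptor_group = character(0))
  } else do.call(rbind, out)
}

#' Per-molecule hydrogen-bond statistics
#'
#' Counts intra- and intermolecular lipid-lipid bonds per frame, divided by
#' the number of lipids, and breaks lipid-water bonds down by lipid oxygen
#' group (hydroxyls count as donors and acceptors, carbonyl/ester oxygens as
#' acceptors only). Means and standard deviations are over frames.
#'
#' @param traj a `mem_traj`.
#' @param frames frame indices (default all).
#' @param d_cut,angle_cut geometric criterion (3.5 Angstrom, 30 degrees).
#' @return list: `intra` and `inter` (`mean`, `sd`, `per_frame` bonds per
#'   molecule), `water_by_group` (data frame `group`, `mean`, `sd`).
#' @export
hbond_statistics <- function(traj, frames = seq_len(traj$n_frames),
                             d_cut = 3.5, angle_cut = 30) {
  groups <- c(vapply(traj$topology$donors, function(d) paste0(d[1], "-H"),
                     character(1)),
              setdiff(traj$topology$acceptors,
                      vapply(traj$topology$donors, `[`, character(1), 1)))
  n_intra <- n_inter <- numeric(length(frames))
  wtab <- matrix(0, length(frames), length(groups),
                 dimnames = list(NULL, groups))
  for (k in seq_along(frames)) {
    hb <- detect_hbonds(traj, frames[k], d_cut, angle_cut)
    n_intra[k] <- sum(hb$class == "intra")
    n_inter[k] <- sum(hb$class == "inter")
    lw <- hb[hb$class == "lipid-water", , drop = FALSE]
    if (nrow(lw) > 0) {
      lipid_grp <- ifelse(lw$donor_group != "water", lw$donor_group,
                          ifelse(lw$acceptor_group %in%
                                   sub("-H", "", grep("-H", groups,
                                                      value = TRUE)),
                                 paste0(lw$acceptor_group, "-H"),
                                 lw$acceptor_group))
      tb <- table(factor(lipid_grp, levels = groups))
      wtab[k, ] <- as.numeric(tb)
    }
  }
  N <- traj$n_lipids
  list(
    intra = list(mean = mean(n_intra / N), sd = stats::sd(n_intra / N) %||% 0,
                 per_frame = n_intra / N),
    inter = list(mean = mean(n_inter / N), sd = stats::sd(n_inter / N) %||% 0,
                 per_frame = n_inter / N),
    water_by_group = data.frame(
      group = groups,
      mean = colMeans(wtab) / N,
      sd = apply(wtab / N, 2, function(x) stats::sd(x) %||% 0),
      row.names = NULL))
}

#' Intermittent hydrogen-bond autocorrelation
#'
#' For every donor-acceptor pair ever bonded in the window, the indicator
#' `h(t)` (1 when bonded) is correlated over all time origins:
#' `C(t) = <h(tau) h(tau+t)> / <h(tau)^2>`. With `correction = TRUE`
#' (tail-corrected form) the long-lag plateau (mean over the last fifth of
#' lags) is subtracted and the series renormalised to `C(0) = 1`; the
#' plateau value is kept as an attribute.
#'
#' @param traj a `mem_traj` (>= 2 frames).
#' @param frames frame indices (default all).
#' @param d_cut,angle_cut geometric criterion.
#' @param correction subtract the long-lag plateau (default `TRUE`).
#' @param max_lag maximal lag in frames (default half the window).
#' @return data frame (class `acf_series`): `lag` (ps), `acf`; attributes
#'   `plateau`, `corrected`, `n_pairs`.
#' @export
hbond_acf <- function(traj, frames = seq_len(traj$n_frames), d_cut = 3.5,
                      angle_cut = 30, correction = TRUE, max_lag = NULL) {
  if (length(frames) < 2) stop("need >= 2 frames", call. = FALSE)
  bonds <- lapply(frames, function(f) {
    hb <- detect_hbonds(traj, f, d_cut, angle_cut)
    hb <- hb[hb$class %in% c("intra", "inter"), , drop = FALSE]
    paste(hb$donor, hb$acceptor, sep = ":")
  })
  keys <- unique(unlist(bonds))
  if (length(keys) == 0) stop("no hydrogen bonds in the window", call. = FALSE)
  Fn <- length(frames)
  H <- vapply(bonds, function(b) keys %in% b, logical(length(keys)))
  H <- matrix(as.numeric(H), nrow = length(keys))   # pairs x frames
  max_lag <- max_lag %||% floor((Fn - 1) / 2)
  raw <- vapply(0:max_lag, function(L) {
    i1 <- seq_len(Fn - L)
    mean(H[, i1, drop = FALSE] * H[, i1 + L, drop = FALSE])
  }, numeric(1))
  raw <- raw / raw[1]
  plateau <- mean(raw[max(2, floor(0.8 * length(raw))):length(raw)])
  acf <- if (correction && plateau < 1) (raw - plateau) / (1 - plateau) else raw
  dt <- stats::median(diff(traj$times[frames]))
  structure(data.frame(lag = (0:max_lag) * dt, acf = acf),
            class = c("acf_series", "data.frame"),
            plateau = plateau, corrected = correction,
            n_pairs = length(keys))
}

#' Glycerol-vector rotational autocorrelation
#'
#' The orientational autocorrelation of the C1-to-C3 glycerol vector;
#' delegates to [vector_acf()].
#'
#' @param traj a `mem_traj`.
#' @param max_lag maximal lag in frames.
#' @return an `acf_series` data frame.
#' @export
glycerol_acf <- function(traj, max_lag = NULL) {
  vector_acf(traj, traj$topology$glycerol_vector_atoms, max_lag = max_lag)
}
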