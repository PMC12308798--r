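## Per-lipid radial-angular three-particle correlation fingerprints: for a
## central atom B, its nearest selection neighbour A, and every other
## selection atom C within the cutoff, the (r_BC, cos theta_ABC) density.
## Intramolecular only: B, A and C all belong to the same lipid.

#' Default fingerprint grid
#' @return list `nr`, `na`, `cutoff` (201 radial bins over (0, 15 A],
#'   101 bins over cos theta in \[-1, 1\]).
#' @export
g3_grid <- function() list(nr = 201L, na = 101L, cutoff = 15)

#' Three-particle correlation histogram of one lipid
#'
#' Accumulates (r_BC, cos theta_ABC) deposits over the stated frames and
#' normalises the frame-averaged histogram to unit total mass. The nearest
#' neighbour A is the closest other selection atom of the same lipid, ties
#' resolved by lowest atom index; C ranges over all selection atoms except B
#' (including A itself, which produces the singular first peak at
#' cos theta = 1).
#'
#' @param traj a `mem_traj`.
#' @param lipid_id lipid index (1-based).
#' @param selection atom names; default the topology's `g3_selection`.
#' @param cutoff radial cutoff in Angstrom (default 15).
#' @param bins `c(n_radial, n_angular)` (default `c(201, 101)`).
#' @param window_frames frame indices to average over (default all).
#' @return `g3_histogram`: an `nr x na` matrix of non-negative densities
#'   summing to 1, with attributes `r_edges`, `cos_edges`, `cutoff`.
#' @export
compute_g3 <- function(traj, lipid_id, selection = NULL, cutoff = 15,
                       bins = c(201L, 101L),
                       window_frames = seq_len(traj$n_frames)) {
  sel <- selection %||% traj$topology$g3_selection
  if (length(sel) < 3) stop("g3 selection needs >= 3 atoms", call. = FALSE)
  within <- resolve_atoms(traj$topology, sel)
  idx <- (lipid_id - 1L) * traj$topology$atoms_per_lipid + within
  sub <- traj$coords[idx, , window_frames, drop = FALSE]
  h <- .g3_accumulate_cpp(as.numeric(sub), length(idx), length(window_frames),
                          cutoff, as.integer(bins[1]), as.integer(bins[2]))
  tot <- sum(h)
  if (tot > 0) h <- h / tot
  structure(h, class = c("g3_histogram", "matrix"),
            r_edges = seq(0, cutoff, length.out = bins[1] + 1),
            cos_edges = seq(-1, 1, length.out = bins[2] + 1),
            cutoff = cutoff)
}

#' Fingerprints for many lipids
#'
#' @inheritParams compute_g3
#' @param lipids lipid indices (default all).
#' @return 3D array `nr x na x n_lipids` of unit-mass histograms, with the
#'   same grid attributes as [compute_g3()].
#' @export
compute_g3_all <- function(traj, lipids = seq_len(traj$n_lipids),
                           selection = NULL, cutoff = 15,
                           bins = c(201L, 101L),
                           window_frames = seq_len(traj$n_frames)) {
  out <- array(0, c(bins[1], bins[2], length(lipids)))
  for (k in seq_along(lipids)) {
    out[, , k] <- compute_g3(traj, lipids[k], selection, cutoff, bins,
                             window_frames)
  }
  structure(out, r_edges = seq(0, cutoff, length.out = bins[1] + 1),
            cos_edges = seq(-1, 1, length.out = bins[2] + 1),
            cutoff = cutoff)
}
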