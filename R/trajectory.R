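## Trajectory container + GRO text I/O + analysis-window and leaflet tools.
## Internal units are Angstrom and picosecond regardless of the input dialect
## (GRO files are nm-based and converted on read, and back on write).

#' Construct a membrane trajectory object
#'
#' The in-memory container shared by all analyses: per-frame coordinates and
#' periodic box, frame times, and the lipid topology with the atom-to-molecule
#' map. Lipid atoms come first and are contiguously indexed per molecule;
#' an optional solvent block follows.
#'
#' @param coords numeric array `[n_atoms, 3, n_frames]`, Angstrom.
#' @param box numeric matrix `[n_frames, 3]` with `(Lx, Ly, Lz)`, Angstrom.
#' @param times numeric vector of frame times in ps, strictly increasing.
#' @param topology a [lipid_topology()].
#' @param n_lipids number of lipid molecules.
#' @param atom_names character vector of atom names (length `n_atoms`).
#' @param resnames character vector of residue names (length `n_atoms`).
#' @return object of class `mem_traj`.
#' @export
membrane_trajectory <- function(coords, box, times, topology, n_lipids,
                                atom_names, resnames = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  n_atoms <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  box <- matrix(box, ncol = 3)
  stopifnot(nrow(box) == n_frames, length(times) == n_frames,
            length(atom_names) == n_atoms)
  if (n_frames > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  if (any(box <= 0)) stop("box edges must be positive", call. = FALSE)
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  n_lipid_atoms <- n_lipids * topology$atoms_per_lipid
  if (n_atoms < n_lipid_atoms) {
    stop("topology error: ", n_atoms, " atoms cannot hold ", n_lipids,
         " lipids of ", topology$atoms_per_lipid, " atoms", call. = FALSE)
  }
  molecule_index <- rep(NA_integer_, n_atoms)
  molecule_index[seq_len(n_lipid_atoms)] <-
    rep(seq_len(n_lipids), each = topology$atoms_per_lipid)
  structure(list(
    coords = coords, box = box, times = times, topology = topology,
    n_lipids = n_lipids, n_frames = n_frames, n_atoms = n_atoms,
    molecule_index = molecule_index, atom_names = atom_names,
    resnames = resnames %||% rep(topology$lipid_name, n_atoms)
  ), class = "mem_traj")
}

#' @export
print.mem_traj <- function(x, ...) {
  cat("<mem_traj> ", x$n_frames, " frames, ", x$n_lipids, " lipids (",
      x$n_atoms, " atoms), t = ", x$times[1], "..",
      x$times[x$n_frames], " ps, box ",
      paste(sprintf("%.1f", x$box[x$n_frames, ]), collapse = " x "),
      " A\n", sep = "")
  invisible(x)
}

#' Global atom indices of a named atom, one per lipid
#' @param traj a `mem_traj`.
#' @param name atom name resolvable in the topology.
#' @return integer vector of length `n_lipids`.
#' @export
atom_indices <- function(traj, name) {
  within <- resolve_atoms(traj$topology, name)
  (seq_len(traj$n_lipids) - 1L) * traj$topology$atoms_per_lipid + within
}

## ---- GRO text I/O -----------------------------------------------------

parse_gro_frames <- function(lines, path) {
  frames <- list()
  pos <- 1L
  n_total <- length(lines)
  while (pos <= n_total) {
    if (all(!nzchar(trimws(lines[pos:n_total])))) break
    fi <- length(frames) + 1L
    fail <- function(msg) {
      stop("truncated trajectory in ", path, ": ", msg,
           "; last valid frame index = ", fi - 1L, call. = FALSE)
    }
    if (pos + 1L > n_total) fail("missing atom-count line")
    title <- lines[pos]
    n_atoms <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(n_atoms) || n_atoms <= 0) fail("unreadable atom count")
    if (pos + 1L + n_atoms + 1L > n_total) fail("incomplete frame")
    at <- lines[(pos + 2L):(pos + 1L + n_atoms)]
    xyz <- cbind(suppressWarnings(as.numeric(substr(at, 21, 28))),
                 suppressWarnings(as.numeric(substr(at, 29, 36))),
                 suppressWarnings(as.numeric(substr(at, 37, 44))))
    if (anyNA(xyz)) fail("unreadable coordinates")
    boxv <- suppressWarnings(as.numeric(strsplit(
      trimws(lines[pos + 2L + n_atoms]), "\\s+")[[1]]))
    if (length(boxv) < 3 || anyNA(boxv[1:3])) fail("unreadable box line")
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time_ps <- if (length(tm) == 1) as.numeric(sub("t=\\s*", "", tm)) else NA
    frames[[fi]] <- list(
      resnames = trimws(substr(at, 6, 10)),
      atom_names = trimws(substr(at, 11, 15)),
      xyz = xyz * 10,                        # nm -> Angstrom
      box = boxv[1:3] * 10,
      time = time_ps)
    pos <- pos + 2L + n_atoms + 1L
  }
  if (length(frames) == 0) stop("no frames in ", path, call. = FALSE)
  frames
}

#' Load a trajectory from GRO coordinate/trajectory files
#'
#' Reads a GRO coordinate file (topology-with-coordinates) and, optionally, a
#' multi-frame GRO trajectory stream; frame times are taken from the `t=` tag
#' on each frame title (falling back to a 1 ps spacing). Units are normalised
#' to Angstrom/ps on load. Coordinates are not wrapped; each analysis applies
#' its own periodic-image policy.
#'
#' @param topology_path GRO file defining atom names and counts.
#' @param trajectory_path optional multi-frame GRO stream; defaults to the
#'   frames of `topology_path`.
#' @param lipid_spec a [lipid_topology()].
#' @return a [membrane_trajectory()].
#' @export
load_trajectory <- function(topology_path, trajectory_path = NULL, lipid_spec) {
  if (!file.exists(topology_path)) {
    stop("no such file: ", topology_path, call. = FALSE)
  }
  top_frames <- parse_gro_frames(readLines(topology_path), topology_path)
  ref <- top_frames[[1]]
  frames <- if (is.null(trajectory_path)) top_frames else {
    if (!file.exists(trajectory_path)) {
      stop("no such file: ", trajectory_path, call. = FALSE)
    }
    parse_gro_frames(readLines(trajectory_path), trajectory_path)
  }
  n_atoms <- nrow(ref$xyz)
  is_lipid <- ref$resnames == lipid_spec$lipid_name
  n_lipid_atoms <- sum(is_lipid)
  if (n_lipid_atoms %% lipid_spec$atoms_per_lipid != 0 || n_lipid_atoms == 0) {
    stop("topology error: ", n_lipid_atoms, " atoms of residue ",
         lipid_spec$lipid_name, " is not a multiple of ",
         lipid_spec$atoms_per_lipid, call. = FALSE)
  }
  n_lipids <- n_lipid_atoms %/% lipid_spec$atoms_per_lipid
  got <- ref$atom_names[seq_len(lipid_spec$atoms_per_lipid)]
  if (!identical(got, lipid_spec$atom_names)) {
    stop("topology error: atom names of first lipid do not match lipid_spec",
         call. = FALSE)
  }
  n_frames <- length(frames)
  coords <- array(NA_real_, c(n_atoms, 3, n_frames))
  box <- matrix(NA_real_, n_frames, 3)
  times <- numeric(n_frames)
  for (i in seq_len(n_frames)) {
    f <- frames[[i]]
    if (nrow(f$xyz) != n_atoms) {
      stop("truncated trajectory: frame ", i, " has ", nrow(f$xyz),
           " atoms, expected ", n_atoms, "; last valid frame index = ", i - 1L,
           call. = FALSE)
    }
    coords[, , i] <- f$xyz
    box[i, ] <- f$box
    times[i] <- if (is.na(f$time)) i - 1 else f$time
  }
  membrane_trajectory(coords, box, times, lipid_spec, n_lipids,
                      ref$atom_names, ref$resnames)
}

#' Write a trajectory as (multi-frame) GRO text
#'
#' @param traj a `mem_traj`.
#' @param path output file.
#' @param frames frame indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path, frames = seq_len(traj$n_frames)) {
  con <- file(path, "w")
  on.exit(close(con))
  resid <- traj$molecule_index
  resid[is.na(resid)] <- traj$n_lipids +
    cumsum(is.na(traj$molecule_index))[is.na(traj$molecule_index)]
  for (fi in frames) {
    xyz <- traj$coords[, , fi, drop = TRUE] / 10
    writeLines(sprintf("synthetic lamellar system t= %.3f", traj$times[fi]), con)
    writeLines(sprintf("%d", traj$n_atoms), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resid %% 100000L, traj$resnames, traj$atom_names,
                       seq_len(traj$n_atoms) %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[fi, 1] / 10,
                       traj$box[fi, 2] / 10, traj$box[fi, 3] / 10), con)
  }
  invisible(path)
}

## ---- window selection and leaflets ------------------------------------

#' Restrict a trajectory to a time window
#'
#' Keeps frames with `start_time <= t <= end_time` (inclusive), preserving
#' order. The production-analysis convention is to analyse only the final
#' part of a run (e.g. the last 500 ns); this is the tool for that cut.
#'
#' @param traj a `mem_traj`.
#' @param start_time,end_time window bounds in ps.
#' @return a `mem_traj` with the selected frames.
#' @export
select_window <- function(traj, start_time, end_time) {
  if (start_time >= end_time) stop("start_time must be < end_time", call. = FALSE)
  keep <- which(traj$times >= start_time & traj$times <= end_time)
  if (length(keep) == 0) stop("empty analysis window", call. = FALSE)
  membrane_trajectory(traj$coords[, , keep, drop = FALSE],
                      traj$box[keep, , drop = FALSE], traj$times[keep],
                      traj$topology, traj$n_lipids, traj$atom_names,
                      traj$resnames)
}

#' Assign lipids to leaflets by marker-atom z bands
#'
#' Lipids are partitioned per frame by a one-dimensional clustering of the
#' z coordinate of a marker atom (by convention the primary hydroxyl oxygen
#' O1) into `n_leaflets` bands; planar lamellar systems separate into clean
#' bands, so the partition is computed deterministically from the
#' `n_leaflets - 1` largest gaps of the sorted marker coordinates (the
#' converged 1D k-means solution for band-separated data). The two bands with
#' extreme mean z are flagged as outer (water-facing).
#'
#' @param traj a `mem_traj`.
#' @param n_leaflets 2 (single bilayer) or 4 (stacked / interdigitated).
#' @param marker_atom marker atom name, default `"O1"`.
#' @param min_gap minimal z separation (Angstrom) between adjacent bands
#'   below which the geometry is declared degenerate.
#' @return object of class `leaflet_assignment`: `leaflet` (n_lipids x
#'   n_frames integer matrix, 1 = lowest band), `outer` (logical per leaflet),
#'   `n_leaflets`.
#' @export
assign_leaflets <- function(traj, n_leaflets = 2, marker_atom = "O1",
                            min_gap = 2) {
  if (!n_leaflets %in% c(2L, 4L)) stop("n_leaflets must be 2 or 4", call. = FALSE)
  idx <- atom_indices(traj, marker_atom)
  leaflet <- matrix(NA_integer_, traj$n_lipids, traj$n_frames)
  for (fi in seq_len(traj$n_frames)) {
    z <- traj$coords[idx, 3, fi]
    if (length(unique(round(z, 6))) < n_leaflets) {
      stop("degenerate geometry: fewer distinct marker z-bands than leaflets",
           call. = FALSE)
    }
    o <- order(z)
    gaps <- diff(z[o])
    cut_at <- sort(order(gaps, decreasing = TRUE)[seq_len(n_leaflets - 1L)])
    if (min(gaps[cut_at]) < min_gap) {
      stop("degenerate geometry: marker z-bands separated by < ", min_gap,
           " A", call. = FALSE)
    }
    band <- integer(traj$n_lipids)
    band[o] <- findInterval(seq_along(o), c(1, cut_at + 1)) # 1..n along z
    leaflet[, fi] <- band
  }
  outer <- rep(FALSE, n_leaflets)
  outer[c(1L, n_leaflets)] <- TRUE
  structure(list(leaflet = leaflet, outer = outer, n_leaflets = n_leaflets),
            class = "leaflet_assignment")
}

#' @export
print.leaflet_assignment <- function(x, ...) {
  pops <- table(x$leaflet[, 1])
  cat("<leaflet_assignment> ", x$n_leaflets, " leaflets; populations (frame 1): ",
      paste(pops, collapse = "/"), "; outer: ",
      paste(which(x$outer), collapse = ","), "\n", sep = "")
  invisible(x)
}
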