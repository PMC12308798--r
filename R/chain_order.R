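## Hydrocarbon-tail statistics: deuterium order parameters (with
## ideal-geometry hydrogen reconstruction), tilt / splay / head-tail angle
## distributions, orientational autocorrelation, and in-plane RDFs.

TETRA_HALF <- (109.47 / 2) * pi / 180   # half the ideal H-C-H angle

## Unit C-H direction pair for every methylene of one carbon triple,
## vectorised over lipids: a = C[i-1]-C[i], b = C[i+1]-C[i] (n x 3 each).
methylene_h_dirs <- function(a, b) {
  norm_rows <- function(m) m / sqrt(rowSums(m^2))
  ah <- norm_rows(a); bh <- norm_rows(b)
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  ## collinear neighbours leave the H plane underdetermined: fall back to an
  ## arbitrary perpendicular of the local axis (still a valid H frame)
  deg <- sqrt(rowSums(cr^2)) < 1e-10
  if (any(deg)) {
    ref <- cbind(1, 0, 0)[rep(1, sum(deg)), , drop = FALSE]
    near_x <- abs(ah[deg, 1]) > 0.9
    ref[near_x, ] <- rep(c(0, 1, 0), each = sum(near_x))
    cr[deg, ] <- cbind(ah[deg, 2] * ref[, 3] - ah[deg, 3] * ref[, 2],
                       ah[deg, 3] * ref[, 1] - ah[deg, 1] * ref[, 3],
                       ah[deg, 1] * ref[, 2] - ah[deg, 2] * ref[, 1])
  }
  v <- norm_rows(cr)
  s <- -(ah + bh)
  u <- matrix(0, nrow(a), 3)
  small <- sqrt(rowSums(s^2)) < 1e-10
  u[!small, ] <- norm_rows(s[!small, , drop = FALSE])  # bisector, away from chain
  if (any(small)) {
    ## straight-angle case: bisector direction from the perpendicular frame
    w <- cbind(v[small, 2] * ah[small, 3] - v[small, 3] * ah[small, 2],
               v[small, 3] * ah[small, 1] - v[small, 1] * ah[small, 3],
               v[small, 1] * ah[small, 2] - v[small, 2] * ah[small, 1])
    u[small, ] <- norm_rows(w)
  }
  list(h1 = cos(TETRA_HALF) * u + sin(TETRA_HALF) * v,
       h2 = cos(TETRA_HALF) * u - sin(TETRA_HALF) * v)
}

#' Deuterium order parameter profile
#'
#' For every methylene carbon of each tail, the two hydrogen directions are
#' reconstructed from the neighbouring carbons assuming ideal tetrahedral
#' geometry (bisector construction, H-C-H plane perpendicular to the
#' C(i-1)-C(i+1) axis), and `S_CD = (3 <cos^2 theta> - 1) / 2` is averaged
#' over hydrogens, lipids and frames within each of `n_blocks` contiguous
#' frame blocks; the block mean and standard deviation are reported per
#' carbon. Terminal methyl carbons are excluded. The bilayer normal is the
#' z axis.
#'
#' @param traj a `mem_traj`.
#' @param tails named list of ordered carbon-name vectors; default the
#'   topology's two tails.
#' @param n_blocks number of frame blocks (default 5; capped at `n_frames`).
#' @return data frame (class `order_profile`): `tail`, `carbon`, `index`,
#'   `scd`, `scd_sd`.
#' @export
scd_profile <- function(traj, tails = NULL, n_blocks = 5) {
  tails <- tails %||% list(tail1 = traj$topology$tail1_atoms,
                           tail2 = traj$topology$tail2_atoms)
  tails <- tails[lengths(tails) > 0]
  for (tl in tails) if (length(tl) < 3) {
    stop("chain too short for hydrogen reconstruction (need >= 3 carbons)",
         call. = FALSE)
  }
  n_blocks <- min(n_blocks, traj$n_frames)
  block_of <- ceiling(seq_len(traj$n_frames) / (traj$n_frames / n_blocks))
  out <- list()
  for (tn in names(tails)) {
    carbons <- tails[[tn]]
    idx <- matrix(vapply(carbons, function(nm) atom_indices(traj, nm),
                         integer(traj$n_lipids)), nrow = traj$n_lipids)
    nC <- length(carbons)
    acc <- matrix(0, nC - 2, n_blocks)   # sum of cos^2 per (methylene, block)
    cnt <- matrix(0, nC - 2, n_blocks)
    for (fi in seq_len(traj$n_frames)) {
      xyz <- traj$coords[, , fi, drop = TRUE]
      b <- block_of[fi]
      for (ci in 2:(nC - 1)) {
        A <- xyz[idx[, ci - 1], , drop = FALSE] - xyz[idx[, ci], , drop = FALSE]
        B <- xyz[idx[, ci + 1], , drop = FALSE] - xyz[idx[, ci], , drop = FALSE]
        h <- methylene_h_dirs(A, B)
        acc[ci - 1, b] <- acc[ci - 1, b] + sum(h$h1[, 3]^2) + sum(h$h2[, 3]^2)
        cnt[ci - 1, b] <- cnt[ci - 1, b] + 2 * nrow(A)
      }
    }
    scd_blocks <- (3 * acc / cnt - 1) / 2
    out[[tn]] <- data.frame(
      tail = tn, carbon = carbons[2:(nC - 1)], index = 2:(nC - 1),
      scd = rowMeans(scd_blocks),
      scd_sd = apply(scd_blocks, 1, function(r) stats::sd(r) %||% 0))
  }
  structure(do.call(rbind, c(out, make.row.names = FALSE)),
            class = c("order_profile", "data.frame"), n_blocks = n_blocks)
}

## shared histogram helper for angle distributions
angle_histogram <- function(angles, breaks, tag) {
  h <- graphics::hist(angles, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  structure(data.frame(angle = h$mids, prob = p),
            class = c("angle_distribution", "data.frame"),
            mode = h$mids[which.max(p)], tag = tag, n = length(angles))
}

#' Tail tilt-angle distribution
#'
#' Angle between each tail vector (terminal-to-first carbon, pointing toward
#' the headgroup) and its leaflet's outward normal, folded to \[0, 90\]
#' degrees and binned.
#'
#' @param traj a `mem_traj`.
#' @param leaflets a [assign_leaflets()] result (leaflet 1 = lowest band;
#'   outward normals alternate -z/+z up the stack).
#' @param vectors named list of `c(from, to)` atom-name pairs; default
#'   `list(tail1 = c("C20","C7"), tail2 = c("C35","C21"))`.
#' @param bin_width degrees (default 0.5).
#' @return named list of `angle_distribution` data frames (prob per bin,
#'   `mode` attribute in degrees).
#' @export
tilt_distribution <- function(traj, leaflets,
                              vectors = list(tail1 = c("C20", "C7"),
                                             tail2 = c("C35", "C21")),
                              bin_width = 0.5) {
  out <- list()
  for (vn in names(vectors)) {
    from_i <- atom_indices(traj, vectors[[vn]][1])
    to_i <- atom_indices(traj, vectors[[vn]][2])
    ang <- numeric(0)
    for (fi in seq_len(traj$n_frames)) {
      v <- matrix(traj$coords[to_i, , fi], ncol = 3) -
        matrix(traj$coords[from_i, , fi], ncol = 3)
      nrm <- sqrt(rowSums(v^2))
      if (any(nrm == 0)) stop("zero-length tail vector", call. = FALSE)
      ## outward normal: -z for odd leaflets, +z for even (stack order)
      sign_n <- ifelse(leaflets$leaflet[, fi] %% 2 == 0, 1, -1)
      ct <- v[, 3] * sign_n / nrm
      a <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
      ang <- c(ang, pmin(a, 180 - a))
    }
    out[[vn]] <- angle_histogram(ang, seq(0, 90, by = bin_width),
                                 tag = paste0("tilt:", vn))
  }
  out
}

#' Splay-angle distribution
#'
#' Vertex angle at the branching carbon between vectors to one atom on each
#' tail: splay 1 uses the second tail carbons (C9, C22), splay 2 the
#' terminal carbons (C20, C35).
#'
#' @param traj a `mem_traj`.
#' @param triple `c(atomA, vertex, atomB)`; default `c("C9","C5","C22")`.
#' @param bin_width degrees (default 1).
#' @return an `angle_distribution` data frame over \[0, 180\] degrees.
#' @export
splay_distribution <- function(traj, triple = c("C9", "C5", "C22"),
                               bin_width = 1) {
  a_i <- atom_indices(traj, triple[1])
  v_i <- atom_indices(traj, triple[2])
  b_i <- atom_indices(traj, triple[3])
  ang <- numeric(0)
  for (fi in seq_len(traj$n_frames)) {
    va <- matrix(traj$coords[a_i, , fi], ncol = 3) -
      matrix(traj$coords[v_i, , fi], ncol = 3)
    vb <- matrix(traj$coords[b_i, , fi], ncol = 3) -
      matrix(traj$coords[v_i, , fi], ncol = 3)
    na_ <- sqrt(rowSums(va^2)); nb <- sqrt(rowSums(vb^2))
    if (any(na_ == 0 | nb == 0)) {
      stop("coincident atoms in splay triple", call. = FALSE)
    }
    ct <- rowSums(va * vb) / (na_ * nb)
    ang <- c(ang, acos(pmin(1, pmax(-1, ct))) * 180 / pi)
  }
  angle_histogram(ang, seq(0, 180, by = bin_width),
                  tag = paste(triple, collapse = "-"))
}

#' Head-to-tail angle distribution
#'
#' Angle between the headgroup vector (C1 to C3) and each tail vector from
#' the branching carbon to the terminal carbon (C5-C20, C5-C35), unfolded
#' over \[0, 180\] degrees.
#'
#' @param traj a `mem_traj`.
#' @param head_vector `c(from, to)`; default `c("C1","C3")`.
#' @param tail_vectors named list of `c(from, to)`; default
#'   `list(tail1 = c("C5","C20"), tail2 = c("C5","C35"))`.
#' @param bin_width degrees (default 1).
#' @return named list of `angle_distribution` data frames.
#' @export
head_tail_angle <- function(traj, head_vector = c("C1", "C3"),
                            tail_vectors = list(tail1 = c("C5", "C20"),
                                                tail2 = c("C5", "C35")),
                            bin_width = 1) {
  hf <- atom_indices(traj, head_vector[1])
  ht <- atom_indices(traj, head_vector[2])
  out <- list()
  for (vn in names(tail_vectors)) {
    tf <- atom_indices(traj, tail_vectors[[vn]][1])
    tt <- atom_indices(traj, tail_vectors[[vn]][2])
    ang <- numeric(0)
    for (fi in seq_len(traj$n_frames)) {
      vh <- matrix(traj$coords[ht, , fi], ncol = 3) -
        matrix(traj$coords[hf, , fi], ncol = 3)
      vt <- matrix(traj$coords[tt, , fi], ncol = 3) -
        matrix(traj$coords[tf, , fi], ncol = 3)
      nh <- sqrt(rowSums(vh^2)); nt <- sqrt(rowSums(vt^2))
      if (any(nh == 0 | nt == 0)) stop("zero-length vector", call. = FALSE)
      ct <- rowSums(vh * vt) / (nh * nt)
      ang <- c(ang, acos(pmin(1, pmax(-1, ct))) * 180 / pi)
    }
    out[[vn]] <- angle_histogram(ang, seq(0, 180, by = bin_width),
                                 tag = paste0("head_tail:", vn))
  }
  out
}

#' Orientational autocorrelation of a molecular vector
#'
#' `C(t) = <u(tau) . u(tau + t)>` over all lipids and all time origins
#' (P1 of the unit vector), normalised so `C(0) = 1`. Lags extend to half
#' the window by default.
#'
#' @param traj a `mem_traj` (>= 2 frames).
#' @param vector_spec `c(from, to)` atom names.
#' @param max_lag maximal lag in frames; default `floor((n_frames - 1) / 2)`.
#' @return data frame (class `acf_series`): `lag` (ps), `acf`.
#' @export
vector_acf <- function(traj, vector_spec, max_lag = NULL) {
  if (traj$n_frames < 2) stop("need >= 2 frames", call. = FALSE)
  from_i <- atom_indices(traj, vector_spec[1])
  to_i <- atom_indices(traj, vector_spec[2])
  F <- traj$n_frames
  max_lag <- max_lag %||% floor((F - 1) / 2)
  max_lag <- min(max_lag, F - 1)
  ## unit-vector components as frames x lipids matrices
  ux <- uy <- uz <- matrix(0, F, traj$n_lipids)
  for (fi in seq_len(F)) {
    v <- matrix(traj$coords[to_i, , fi], ncol = 3) -
      matrix(traj$coords[from_i, , fi], ncol = 3)
    nrm <- sqrt(rowSums(v^2))
    ux[fi, ] <- v[, 1] / nrm; uy[fi, ] <- v[, 2] / nrm; uz[fi, ] <- v[, 3] / nrm
  }
  acf <- vapply(0:max_lag, function(L) {
    i1 <- seq_len(F - L); i2 <- i1 + L
    mean(ux[i1, ] * ux[i2, ] + uy[i1, ] * uy[i2, ] + uz[i1, ] * uz[i2, ])
  }, numeric(1))
  acf <- acf / acf[1]
  dt <- if (F > 1) stats::median(diff(traj$times)) else 1
  structure(data.frame(lag = (0:max_lag) * dt, acf = acf),
            class = c("acf_series", "data.frame"),
            normalization = "P1", vector = paste(vector_spec, collapse = "->"))
}

#' In-plane radial distribution function
#'
#' 2D pair distribution of per-lipid centres of mass in the xy plane,
#' computed per leaflet with the minimum-image convention, normalised by the
#' ideal-gas annulus density, and averaged over leaflets and frames.
#'
#' @param traj a `mem_traj`.
#' @param leaflets a [assign_leaflets()] result.
#' @param com_atoms atom names defining the per-lipid COM (reference and
#'   selection alike), e.g. tail carbons `C7..C35` or the headgroup.
#' @param r_max maximal distance (must be `<= min(Lx, Ly) / 2`).
#' @param n_bins number of radial bins.
#' @param which_leaflets leaflet ids to include (default the outer ones).
#' @return data frame (class `rdf2d`): `r`, `g`.
#' @export
rdf_2d <- function(traj, leaflets, com_atoms, r_max, n_bins = 100,
                   which_leaflets = which(leaflets$outer)) {
  if (r_max > min(traj$box[, 1:2]) / 2) {
    stop("r_max exceeds half the smallest lateral box edge", call. = FALSE)
  }
  edges <- seq(0, r_max, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  norm <- numeric(n_bins)
  for (fi in seq_len(traj$n_frames)) {
    com <- lipid_com(traj, fi, com_atoms)
    Lx <- traj$box[fi, 1]; Ly <- traj$box[fi, 2]
    for (li in which_leaflets) {
      sel <- which(leaflets$leaflet[, fi] == li)
      n <- length(sel)
      if (n < 2) next
      dx <- outer(com[sel, 1], com[sel, 1], `-`)
      dy <- outer(com[sel, 2], com[sel, 2], `-`)
      dx <- min_image(dx, Lx); dy <- min_image(dy, Ly)
      d <- sqrt(dx^2 + dy^2)[upper.tri(matrix(0, n, n))]
      h <- graphics::hist(d[d <= r_max], breaks = edges, plot = FALSE)$counts
      counts <- counts + 2 * h                        # both orderings
      rho <- (n - 1) / (Lx * Ly)
      ann <- pi * (edges[-1]^2 - edges[-(n_bins + 1)]^2)
      norm <- norm + n * rho * ann
    }
  }
  structure(data.frame(r = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                       g = ifelse(norm > 0, counts / norm, 0)),
            class = c("rdf2d", "data.frame"))
}
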