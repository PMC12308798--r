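## Shared small helpers: geometry, periodic images, seed fan-out.

#' @useDynLib lamellr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unit vector
#' @noRd
unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector", call. = FALSE)
  v / n
}

#' Angle between two vectors in degrees, in [0, 180]
#' @noRd
angle_deg <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  acos(min(1, max(-1, ca))) * 180 / pi
}

#' Rotation matrix for angle `theta` (radians) about unit axis `k`
#' (Rodrigues formula).
#' @noRd
rotation_matrix <- function(k, theta) {
  k <- unit(k)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Any unit vector perpendicular to `v`
#' @noRd
perp_unit <- function(v) {
  v <- unit(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(pracma_cross(ref, v))
}

#' Cross product (kept local; avoids pulling in a package for one line)
#' @noRd
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Minimum-image displacement components for one periodic dimension
#' @noRd
min_image <- function(dx, L) dx - L * round(dx / L)

#' Deterministic per-stage seeds fanned out from one master seed.
#'
#' Offsets keep stages statistically independent while the whole pipeline
#' stays reproducible from a single integer. Values stay below 2^31.
#' @param seed master seed (integer)
#' @param stage stage name
#' @return integer seed
#' @export
stage_seed <- function(seed, stage = c("generator", "embedding", "clustering",
                                       "noise", "fit")) {
  stage <- match.arg(stage)
  off <- c(generator = 101L, embedding = 202L, clustering = 303L,
           noise = 404L, fit = 505L)[[stage]]
  (as.integer(seed) * 1009L + off) %% 2147483647L
}

#' Electron count for an atom name (first alphabetic character read as the
#' element; sufficient for C/H/O/N/P lipid systems).
#' @noRd
electrons_for_name <- function(names) {
  el <- toupper(substr(gsub("^[0-9]+", "", names), 1, 1))
  z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)
  out <- unname(z[el])
  if (anyNA(out)) stop("unknown element for atom name(s): ",
                       paste(unique(names[is.na(out)]), collapse = ", "),
                       call. = FALSE)
  out
}
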