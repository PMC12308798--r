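## Structural similarity of fingerprint histograms.

#' Structural similarity index of two 2D histograms
#'
#' Mean local SSIM over sliding uniform windows (valid region), with the
#' standard luminance/contrast/structure terms and stabilisation constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` where `L` is the dynamic range.
#' Symmetric in its arguments; `ssim_score(x, x) = 1`.
#'
#' @param h1,h2 numeric matrices of identical shape.
#' @param window odd window size (default 7).
#' @param dynamic_range `L`; default the data range of the two inputs.
#' @return similarity in \[-1, 1\].
#' @export
ssim_score <- function(h1, h2, window = 7, dynamic_range = NULL) {
  if (!all(dim(h1) == dim(h2))) {
    stop("histogram shape mismatch: ", paste(dim(h1), collapse = "x"),
         " vs ", paste(dim(h2), collapse = "x"), call. = FALSE)
  }
  if (window %% 2 != 1 || window < 3) stop("window must be odd >= 3",
                                           call. = FALSE)
  if (any(dim(h1) < window)) stop("window larger than histogram", call. = FALSE)
  L <- dynamic_range %||% (max(h1, h2) - min(h1, h2))
  if (L <= 0) return(1)
  .ssim_pair_cpp(unclass(h1), unclass(h2), as.integer(window), L)
}

#' Pairwise SSIM similarity matrix
#'
#' Computes each pair once (the matrix is symmetric with unit diagonal).
#' One dynamic range, the global data range of all histograms, is used for
#' every pair so scores are comparable.
#'
#' @param histograms a 3D array `nr x na x n` (e.g. [compute_g3_all()]) or a
#'   list of equally shaped matrices.
#' @param window odd window size (default 7).
#' @param dynamic_range optional override of the global data range.
#' @return `n x n` symmetric similarity matrix.
#' @export
build_similarity_matrix <- function(histograms, window = 7,
                                    dynamic_range = NULL) {
  if (is.list(histograms)) {
    dims <- dim(histograms[[1]])
    histograms <- array(unlist(histograms), c(dims, length(histograms)))
  }
  stopifnot(length(dim(histograms)) == 3)
  n <- dim(histograms)[3]
  if (n < 2) stop("need >= 2 histograms", call. = FALSE)
  nr <- dim(histograms)[1]; nc <- dim(histograms)[2]
  L <- dynamic_range %||% (max(histograms) - min(histograms))
  if (L <= 0) return(matrix(1, n, n))
  H <- matrix(as.numeric(histograms), nr * nc, n)
  .ssim_matrix_cpp(H, nr, nc, as.integer(window), L)
}
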