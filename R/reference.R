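## Published reference values for the MMG lamellar systems, shipped as
## plain-text tables. These are inputs for cross-study arithmetic (area
## expansion on interdigitation, stack thinning) and sources of realistic
## generator / fit-recovery parameters; the package never tunes itself
## against them at run time.

#' Reference membrane properties of the MMG systems
#'
#' Area per lipid (box method) and electron-density peak-to-peak membrane /
#' bilayer thickness, with standard deviations, for MMG-1 and MMG-6 in the
#' single-bilayer, double-bilayer and interdigitated configurations.
#'
#' @return data frame with columns `system`, `analog`, `apl_xy`,
#'   `apl_xy_sd`, `membrane_thickness`, `membrane_thickness_sd`,
#'   `bilayer_thickness`, `bilayer_thickness_sd`.
#' @export
reference_membrane_properties <- function() {
  utils::read.delim(system.file("extdata", "membrane_properties_reference.tsv",
                                package = "lamellr"))
}

#' Reference rotational fit parameters of the glycerol vector
#'
#' Double-exponential characteristic times (ns) and amplitudes of the
#' glycerol C1-C3 rotational autocorrelation per system and stereoisomer.
#'
#' @return data frame with columns `system`, `analog`, `stereoisomer`,
#'   `tau1_ns`, `a1`, `tau2_ns`, `a2`.
#' @export
reference_rotational_fits <- function() {
  utils::read.delim(system.file("extdata", "rotational_fits_reference.tsv",
                                package = "lamellr"))
}

#' Cross-system arithmetic on the reference membrane table
#'
#' The two headline contrasts: the lateral area expansion on
#' interdigitation (interdigitated over double-bilayer `APL_xy`) and the
#' membrane thinning of MMG-6 relative to MMG-1 in the noninterdigitated
#' configurations.
#'
#' @return list: `apl_expansion` (named per analog),
#'   `thinning` (named per noninterdigitated system, Angstrom).
#' @export
reference_contrasts <- function() {
  m <- reference_membrane_properties()
  g <- function(sys, an, col) m[m$system == sys & m$analog == an, col]
  list(
    apl_expansion = c(
      `MMG-1` = g("interdigitated", "MMG-1", "apl_xy") /
        g("double_bilayer", "MMG-1", "apl_xy"),
      `MMG-6` = g("interdigitated", "MMG-6", "apl_xy") /
        g("double_bilayer", "MMG-6", "apl_xy")),
    thinning = c(
      single_bilayer = g("single_bilayer", "MMG-1", "membrane_thickness") -
        g("single_bilayer", "MMG-6", "membrane_thickness"),
      double_bilayer = g("double_bilayer", "MMG-1", "membrane_thickness") -
        g("double_bilayer", "MMG-6", "membrane_thickness")))
}
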