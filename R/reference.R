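# Published group-level class statistics used to calibrate the simulator and
# for desk-scale consistency checks.

#' Reference class-level statistics from the lipophagy mouse study
#'
#' Group-level summary statistics of the hepatic complex-lipid panel of a
#' congenic mouse model of impaired lipophagy (control genotype "IRG" with
#' intact lipophagy vs. "dIRG" with suppressed Ifgga2 and impaired lipophagy;
#' 16-h-fasted animals, n = 7 per group). One row per detected lipid class:
#' number of detected species, group mean and SD of the class concentration
#' (nmol per mg tissue) and of the class mol% composition, and the counts of
#' species significantly down-/up-regulated in the impaired-lipophagy group
#' on each scale.
#'
#' These printed group-level values are the calibration source for
#' [effect_config()] defaults (class means, coefficients of variation and
#' case/control multipliers). The underlying per-sample data are not publicly
#' deposited, so simulated panels reproduce these class-level moments, not
#' the raw measurements.
#'
#' @param path Optional path to an alternative TSV in the same layout;
#'   defaults to the table shipped with the package.
#' @return A tibble with 14 rows and the columns described above
#'   (`*_control` = intact lipophagy, `*_case` = impaired lipophagy).
#' @export
#' @examples
#' ref <- class_reference()
#' sum(ref$n_species)  # detected species in the panel
class_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "class_reference.tsv", package = "lipidpanel",
                        mustWork = TRUE)
  }
  ref <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(ref$lipid_class %in% lipid_classes()))
  ref
}
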