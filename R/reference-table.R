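#' Published reference agreement table
#'
#' The per-artery agreement summary published by the clinical TCCD
#' validation study of the patient-specific simulation approach this package
#' re-implements (n = 53 stroke/TIA patients): for each of the nine arterial
#' sites and each velocity type, the reported ICC with 95% CI, the two
#' modalities' means and SDs (cm/s), and the printed mean difference (cm/s
#' and percent of the simulation mean). Used to pin down the reporting
#' conventions (difference sign, percent denominator, overall averaging) and
#' as worked-example input; it is reference data, not output of this
#' package.
#'
#' @return A tibble with columns `phase`, `artery`, `side`, `icc`,
#'   `icc_ci_low`, `icc_ci_high`, `mean_sim`, `sd_sim`, `mean_meas`,
#'   `sd_meas`, `mean_diff_cms`, `pct_diff`.
#' @export
#' @examples
#' ref <- reference_agreement_table()
#' overall_difference(ref[ref$phase == "PSV", ])
reference_agreement_table <- function() {
  as_tibble(utils::read.csv(
    system.file("extdata", "tccd_validation_reference.csv",
                package = "cowflow"),
    stringsAsFactors = FALSE))
}
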