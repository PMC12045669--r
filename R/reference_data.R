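#' Reference ex vivo cohort tables
#'
#' Per-specimen measurements of the six-thorax ex vivo leporine cohort that
#' motivates this package's defaults, shipped as plain CSV under
#' `inst/extdata/`:
#' * `"lung_function"`: delta P (cmH2O) and compliance (mL/cmH2O) per
#'   specimen;
#' * `"enhanced_quantification"`: contrast-enhanced volume (mL), mean
#'   post-administration T1 (ms), mean Gd3+ concentration (mM) and Gd3+
#'   amount (umol) per specimen;
#' * `"distribution_fractions"`: PDF and PVF (percent) per specimen;
#' * `"region_volume_summaries"`: cohort mean and SD (mL) of the TLV, PER
#'   and CER volumes.
#'
#' These tables are the inputs for the cohort-statistics checks and for
#' building phantom cohorts with matching per-specimen targets.
#'
#' @param table One of `"lung_function"`, `"enhanced_quantification"`,
#'   `"distribution_fractions"`, `"region_volume_summaries"`.
#' @return A data.frame.
#' @export
reference_cohort <- function(table = c("lung_function",
                                       "enhanced_quantification",
                                       "distribution_fractions",
                                       "region_volume_summaries")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0(table, ".csv"),
                      package = "lungsurf", mustWork = TRUE)
  utils::read.csv(path)
}
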