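#' Run the full quantification pipeline for one specimen
#'
#' The ordered chain of the method: calibrate (A, R1_pre) from the
#' pre-administration flip-angle series in a solution-free distal-lung ROI,
#' invert the post-administration volume pixel-wise into an R1 map, convert
#' to Gd3+ concentration via the relaxivity, and summarize the regional
#' distribution.
#'
#' Inputs can come from a [build_phantom()] dataset (pass it as
#' `dataset`) or be supplied individually (e.g. volumes read with
#' [read_volume()] and labels with [ingest_labels()]).
#'
#' @param dataset Optional `phantom_dataset`; supplies the volumes and, by
#'   default, the truth labels.
#' @param pre_volumes List of pre-administration [volume3d()] volumes, one
#'   per flip angle of `params`.
#' @param post_volume Post-administration [volume3d()] at
#'   `params$post_flip_angle`.
#' @param labels [region_labels()] partition of the grid. Defaults to the
#'   dataset's truth labels when `dataset` is given.
#' @param params An [acquisition_params()].
#' @param calib_roi Logical calibration ROI; defaults to the un-enhanced
#'   lung (label "TLV-only"), the solution-free distal region.
#' @param analysis_mask Logical mask for the R1/concentration maps;
#'   defaults to TLV.
#' @param clamp_negative Clamp negative concentrations for amounts
#'   (default TRUE).
#' @param specimen Identifier carried into the report.
#' @return A list of class `specimen_run` with fields `report`
#'   ([specimen_report()]), `calibration`, `r1_post`
#'   (an `r1_map`), `concentration` (a `concentration_result`) and
#'   `labels`.
#' @export
run_specimen <- function(dataset = NULL, pre_volumes = NULL,
                         post_volume = NULL, labels = NULL,
                         params = acquisition_params(),
                         calib_roi = NULL, analysis_mask = NULL,
                         clamp_negative = TRUE,
                         specimen = NA_character_) {
  if (!is.null(dataset)) {
    stopifnot(inherits(dataset, "phantom_dataset"))
    if (is.null(pre_volumes)) pre_volumes <- dataset$pre_volumes
    if (is.null(post_volume)) post_volume <- dataset$post_volume
    if (is.null(labels)) labels <- dataset$truth_labels
    params <- dataset$params
  }
  if (is.null(pre_volumes) || is.null(post_volume))
    stop("missing input: both `pre_volumes` and `post_volume` are required")
  if (is.null(labels))
    stop("missing input: `labels` (or a dataset with truth labels) required")
  stopifnot(inherits(post_volume, "volume3d"),
            inherits(labels, "region_labels"))
  if (length(pre_volumes) != length(params$flip_angles))
    stop("flip-angle count of the pre series (", length(pre_volumes),
         ") does not match acquisition parameters (",
         length(params$flip_angles), ")")
  if (is.null(calib_roi)) calib_roi <- region_mask(labels, "TLV_only")
  if (is.null(analysis_mask)) analysis_mask <- region_mask(labels, "TLV")

  calib <- calibrate_from_volumes(pre_volumes, calib_roi, params)
  r1 <- r1_post_map(post_volume, calib, params, analysis_mask)
  conc <- concentration_map(r1, calib, params,
                            clamp_negative = clamp_negative)
  rep <- specimen_report(conc, labels, post_volume$spacing,
                         specimen = specimen)
  structure(list(report = rep, calibration = calib, r1_post = r1,
                 concentration = conc, labels = labels),
            class = "specimen_run")
}

#' Cohort summary tables over specimen reports
#'
#' Per-metric mean, sample SD (n-1 denominator) and coefficient of
#' variation across at least two specimens.
#'
#' @param reports List of [specimen_report()] objects (or `specimen_run`
#'   objects, whose reports are extracted).
#' @return A data.frame with columns `metric`, `n`, `mean`, `sd`,
#'   `cov_percent`.
#' @export
run_cohort <- function(reports) {
  reports <- lapply(reports, function(r)
    if (inherits(r, "specimen_run")) r$report else r)
  if (length(reports) < 2L)
    stop("need at least two specimens for a cohort SD/CoV")
  df <- reports_to_df(reports)
  metrics <- c("enhanced_volume_ml", "mean_t1_post_ms",
               "mean_concentration_mm", "gd_amount_umol", "pdf_percent",
               "pvf_percent", "tlv_ml", "per_ml", "cer_ml")
  rows <- lapply(metrics, function(m) {
    s <- summarize_cohort(df[[m]])
    data.frame(metric = m, n = s$n, mean = s$mean, sd = s$sd,
               cov_percent = s$cov)
  })
  do.call(rbind, rows)
}
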