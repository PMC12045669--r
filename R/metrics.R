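#' Peripheral distribution fraction (PDF)
#'
#' Fraction of the Gd3+ quantity found in the peripheral enhanced region,
#' out of the total quantity in the enhanced lung:
#' `100 * Q(PER) / (Q(PER) + Q(CER))`, in percent. Uses clamped
#' (non-negative) concentrations by default so the fraction stays in
#' [0, 100] under noise; set `clamp_negative = FALSE` in the concentration
#' result for signed amounts.
#'
#' @param conc A `concentration_result` from [concentration_map()].
#' @param labels A [region_labels()] object.
#' @param spacing Voxel spacing in mm.
#' @return PDF in percent.
#' @export
pdf_metric <- function(conc, labels, spacing) {
  q_per <- gd_amount(conc, labels, spacing, "PER")
  q_cer <- gd_amount(conc, labels, spacing, "CER")
  tot <- q_per + q_cer
  if (!is.finite(tot) || tot == 0)
    stop("total enhanced Gd amount is zero; PDF undefined")
  100 * q_per / tot
}

#' Peripheral volume fraction (PVF)
#'
#' Proportion of the total lung volume occupied by the peripheral enhanced
#' region: `100 * volume(PER) / volume(TLV)`, in percent. A pure volume
#' ratio -- independent of the concentration map.
#'
#' @param labels A [region_labels()] object.
#' @return PVF in percent.
#' @export
pvf_metric <- function(labels) {
  stopifnot(inherits(labels, "region_labels"))
  n_tlv <- sum(labels$labels >= 1L)
  if (n_tlv == 0) stop("TLV is empty; PVF undefined")
  100 * sum(labels$labels == 2L) / n_tlv
}

#' Slice-wise anatomical profile of Gd quantity or region area
#'
#' Collapses the volume slice by slice along an anatomical direction.
#' In `"quantity"` mode each slice value is the summed Gd3+ amount
#' (concentration x voxel volume, micromoles) of the region's voxels in
#' that slice, so the profile sums exactly to the region's total amount.
#' In `"area"` mode it is the in-plane mask area (voxel count x in-plane
#' voxel area, mm^2), so profile x slice thickness sums to the region
#' volume.
#'
#' @param conc A `concentration_result` (required for `"quantity"`; may be
#'   NULL for `"area"`).
#' @param labels A [region_labels()] object.
#' @param spacing Voxel spacing in mm.
#' @param axis Anatomical direction, e.g. `"ventral-dorsal"`,
#'   `"right-left"`, `"cranial-caudal"` (or the codes `"VD"`, `"RL"`,
#'   `"CC"`).
#' @param mode `"quantity"` or `"area"`.
#' @param regions Regions to profile; defaults to CER and PER for quantity,
#'   plus TLV for area.
#' @return A data.frame with columns `slice`, `position_mm` (slice-center
#'   coordinate along the axis) and one column per region.
#' @export
slice_profile <- function(conc = NULL, labels, spacing,
                          axis = "ventral-dorsal",
                          mode = c("quantity", "area"),
                          regions = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(labels, "region_labels"))
  k <- axis_index(labels$axes, axis)
  if (is.null(regions))
    regions <- if (mode == "quantity") c("CER", "PER") else
      c("CER", "PER", "TLV")
  d <- dim(labels$labels)
  n <- d[k]
  out <- data.frame(slice = seq_len(n),
                    position_mm = (seq_len(n) - 0.5) * spacing[k])
  if (mode == "quantity") {
    if (!inherits(conc, "concentration_result"))
      stop("`conc` must be a concentration_result in quantity mode")
    cmap <- effective_concentration(conc) * voxel_volume_ml(spacing)
    for (r in regions) {
      m <- region_mask(labels, r)
      v <- cmap
      v[!m] <- 0
      out[[r]] <- apply(v, k, sum)
    }
  } else {
    in_plane <- prod(spacing[-k])
    for (r in regions) {
      m <- region_mask(labels, r)
      out[[r]] <- apply(m, k, sum) * in_plane
    }
  }
  out
}

#' Maximum intensity projection along an anatomical axis
#'
#' @param vol A [volume3d()] object.
#' @param axis Anatomical direction of the projection rays.
#' @return A 2D matrix (per-ray maxima) with attribute `spacing` carrying
#'   the in-plane spacing in mm and attribute `axes` naming the remaining
#'   anatomical axes.
#' @export
mip_render <- function(vol, axis = "ventral-dorsal") {
  stopifnot(inherits(vol, "volume3d"))
  k <- axis_index(vol$axes, axis)
  m <- apply(vol$data, setdiff(1:3, k), max, na.rm = TRUE)
  structure(m, spacing = vol$spacing[-k], axes = vol$axes[-k])
}

#' Cohort summary: mean, sample SD and coefficient of variation
#'
#' @param values Numeric vector of per-specimen values, at least two finite.
#' @return A list with `n`, `mean`, `sd` (n-1 denominator) and
#'   `cov` (= 100 * sd/mean, percent).
#' @export
summarize_cohort <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    stop("need at least two finite values for a cohort SD/CoV")
  m <- mean(values); s <- stats::sd(values)
  list(n = length(values), mean = m, sd = s, cov = 100 * s / m)
}

#' Per-specimen report of the distribution metrics
#'
#' Collects the quantities reported per specimen: enhanced volume, mean
#' post-administration T1 and concentration over the enhanced region, total
#' Gd3+ amount, PDF, PVF, and the three region volumes.
#'
#' @param conc A `concentration_result`.
#' @param labels A [region_labels()] object.
#' @param spacing Voxel spacing in mm.
#' @param specimen Optional specimen identifier.
#' @return An object of class `specimen_report` (a one-row-able list).
#' @export
specimen_report <- function(conc, labels, spacing, specimen = NA_character_) {
  vols <- region_volumes(labels, spacing)
  enh <- region_mask(labels, "enhanced")
  r1v <- conc$r1_post$volume$data[enh]
  t1_mean <- mean(1000 / r1v[is.finite(r1v) & r1v > 0])
  cmap <- effective_concentration(conc)
  rep <- list(
    specimen = specimen,
    enhanced_volume_ml = unname(vols["PER"] + vols["CER"]),
    mean_t1_post_ms = t1_mean,
    mean_concentration_mm = mean(cmap[enh]),
    gd_amount_umol = gd_amount(conc, labels, spacing, "enhanced"),
    pdf_percent = pdf_metric(conc, labels, spacing),
    pvf_percent = pvf_metric(labels),
    tlv_ml = unname(vols["TLV"]),
    per_ml = unname(vols["PER"]),
    cer_ml = unname(vols["CER"]),
    invalid_voxel_count = conc$invalid_voxel_count,
    negative_clamped_count = conc$negative_clamped_count
  )
  stopifnot(rep$pdf_percent >= 0, rep$pdf_percent <= 100,
            rep$pvf_percent >= 0, rep$pvf_percent <= 100,
            rep$gd_amount_umol >= 0)
  structure(rep, class = "specimen_report")
}

#' @export
print.specimen_report <- function(x, ...) {
  cat("specimen report", if (!is.na(x$specimen)) x$specimen else "", "\n")
  cat(sprintf("  enhanced volume %.1f mL; mean T1_post %.1f ms; mean C %.2f mM\n",
              x$enhanced_volume_ml, x$mean_t1_post_ms,
              x$mean_concentration_mm))
  cat(sprintf("  Gd amount %.1f umol; PDF %.1f%%; PVF %.1f%%\n",
              x$gd_amount_umol, x$pdf_percent, x$pvf_percent))
  cat(sprintf("  volumes: TLV %.1f, PER %.1f, CER %.1f mL\n",
              x$tlv_ml, x$per_ml, x$cer_ml))
  invisible(x)
}

#' Convert specimen reports to a data.frame
#'
#' @param reports A list of `specimen_report` objects.
#' @return A data.frame with one row per specimen.
#' @export
reports_to_df <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    as.data.frame(unclass(r), stringsAsFactors = FALSE)))
}
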