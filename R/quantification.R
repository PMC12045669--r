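#' Calibrate the scale constant and pre-administration R1 from a
#' variable-flip-angle series
#'
#' Given the mean ROI signal at each flip angle of the pre-administration
#' series (an ROI in a distal lung region free of contrast solution), jointly
#' estimates the scanner scale constant `A` and the pre-administration
#' longitudinal relaxation rate `R1_pre` of the spoiled gradient-echo model.
#'
#' The solve is the classic variable-flip-angle linearization -- regressing
#' `S/sin(alpha)` on `S/tan(alpha)` gives slope `E1` and intercept
#' `A*(1 - E1)` -- followed by nonlinear least squares on the signal
#' equation itself (Levenberg-Marquardt). With noiseless inputs the
#' linearized solve is already exact; the refinement matters for noisy ROI
#' means.
#'
#' @param signals Numeric vector of mean ROI signals, one per flip angle of
#'   `params$flip_angles`, all strictly positive; at least two distinct
#'   angles.
#' @param params An [acquisition_params()] object.
#' @param roi Optional logical mask (or voxel count) recording the ROI size,
#'   kept as provenance in the result.
#' @return An object of class `pre_calibration` with fields `A`,
#'   `R1_pre` (s^-1), `T1_pre_ms`, `fit_residual` (relative RMS of the
#'   flip-angle fit) and `roi_voxel_count`.
#' @examples
#' p <- acquisition_params()
#' s <- ute_signal(1000, p$flip_angles, p$tr, 800)
#' fit_pre_calibration(s, p)
#' @export
fit_pre_calibration <- function(signals, params, roi = NULL) {
  stopifnot(inherits(params, "acquisition_params"))
  alpha <- params$flip_angles
  if (length(signals) != length(alpha))
    stop("need one mean signal per flip angle (", length(alpha),
         "); got ", length(signals))
  if (length(unique(alpha)) < 2L)
    stop("degenerate flip-angle series: at least two distinct angles needed")
  if (any(!is.finite(signals)) || any(signals <= 0))
    stop("all mean ROI signals must be finite and strictly positive")

  a <- alpha * pi / 180
  y <- signals / sin(a)
  x <- signals / tan(a)
  lin <- stats::lm(y ~ x)
  e1 <- unname(stats::coef(lin)[2])
  if (!is.finite(e1) || e1 <= 0 || e1 >= 1)
    stop("flip-angle fit produced saturation factor E1 = ", signif(e1, 4),
         " outside (0, 1); check the ROI signals")
  A0 <- unname(stats::coef(lin)[1]) / (1 - e1)
  r1_0 <- -log(e1) / params$tr * 1000  # s^-1

  fit <- minpack.lm::nlsLM(
    S_obs ~ ute_signal(A, alpha_deg, tr_ms, 1000 / R1),
    data = list(S_obs = signals, alpha_deg = alpha,
                tr_ms = rep(params$tr, length(alpha))),
    start = list(A = A0, R1 = r1_0),
    lower = c(1e-12, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  est <- stats::coef(fit)
  A <- unname(est["A"]); R1 <- unname(est["R1"])
  if (!is.finite(A) || A <= 0 || !is.finite(R1) || R1 <= 0)
    stop("calibration fit did not converge to positive (A, R1_pre)")
  e1_fit <- exp(-params$tr * R1 / 1000)
  if (e1_fit <= 0 || e1_fit >= 1)
    stop("fitted saturation factor outside (0, 1)")
  pred <- ute_signal(A, alpha, params$tr, 1000 / R1)
  resid_rel <- sqrt(mean(((signals - pred) / signals)^2))

  n_roi <- if (is.null(roi)) NA_integer_
           else if (is.logical(roi)) sum(roi) else as.integer(roi)
  structure(
    list(A = A, R1_pre = R1, T1_pre_ms = 1000 / R1,
         fit_residual = resid_rel, roi_voxel_count = n_roi),
    class = "pre_calibration"
  )
}

#' @export
print.pre_calibration <- function(x, ...) {
  cat(sprintf(
    "pre-administration calibration: A = %.6g, R1_pre = %.4g s^-1 (T1 = %.4g ms)\n",
    x$A, x$R1_pre, x$T1_pre_ms))
  cat(sprintf("  relative RMS residual %.3g; ROI voxels: %s\n",
              x$fit_residual,
              ifelse(is.na(x$roi_voxel_count), "n/a", x$roi_voxel_count)))
  invisible(x)
}

#' Calibrate from the pre-administration volumes directly
#'
#' Convenience wrapper: takes the mean of each pre-administration volume over
#' the calibration ROI and calls [fit_pre_calibration()].
#'
#' @param pre_volumes List of [volume3d()] objects, one per flip angle, in
#'   the order of `params$flip_angles`.
#' @param roi Logical mask of the solution-free distal-lung ROI.
#' @param params An [acquisition_params()] object.
#' @return A `pre_calibration` object.
#' @export
calibrate_from_volumes <- function(pre_volumes, roi, params) {
  stopifnot(inherits(params, "acquisition_params"))
  if (length(pre_volumes) != length(params$flip_angles))
    stop("flip-angle count of the pre series (", length(pre_volumes),
         ") does not match acquisition parameters (",
         length(params$flip_angles), ")")
  if (!any(roi)) stop("calibration ROI is empty")
  means <- vapply(pre_volumes,
                  function(v) mean(v$data[roi], na.rm = TRUE), numeric(1))
  fit_pre_calibration(means, params, roi = roi)
}

#' Pixel-wise post-administration R1 map
#'
#' Inverts the single-flip-angle post-administration volume voxel by voxel
#' using the calibrated scale constant, then converts T1 (ms) to
#' R1 = 1000/T1 (s^-1). Voxels whose signal falls outside the invertible
#' domain are flagged NA and counted; T1 values above `t1_max` are capped
#' and counted.
#'
#' @param post_vol [volume3d()] acquired at `params$post_flip_angle`.
#' @param calib A `pre_calibration` object.
#' @param params An [acquisition_params()] object.
#' @param mask Logical analysis mask (non-empty); voxels outside are NA.
#' @param t1_max T1 cap in ms (default 5000).
#' @return Object of class `r1_map` with fields `volume` ([volume3d()],
#'   s^-1), `invalid_voxel_count`, `capped_voxel_count`, `mask`.
#' @export
r1_post_map <- function(post_vol, calib, params, mask, t1_max = 5000) {
  stopifnot(inherits(post_vol, "volume3d"),
            inherits(calib, "pre_calibration"),
            inherits(params, "acquisition_params"),
            identical(dim(mask), dim(post_vol$data)))
  if (!any(mask)) stop("analysis mask is empty")
  t1 <- invert_signal_to_t1(post_vol$data[mask], calib$A,
                            params$post_flip_angle, params$tr,
                            t1_max = t1_max, on_invalid = "na")
  r1 <- array(NA_real_, dim = dim(post_vol$data))
  r1[mask] <- 1000 / as.numeric(t1)
  structure(
    list(volume = volume3d(r1, post_vol$spacing, post_vol$axes),
         invalid_voxel_count = attr(t1, "invalid"),
         capped_voxel_count = attr(t1, "capped"),
         mask = mask),
    class = "r1_map"
  )
}

#' Contrast-agent concentration map
#'
#' Converts the post-administration relaxation-rate map to Gd3+
#' concentration via the relaxivity relation
#' `C = (R1_post - R1_pre) / r1` (mM). The raw map is always retained;
#' when `clamp_negative` is set (the default), region amounts and
#' distribution metrics use concentrations floored at zero, and the number
#' of clamped voxels is reported -- noise makes scattered negatives
#' inevitable.
#'
#' @param r1_post An `r1_map` from [r1_post_map()].
#' @param calib A `pre_calibration` (supplies the scalar `R1_pre`).
#' @param params An [acquisition_params()] (supplies `r1`).
#' @param clamp_negative Clamp negative concentrations to zero for amount
#'   integration (default TRUE).
#' @return Object of class `concentration_result` with fields
#'   `concentration` (raw [volume3d()], mM), `r1_post` (the input map),
#'   `R1_pre`, `r1`, `clamp_negative`, `invalid_voxel_count`,
#'   `negative_clamped_count`, `mask`.
#' @export
concentration_map <- function(r1_post, calib, params, clamp_negative = TRUE) {
  stopifnot(inherits(r1_post, "r1_map"),
            inherits(calib, "pre_calibration"),
            inherits(params, "acquisition_params"))
  cmap <- (r1_post$volume$data - calib$R1_pre) / params$r1
  n_neg <- sum(cmap < 0, na.rm = TRUE)
  structure(
    list(concentration = volume3d(cmap, r1_post$volume$spacing,
                                  r1_post$volume$axes),
         r1_post = r1_post,
         R1_pre = calib$R1_pre, r1 = params$r1,
         clamp_negative = clamp_negative,
         invalid_voxel_count = r1_post$invalid_voxel_count,
         negative_clamped_count = if (clamp_negative) n_neg else 0L,
         mask = r1_post$mask),
    class = "concentration_result"
  )
}

# concentration values used for amount integration and metrics: clamped
# (if requested) and with invalid voxels contributing zero
effective_concentration <- function(conc) {
  stopifnot(inherits(conc, "concentration_result"))
  cmap <- conc$concentration$data
  if (conc$clamp_negative) cmap <- pmax(cmap, 0)
  cmap[is.na(cmap)] <- 0
  cmap
}

#' Integrated Gd3+ amount in a region
#'
#' Sum over the region's voxels of concentration (mM) times voxel volume
#' (mL); mM x mL is micromoles. Invalid (non-invertible) voxels contribute
#' zero. With clamping enabled in the concentration result, negative voxels
#' also contribute zero.
#'
#' @param conc A `concentration_result`.
#' @param labels A [region_labels()] object.
#' @param spacing Voxel spacing in mm.
#' @param region One of `"PER"`, `"CER"`, `"TLV"`, `"enhanced"`.
#' @return Amount of Gd3+ in micromoles.
#' @export
gd_amount <- function(conc, labels, spacing, region) {
  if (!region %in% c("PER", "CER", "TLV", "enhanced"))
    stop("unknown region '", region,
         "'; expected one of PER, CER, TLV, enhanced")
  m <- region_mask(labels, region)
  cmap <- effective_concentration(conc)
  sum(cmap[m]) * voxel_volume_ml(spacing)
}

#' Instilled Gd3+ dose from the mixture recipe
#'
#' The instilled solution is a mixture of surfactant and a Gd-based contrast
#' agent. The delivered Gd3+ amount is the delivered volume times the
#' contrast agent's volume fraction in the mixture times its stock
#' concentration: `delivered * contrast/(surfactant + contrast) * conc`,
#' in micromoles (mL x mM).
#'
#' @param surfactant_vol Surfactant volume in the mixture, mL.
#' @param contrast_vol Contrast-agent volume in the mixture, mL.
#' @param contrast_conc Gd3+ concentration of the contrast stock, mM.
#' @param delivered_vol Volume of mixture actually instilled, mL; at most
#'   the total mixture volume.
#' @return Delivered Gd3+ amount in micromoles.
#' @examples
#' instilled_gd_amount(2.7, 0.27, 500, 2.2)  # 100
#' @export
instilled_gd_amount <- function(surfactant_vol, contrast_vol, contrast_conc,
                                delivered_vol) {
  if (surfactant_vol <= 0 || contrast_vol <= 0 || contrast_conc <= 0)
    stop("mixture volumes and stock concentration must be positive")
  if (delivered_vol < 0)
    stop("`delivered_vol` must be non-negative")
  if (delivered_vol > surfactant_vol + contrast_vol)
    stop("`delivered_vol` exceeds the total mixture volume")
  delivered_vol * contrast_vol / (surfactant_vol + contrast_vol) *
    contrast_conc
}
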