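#' Steady-state spoiled gradient-echo (UTE) signal amplitude
#'
#' The forward signal model for the 3D UTE acquisition:
#' \deqn{S = A \sin\alpha \frac{1 - E_1}{1 - \cos\alpha\, E_1}, \qquad
#'       E_1 = e^{-TR/T_1}}
#' where `A` is a scale constant set by the instrumentation and equilibrium
#' magnetization, `alpha` the excitation flip angle, `TR` the repetition
#' time and `T1` the longitudinal relaxation time. With the ultra-short
#' echo time of the sequence, T2* decay between excitation and readout is
#' neglected. All arguments are vectorized.
#'
#' @param A Scale constant (arbitrary units), positive.
#' @param alpha Flip angle in degrees, strictly in (0, 90].
#' @param tr Repetition time in ms, positive.
#' @param t1 Longitudinal relaxation time in ms, positive.
#' @return Signal amplitude, same units as `A`. Strictly decreasing in `t1`
#'   and bounded above by `A * sin(alpha)` (the fully relaxed limit).
#' @examples
#' ute_signal(1000, 25, 3.7, 266.2)  # ~54.93
#' @export
ute_signal <- function(A, alpha, tr, t1) {
  if (any(!is.finite(t1)) || any(t1 <= 0))
    stop("`t1` must be positive (ms)")
  if (any(!is.finite(tr)) || any(tr <= 0))
    stop("`tr` must be positive (ms)")
  if (any(alpha <= 0 | alpha > 90))
    stop("`alpha` must be strictly in (0, 90] degrees")
  a <- alpha * pi / 180
  e1 <- exp(-tr / t1)
  A * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Invert the spoiled gradient-echo signal for T1
#'
#' Closed-form inversion of the signal model at a single flip angle, given a
#' calibrated scale constant: solves for the saturation factor
#' \eqn{E_1 = (A\sin\alpha - S)/(A\sin\alpha - S\cos\alpha)} and returns
#' \eqn{T_1 = -TR / \ln E_1}. Valid for `0 < S < A*sin(alpha)`.
#'
#' Near-zero signal drives T1 to infinity; values above `t1_max` are capped
#' there and counted in the `"capped"` attribute. Out-of-domain signals
#' (`S >= A*sin(alpha)` or a computed `E1` outside (0, 1)) raise an error
#' when `on_invalid = "error"` or become NA (counted in the `"invalid"`
#' attribute) when `on_invalid = "na"` -- the map-level policy, since
#' magnitude noise guarantees some voxels exceed the model ceiling.
#'
#' @param S Signal amplitude(s).
#' @param A Calibrated scale constant.
#' @param alpha Flip angle in degrees.
#' @param tr Repetition time in ms.
#' @param t1_max Upper cap for T1 in ms (default 5000), bounding the
#'   inversion in near-zero-signal background.
#' @param on_invalid `"error"` (scalar use) or `"na"` (map use).
#' @return T1 in ms, with attributes `invalid` and `capped` giving counts.
#' @examples
#' invert_signal_to_t1(54.93, 1000, 25, 3.7)  # ~266.2
#' @export
invert_signal_to_t1 <- function(S, A, alpha, tr, t1_max = 5000,
                                on_invalid = c("error", "na")) {
  on_invalid <- match.arg(on_invalid)
  if (any(alpha <= 0 | alpha > 90))
    stop("`alpha` must be strictly in (0, 90] degrees")
  if (any(tr <= 0)) stop("`tr` must be positive (ms)")
  a <- alpha * pi / 180
  ceiling_ <- A * sin(a)
  e1 <- (ceiling_ - S) / (ceiling_ - S * cos(a))
  ok <- is.finite(S) & S > 0 & is.finite(e1) & e1 > 0 & e1 < 1
  if (!all(ok, na.rm = TRUE) || anyNA(S)) {
    if (on_invalid == "error") {
      if (any(is.finite(S) & S >= ceiling_))
        stop("signal exceeds model ceiling A*sin(alpha) = ",
             signif(max(ceiling_), 6))
      stop("signal outside the invertible domain (0, A*sin(alpha))")
    }
  }
  t1 <- rep(NA_real_, length(e1))
  t1[ok] <- -tr / log(e1[ok])
  capped <- !is.na(t1) & t1 > t1_max
  t1[capped] <- t1_max
  structure(t1, invalid = sum(!ok), capped = sum(capped))
}

#' Signal enhancement
#'
#' Relative SNR increase after contrast administration:
#' `SE = (snr_post - snr_pre) / snr_pre`. Returned as a fraction; multiply
#' by 100 for percent. Negative values (signal loss) are permitted.
#'
#' @param snr_pre Pre-administration SNR, strictly positive.
#' @param snr_post Post-administration SNR.
#' @return SE as a fraction (1 = 100% increase). Vectorized.
#' @export
signal_enhancement <- function(snr_pre, snr_post) {
  if (any(!is.finite(snr_pre)) || any(snr_pre <= 0))
    stop("`snr_pre` must be strictly positive")
  (snr_post - snr_pre) / snr_pre
}

#' ROI-based signal-to-noise ratio
#'
#' Mean intensity over a signal ROI divided by the standard deviation over
#' a noise ROI. This estimator is a declared convention of this package
#' (the size and placement of the ROIs are the caller's choice); the noise
#' ROI should sit in a signal-free or uniform region.
#'
#' @param vol A [volume3d()] object.
#' @param signal_mask,noise_mask Logical arrays congruent with `vol`,
#'   non-empty and disjoint.
#' @return SNR (dimensionless).
#' @export
roi_snr <- function(vol, signal_mask, noise_mask) {
  stopifnot(inherits(vol, "volume3d"),
            identical(dim(signal_mask), dim(vol$data)),
            identical(dim(noise_mask), dim(vol$data)))
  if (!any(signal_mask) || !any(noise_mask))
    stop("both ROIs must be non-empty")
  if (any(signal_mask & noise_mask))
    stop("signal and noise ROIs overlap; they must be disjoint")
  s <- mean(vol$data[signal_mask], na.rm = TRUE)
  n <- stats::sd(vol$data[noise_mask], na.rm = TRUE)
  if (!is.finite(n) || n == 0)
    stop("zero noise variance in the noise ROI; SNR undefined")
  s / n
}
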