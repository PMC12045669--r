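#' Acquisition parameters for the UTE spoiled gradient-echo protocol
#'
#' Bundles the sequence constants that enter the steady-state spoiled
#' gradient-echo signal equation and the concentration conversion: repetition
#' time, the flip-angle series of the pre-administration acquisition, the
#' flip angle of the post-administration volume, and the longitudinal
#' relaxivity of the contrast agent. The echo time is recorded for provenance
#' only; with a TE of ~0.1 ms, T2* decay is neglected by the signal model.
#'
#' Flip angles are in degrees at every interface of this package; conversion
#' to radians happens internally.
#'
#' @param tr Repetition time in ms.
#' @param te Echo time in ms (recorded, not used by the signal model).
#' @param flip_angles Flip angles of the pre-administration series, degrees,
#'   each strictly in (0, 90].
#' @param r1 Longitudinal relaxivity of the contrast agent per Gd3+ ion, in
#'   mM^-1 s^-1. Default 3, the value for Gd-DOTA in plasma at 3 T.
#' @param post_flip_angle Flip angle (degrees) of the post-administration
#'   volume; must be one of `flip_angles`.
#' @return An object of class `acquisition_params`.
#' @examples
#' acquisition_params()
#' @export
acquisition_params <- function(tr = 3.7, te = 0.096,
                               flip_angles = c(5, 8, 16, 25),
                               r1 = 3, post_flip_angle = 25) {
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("`tr` must be a single positive number (ms)")
  if (!is.numeric(flip_angles) || length(flip_angles) < 1L ||
      any(!is.finite(flip_angles)) ||
      any(flip_angles <= 0 | flip_angles > 90))
    stop("every flip angle must be strictly in (0, 90] degrees")
  if (!is.numeric(r1) || length(r1) != 1L || !is.finite(r1) || r1 <= 0)
    stop("`r1` must be a single positive relaxivity (mM^-1 s^-1)")
  if (!post_flip_angle %in% flip_angles)
    stop("`post_flip_angle` (", post_flip_angle,
         ") must be a member of `flip_angles`")
  structure(
    list(tr = tr, te = te, flip_angles = as.numeric(flip_angles),
         r1 = r1, post_flip_angle = post_flip_angle),
    class = "acquisition_params"
  )
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("UTE acquisition parameters\n")
  cat(sprintf("  TR %.3g ms, TE %.3g ms\n", x$tr, x$te))
  cat(sprintf("  flip angles: %s deg (post-administration volume at %g deg)\n",
              paste(x$flip_angles, collapse = ", "), x$post_flip_angle))
  cat(sprintf("  relaxivity r1 = %.3g mM^-1 s^-1\n", x$r1))
  invisible(x)
}
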