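#' Pipeline configuration
#'
#' Bundles every tunable of the detection pipeline.  The only parameter that
#' must be known a priori is the nominal optic-disc radius `nominal_radius`
#' (in pixels at the original image resolution); it is estimated once per
#' dataset from the camera resolution and field of view, assuming an
#' anatomical disc diameter of about 1.75 mm.  All remaining factors default
#' to the fixed values of the method and rarely need changing.
#'
#' @param nominal_radius Expected optic-disc radius \eqn{R_a} in pixels at
#'   original scale.  Mandatory, no default.
#' @param k Number of thresholds for multilevel Otsu (giving `k + 1`
#'   intensity classes).  Default 5.
#' @param roundness_min Minimum roundness \eqn{4\pi A / P^2} for an object to
#'   be considered disc-like.  Default 0.6.
#' @param sigma_factor Gaussian smoothing scale as a fraction of
#'   `nominal_radius` (\eqn{\sigma = R_a/4}).  Default 0.25.
#' @param se_factor Radius of the disc structuring element used for vessel
#'   suppression, as a fraction of `nominal_radius`.  Default 0.15 (the
#'   anatomical vessel-width to disc-diameter ratio).
#' @param r_min_factor,r_max_factor Hough search band \eqn{[0.95, 1.3] R_a}.
#' @param downscale_trigger Images with a side longer than this many pixels
#'   are reduced to quarter size before processing.  Default 1000.
#' @param downscale_factor Linear reduction factor.  Default 0.25.
#' @param mean_filter_size Side of the post-closing mean filter.  Default 3.
#' @param fov_channel Channel used to estimate the field-of-view mask.
#'   Default `"R"`.
#' @param gradient_quantile Quantile of the in-FOV gradient magnitude above
#'   which pixels vote in the Hough accumulator.  Default 0.9.
#' @param accumulator_sigma Gaussian smoothing (pixels) applied to the Hough
#'   accumulator before peak picking.  Default 2.
#' @param ring_width Half-width (pixels) of the inner/outer bands used for the
#'   radial ring-contrast profile.  Default 2.
#' @param radius_rule Either `"ring_contrast"` (inward minus outward ring-mean
#'   contrast, the default) or `"ring_mean"` (first local maximum of the raw
#'   radial intensity histogram).
#'
#' @return An object of class `od_config` (a named list).
#' @examples
#' cfg <- od_config(nominal_radius = 50)
#' cfg$k
#' @export
od_config <- function(nominal_radius,
                      k = 5L,
                      roundness_min = 0.6,
                      sigma_factor = 0.25,
                      se_factor = 0.15,
                      r_min_factor = 0.95,
                      r_max_factor = 1.3,
                      downscale_trigger = 1000L,
                      downscale_factor = 0.25,
                      mean_filter_size = 3L,
                      fov_channel = c("R", "G", "B"),
                      gradient_quantile = 0.9,
                      accumulator_sigma = 2,
                      ring_width = 2L,
                      radius_rule = c("ring_contrast", "ring_mean")) {
  if (missing(nominal_radius)) {
    abort("`nominal_radius` (R_a, pixels at original scale) is required.",
          class = "od_config_error")
  }
  stopifnot(is.numeric(nominal_radius), length(nominal_radius) == 1L,
            nominal_radius > 0)
  k <- as.integer(k)
  if (k < 1L) abort("`k` must be >= 1.", class = "od_config_error")
  if (!(r_min_factor > 0 && r_min_factor < r_max_factor)) {
    abort("need 0 < r_min_factor < r_max_factor.", class = "od_config_error")
  }
  structure(
    list(
      nominal_radius = as.numeric(nominal_radius),
      k = k,
      roundness_min = roundness_min,
      sigma_factor = sigma_factor,
      se_factor = se_factor,
      r_min_factor = r_min_factor,
      r_max_factor = r_max_factor,
      downscale_trigger = as.integer(downscale_trigger),
      downscale_factor = downscale_factor,
      mean_filter_size = as.integer(mean_filter_size),
      fov_channel = match.arg(fov_channel),
      gradient_quantile = gradient_quantile,
      accumulator_sigma = accumulator_sigma,
      ring_width = as.integer(ring_width),
      radius_rule = match.arg(radius_rule)
    ),
    class = "od_config"
  )
}

#' @export
print.od_config <- function(x, ...) {
  cat("<od_config>\n")
  cat(sprintf("  nominal radius R_a : %g px (original scale)\n", x$nominal_radius))
  cat(sprintf("  Otsu thresholds k  : %d\n", x$k))
  cat(sprintf("  roundness min      : %g\n", x$roundness_min))
  cat(sprintf("  sigma = %g R_a, se = %g R_a, band = [%g, %g] R_a\n",
              x$sigma_factor, x$se_factor, x$r_min_factor, x$r_max_factor))
  cat(sprintf("  downscale: > %d px -> x%g\n", x$downscale_trigger,
              x$downscale_factor))
  invisible(x)
}

# Working-scale nominal radius; every kernel size derives from it.
working_radius <- function(config, scale_factor) {
  max(8, round(config$nominal_radius * scale_factor))
}
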