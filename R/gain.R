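# Detector gain estimation from background pixels.
#
# An integrating detector reports roughly G ADU per primary electron. If
# the number of primaries per background pixel is Poisson with mean n, the
# recorded values have mean G*n and variance G^2*n, so the index of
# dispersion var/mean equals G. This is the standard method-of-moments
# estimator; it needs no flat-field exposure, only background pixels.

#' Estimate detector gain from Poisson background statistics
#'
#' Selects background pixels as those at or below a quantile of the
#' pedestal-subtracted frame (excluding the brightest fraction suppresses
#' Bragg spots), then returns `G = var / mean` of the selection. A known
#' Gaussian read-noise variance can be subtracted from the numerator to
#' de-bias the estimate.
#'
#' @param frame Numeric matrix (a single detector frame), >= 1000 pixels.
#' @param pedestal Constant already present in the pixel values, subtracted
#'   before estimation (ADU, >= 0).
#' @param spot_exclusion_quantile Pixels above this quantile are excluded
#'   (default 0.99); use 1 for spot-free flat exposures. Must be in \[0, 1).
#'   behaviour at exactly 1 keeps every pixel.
#' @param read_noise_var Known read-noise variance in ADU^2, subtracted
#'   from the background variance (default 0).
#' @param mask Optional logical array the shape of `frame`; only `TRUE`
#'   pixels are used (e.g. to exclude predicted spot regions exactly,
#'   avoiding the slight downward bias quantile truncation puts on the
#'   variance of a Poisson background).
#' @return A `gain_estimate` with `G`, `background_mean`,
#'   `background_variance`, `n_pixels_used`.
#' @export
estimate_gain <- function(frame, pedestal = 0, spot_exclusion_quantile = 0.99,
                          read_noise_var = 0, mask = NULL) {
  stopifnot(is.numeric(frame))
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), length(mask) == length(frame))
    frame <- frame[mask]
  }
  if (length(frame) < 1000)
    stop("frame too small for gain estimation (need >= 1000 pixels)", call. = FALSE)
  if (spot_exclusion_quantile < 0 || spot_exclusion_quantile > 1)
    stop("spot_exclusion_quantile must be in [0, 1]", call. = FALSE)
  v <- as.numeric(frame) - pedestal
  if (spot_exclusion_quantile < 1) {
    cut <- stats::quantile(v, spot_exclusion_quantile, names = FALSE, type = 7)
    v <- v[v <= cut]
  }
  m <- mean(v)
  if (m <= 0)
    stop("background mean <= 0 after pedestal subtraction; ",
         "the pedestal appears mis-specified", call. = FALSE)
  s2 <- stats::var(v) - read_noise_var
  if (s2 <= 0) {
    warning("degenerate background statistics (variance <= 0); gain set to 0")
    s2 <- 0
  }
  structure(list(G = s2 / m,
                 background_mean = m,
                 background_variance = s2,
                 n_pixels_used = length(v)),
            class = "gain_estimate")
}

#' @export
print.gain_estimate <- function(x, ...) {
  cat(sprintf("Gain estimate: G = %.4g ADU/event (mean %.4g, var %.4g, n = %d)\n",
              x$G, x$background_mean, x$background_variance, x$n_pixels_used))
  invisible(x)
}
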