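# Double-gamma hemodynamic response function.

#' Parameters of the double-gamma HRF
#'
#' The canonical shape: a gamma-density peak minus a scaled, later gamma
#' density modelling the post-stimulus undershoot. With the defaults the peak
#' sits at (peak_delay - peak_dispersion) = 5 s and the undershoot at 15 s.
#'
#' @param peak_delay_s Time-to-peak parameter of the positive lobe (gamma
#'   shape x scale), seconds.
#' @param undershoot_delay_s Same for the undershoot lobe.
#' @param peak_dispersion_s Gamma scale of the positive lobe, seconds.
#' @param undershoot_dispersion_s Gamma scale of the undershoot lobe.
#' @param undershoot_ratio Amplitude of the undershoot relative to the peak
#'   lobe (>= 0; 0 disables the undershoot).
#' @return A list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_dispersion_s = 1, undershoot_dispersion_s = 1,
                       undershoot_ratio = 1 / 6) {
  stopifnot(peak_delay_s > 0, undershoot_delay_s > 0,
            peak_dispersion_s > 0, undershoot_dispersion_s > 0,
            undershoot_ratio >= 0)
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_dispersion_s = peak_dispersion_s,
                 undershoot_dispersion_s = undershoot_dispersion_s,
                 undershoot_ratio = undershoot_ratio),
            class = "hrf_params")
}

# Unnormalized continuous double-gamma.
hrf_raw <- function(t, p) {
  stats::dgamma(t, shape = p$peak_delay_s / p$peak_dispersion_s,
                scale = p$peak_dispersion_s) -
    p$undershoot_ratio *
      stats::dgamma(t, shape = p$undershoot_delay_s / p$undershoot_dispersion_s,
                    scale = p$undershoot_dispersion_s)
}

# Continuous peak value, used so that sampled kernels at any resolution share
# one normalization (a coarse kernel is then exactly a decimated fine kernel).
hrf_peak_value <- function(p) {
  opt <- stats::optimize(function(t) hrf_raw(t, p), interval = c(0.5, 12),
                         maximum = TRUE, tol = 1e-10)
  opt$objective
}

#' Sample the double-gamma HRF kernel
#'
#' @param tr_s Sampling interval in seconds (> 0). For design-matrix
#'   construction this is a fine oversampling interval, not necessarily the
#'   scanner TR.
#' @param params An [hrf_params()] object.
#' @param duration_s Kernel length in seconds; must cover the undershoot
#'   (default 32 s).
#' @return Numeric vector sampled at `0, tr_s, 2 tr_s, ...`, normalized so the
#'   continuous peak equals 1.
#' @export
double_gamma_hrf <- function(tr_s, params = hrf_params(), duration_s = 32) {
  if (tr_s <= 0) stop("tr_s must be positive")
  stopifnot(duration_s >= 28)
  t <- seq(0, duration_s, by = tr_s)
  hrf_raw(t, params) / hrf_peak_value(params)
}
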