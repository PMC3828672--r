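#' Denoising configuration
#'
#' Parameters for wavelet soft-threshold denoising: the mother wavelet,
#' the threshold correction factor gamma, and the decomposition depth.
#' Gamma scales the universal threshold; values in [0.4, 2] span gentle
#' to aggressive shrinkage.
#'
#' @param wavelet Mother wavelet, one of [MU_WAVELETS].
#' @param gamma Threshold correction factor (> 0).
#' @param levels Decomposition depth (default 5).
#' @return Object of class `denoise_config`.
#' @export
denoise_config <- function(wavelet = "db6", gamma = 0.8, levels = 5L) {
  if (!is.character(wavelet) || !wavelet %in% MU_WAVELETS)
    stop("unsupported wavelet: ", wavelet)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a single positive number")
  structure(list(wavelet = wavelet, gamma = gamma,
                 levels = as.integer(levels)),
            class = "denoise_config")
}

#' Robust noise standard deviation from a quantile-quantile fit
#'
#' Estimates the standard deviation of the Gaussian noise floor as the
#' least-squares slope of the empirical order statistics against the
#' standard-normal quantiles, restricted to the central quantile band.
#' The central band makes the estimate insensitive to the heavy tails
#' contributed by spikes.
#'
#' @param window Numeric vector of at least 100 samples.
#' @param band Quantile band used for the fit (default central 25th-75th
#'   percentiles).
#' @return Estimated noise standard deviation (same units as `window`,
#'   non-negative). A constant window yields 0 with a warning.
#' @export
estimate_noise_sigma_qq <- function(window, band = c(0.25, 0.75)) {
  if (!is.numeric(window) || length(window) < 100L)
    stop("need at least 100 samples for the quantile-quantile fit")
  n <- length(window)
  p <- stats::ppoints(n)
  keep <- p >= band[1] & p <= band[2]
  s <- sort(window)[keep]
  if (all(s == s[1L])) {
    warning("constant window: noise sigma estimated as 0")
    return(0)
  }
  q <- stats::qnorm(p[keep])
  slope <- stats::cov(q, s) / stats::var(q)
  max(slope, 0)
}

#' Robust noise standard deviation from the median absolute amplitude
#'
#' The median-based estimator sigma_D = median(|x|) / 0.6745, which is
#' unbiased for Gaussian noise and insensitive to the high-amplitude
#' excursions caused by action potentials, avoiding the inflation of the
#' noise estimate at high firing rates.
#'
#' @param window Numeric vector (non-empty).
#' @return Estimated noise standard deviation.
#' @export
estimate_noise_sigma_mad <- function(window) {
  if (length(window) == 0L) stop("empty window")
  stats::median(abs(window)) / 0.6745
}

#' Universal wavelet shrinkage threshold
#'
#' Th = gamma * sigma * sqrt(2 ln N): the universal threshold for a data
#' vector of length N with noise standard deviation sigma, scaled by the
#' correction factor gamma.
#'
#' @param sigma Noise standard deviation (>= 0).
#' @param gamma Threshold correction factor (> 0).
#' @param N Length of the data vector (>= 2).
#' @return Threshold in the units of `sigma`.
#' @export
wavelet_threshold <- function(sigma, gamma, N) {
  stopifnot(is.numeric(sigma), sigma >= 0, is.numeric(gamma), gamma > 0)
  if (!is.numeric(N) || length(N) != 1L || N < 2)
    stop("N must be a single count >= 2")
  gamma * sigma * sqrt(2 * log(N))
}

#' Soft-threshold (shrinkage) operator
#'
#' sign(c) * max(|c| - Th, 0), applied elementwise.
#'
#' @param coef Numeric vector of coefficients.
#' @param Th Threshold (>= 0).
#' @return Shrunk coefficients.
#' @export
soft_threshold <- function(coef, Th) {
  stopifnot(is.numeric(Th), length(Th) == 1L, Th >= 0)
  sign(coef) * pmax(abs(coef) - Th, 0)
}

#' Wavelet soft-threshold denoising of a signal
#'
#' Decomposes the signal to `levels` scales, soft-thresholds all detail
#' coefficients with the universal threshold computed from the
#' quantile-quantile noise estimate of the input (N = signal length),
#' and reconstructs. Approximation coefficients are left untouched.
#'
#' @param x Numeric signal vector.
#' @param config A [denoise_config()].
#' @return Denoised signal, same length as `x`. The applied threshold
#'   and noise estimate are attached as attributes `threshold` and
#'   `sigma`.
#' @export
denoise_signal <- function(x, config = denoise_config()) {
  stopifnot(inherits(config, "denoise_config"))
  sigma <- estimate_noise_sigma_qq(x)
  Th <- wavelet_threshold(sigma, config$gamma, length(x))
  dec <- dwt_decompose(x, config$wavelet, config$levels)
  dec$details <- lapply(dec$details, soft_threshold, Th = Th)
  out <- dwt_reconstruct(dec)
  attr(out, "threshold") <- Th
  attr(out, "sigma") <- sigma
  out
}

#' Signal-to-noise ratio estimate of a data window
#'
#' SNR = 20 log10(A_s / A_n), where A_s is the maximum absolute
#' amplitude in the window (signal plus noise) and A_n = 4 sigma_D is
#' the noise amplitude derived from the median-based noise estimate
#' ([estimate_noise_sigma_mad()]).
#'
#' @param window Numeric vector (non-empty), typically 400 ms of signal.
#' @return List with `A_s`, `A_n` (same units as the window) and
#'   `snr_db`. If A_n is 0 the SNR is undefined and returned as `NA`
#'   with a warning.
#' @export
snr_estim <- function(window) {
  if (length(window) == 0L) stop("empty window")
  A_s <- max(abs(window))
  A_n <- 4 * estimate_noise_sigma_mad(window)
  if (A_n == 0) {
    warning("zero noise amplitude: SNR undefined")
    snr <- NA_real_
  } else {
    snr <- 20 * log10(A_s / A_n)
  }
  list(A_s = A_s, A_n = A_n, snr_db = snr)
}
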