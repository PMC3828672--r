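#' Multi-level discrete wavelet decomposition
#'
#' Decomposes a signal into `levels` detail bands plus a final
#' approximation band using an orthogonal DWT with half-point symmetric
#' boundary extension. The inverse of [dwt_reconstruct()] up to floating
#' point round-off.
#'
#' @param x Numeric signal vector.
#' @param wavelet Mother wavelet name, one of [MU_WAVELETS].
#' @param levels Decomposition depth (default 5).
#' @return Object of class `mu_dwt`: list with `approx` (coarsest
#'   approximation coefficients), `details` (list of detail coefficient
#'   vectors, level 1 = finest), `lengths` (segment length entering each
#'   level, needed for exact reconstruction), and `wavelet`.
#' @export
dwt_decompose <- function(x, wavelet, levels = 5L) {
  stopifnot(is.numeric(x), length(levels) == 1L, levels >= 1L)
  f <- wavelet_filters(wavelet)
  if (length(x) < 2^levels)
    stop("signal too short for ", levels, "-level decomposition")
  details <- vector("list", levels)
  lengths <- integer(levels)
  cur <- as.numeric(x)
  for (lev in seq_len(levels)) {
    lengths[lev] <- length(cur)
    s <- .dwt_step(cur, f$dec_lo, f$dec_hi)
    details[[lev]] <- s$cD
    cur <- s$cA
  }
  structure(list(approx = cur, details = details, lengths = lengths,
                 wavelet = wavelet),
            class = "mu_dwt")
}

#' Inverse multi-level discrete wavelet transform
#'
#' @param dec A `mu_dwt` object from [dwt_decompose()].
#' @return Numeric vector with the length of the original signal.
#' @export
dwt_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "mu_dwt"))
  f <- wavelet_filters(dec$wavelet)
  cur <- dec$approx
  for (lev in rev(seq_along(dec$details))) {
    cur <- .idwt_step(cur, dec$details[[lev]], f$rec_lo, f$rec_hi,
                      dec$lengths[lev])
  }
  cur
}
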