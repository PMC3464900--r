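#' Discrete Fourier transform of a framed, mean-shifted series
#'
#' Computes the unnormalised forward DFT
#' \deqn{G_n = \sum_{k=0}^{K-1} g(kT)\, e^{-i 2\pi nk/N}, \quad n = 0,\dots,N-1}
#' with \eqn{N = K} frequency components, the convention implemented by
#' [stats::fft()]. Bin \eqn{n} corresponds to frequency \eqn{f_n = n/(NT)}
#' cycles per hour. For a zero-mean input the DC coefficient \eqn{G_0}
#' vanishes.
#'
#' @param x numeric vector of samples on a uniform grid, or a
#'   `mean_shifted` object from [mean_shift()].
#' @param sample_interval_h sampling interval T in hours.
#' @return An object of class `priism_spectrum`: `coefficients` (complex,
#'   length N), `N`, `sample_interval_h` and `frequencies` (cycles/hour).
#' @export
dft <- function(x, sample_interval_h) {
  if (inherits(x, "mean_shifted")) x <- x$samples
  x <- as.numeric(x)
  if (length(x) < 4) stop("series must have at least 4 samples")
  stopifnot(sample_interval_h > 0)
  n <- length(x)
  structure(
    list(coefficients = stats::fft(x), N = n,
         sample_interval_h = sample_interval_h,
         frequencies = (0:(n - 1)) / (n * sample_interval_h)),
    class = "priism_spectrum"
  )
}

new_spectrum_like <- function(sp, coefficients) {
  sp$coefficients <- coefficients
  sp
}

#' Amplitude spectrum over the non-redundant frequency bins
#'
#' For a real input the upper half of the spectrum mirrors the lower half,
#' so only bins 0..floor(N/2) are reported. Relative amplitudes are the
#' moduli divided by their maximum; an all-zero spectrum is flagged
#' degenerate and gets all-zero relative amplitudes.
#'
#' @param sp a `priism_spectrum`.
#' @return Object of class `amplitude_spectrum`: `bins` (0-based indices),
#'   `frequencies` (cycles/hour), `amplitudes`, `relative_amplitudes`,
#'   `degenerate`.
#' @export
amplitude_spectrum <- function(sp) {
  stopifnot(inherits(sp, "priism_spectrum"))
  half <- floor(sp$N / 2)
  bins <- 0:half
  amps <- Mod(sp$coefficients)[bins + 1L]
  mx <- max(amps)
  degenerate <- mx <= 0
  rel <- if (degenerate) rep(0, length(amps)) else amps / mx
  structure(
    list(bins = bins, frequencies = sp$frequencies[bins + 1L],
         amplitudes = amps, relative_amplitudes = rel,
         degenerate = degenerate, N = sp$N,
         sample_interval_h = sp$sample_interval_h),
    class = "amplitude_spectrum"
  )
}

#' Inverse discrete Fourier transform
#'
#' Reconstructs \eqn{g(kT) = \frac{1}{N}\sum_{n=0}^{N-1} G_n e^{i2\pi nk/N}}.
#' The spectrum must satisfy the real-signal condition
#' \eqn{G_{N-n} = \overline{G_n}}; any sub-tolerance imaginary residue of
#' the reconstruction is discarded.
#'
#' @param sp a `priism_spectrum` with conjugate-symmetric coefficients.
#' @param tol absolute tolerance for the conjugate-symmetry check.
#' @return Real numeric vector of length N.
#' @export
idft <- function(sp, tol = 1e-9) {
  stopifnot(inherits(sp, "priism_spectrum"))
  co <- sp$coefficients
  n <- sp$N
  mirror <- co[c(1L, n:2L)]
  asym <- max(Mod(co - Conj(mirror)))
  if (asym > tol * max(1, max(Mod(co)))) {
    stop("spectrum is not conjugate-symmetric (residual ", signif(asym, 3),
         "); inverse transform would be complex")
  }
  x <- stats::fft(co, inverse = TRUE) / n
  Re(x)
}

#' @export
print.priism_spectrum <- function(x, ...) {
  cat(sprintf("<priism_spectrum> N = %d, T = %g h, f in [0, %.4g] cycles/h\n",
              x$N, x$sample_interval_h, max(x$frequencies)))
  invisible(x)
}
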