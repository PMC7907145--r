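# Discrete Fourier transform: radix-2 decimation-in-time butterfly for
# power-of-two lengths, direct O(N^2) DFT otherwise, and the per-band
# amplitude summary used as the frequency-domain feature.
#
# The pipeline default window is 200 samples at 500 Hz, which is not a power
# of two; the direct path keeps the bin frequencies at exact multiples of
# 2.5 Hz.  The butterfly path exists for power-of-two lengths and is checked
# against the direct sum.

.dft_cache <- new.env(parent = emptyenv())

dft_matrix <- function(n) {
  key <- as.character(n)
  w <- .dft_cache[[key]]
  if (is.null(w)) {
    k <- 0:(n - 1)
    w <- exp(-2i * pi * outer(k, k) / n)
    .dft_cache[[key]] <- w
  }
  w
}

is_pow2 <- function(n) n >= 1 && bitwAnd(n, n - 1L) == 0L

# iterative radix-2 decimation-in-time FFT (input length must be 2^M)
fft_radix2 <- function(x) {
  n <- length(x)
  if (n == 1L) return(as.complex(x))
  # bit-reversal permutation
  bits <- as.integer(round(log2(n)))
  idx <- 0L
  rev <- integer(n)
  for (i in 0:(n - 1L)) {
    r <- 0L; v <- i
    for (b in seq_len(bits)) { r <- bitwOr(bitwShiftL(r, 1L), bitwAnd(v, 1L)); v <- bitwShiftR(v, 1L) }
    rev[i + 1L] <- r
  }
  y <- as.complex(x)[rev + 1L]
  len <- 2L
  while (len <= n) {
    half <- len %/% 2L
    tw <- exp(-2i * pi * (0:(half - 1L)) / len)
    for (start in seq(1L, n, by = len)) {
      a <- y[start:(start + half - 1L)]
      b <- y[(start + half):(start + len - 1L)] * tw
      y[start:(start + half - 1L)] <- a + b
      y[(start + half):(start + len - 1L)] <- a - b
    }
    len <- len * 2L
  }
  y
}

#' Discrete Fourier spectrum of a real window
#'
#' Computes `X(k) = sum_n x(n) exp(-2i pi n k / N)`, `k = 0..N-1`.  For
#' power-of-two lengths the recursive even/odd (butterfly) decomposition is
#' used; other lengths fall back to the direct DFT sum.
#'
#' @param x numeric vector (length >= 1).
#' @param fs sampling rate in Hz (stored for bin-frequency computation).
#' @return a `spectrum_result`: list with `coefficients` (complex, length N),
#'   `N`, and `fs`.
#' @export
fft_spectrum <- function(x, fs = NA_real_) {
  if (length(x) < 1L) stop_input("empty input")
  n <- length(x)
  coef <- if (is_pow2(n)) fft_radix2(x) else drop(dft_matrix(n) %*% as.complex(x))
  structure(list(coefficients = coef, N = n, fs = fs), class = "spectrum_result")
}

#' Bin indices of a frequency band
#'
#' Integer bins `k >= 1` with `f_lo <= k * fs / N <= f_hi` (DC excluded).
#'
#' @param band a [band_definition()].
#' @param N window length in samples.
#' @param fs sampling rate in Hz.
#' @return integer vector of bin indices (possibly empty).
#' @export
band_bins <- function(band, N, fs) {
  k <- seq_len(floor(N / 2))
  k[k * fs / N >= band$f_lo & k * fs / N <= band$f_hi]
}

#' Mean in-band spectral amplitude
#'
#' The frequency-domain feature: mean of `|X(k)|` over the DFT bins whose
#' frequency falls inside the band (DC excluded).
#'
#' @param spec a `spectrum_result` from [fft_spectrum()] (with `fs` set).
#' @param band a [band_definition()].
#' @return scalar feature value.
#' @export
band_feature <- function(spec, band) {
  stopifnot(inherits(spec, "spectrum_result"))
  if (!is.finite(spec$fs)) stop_input("spectrum has no sampling rate")
  ks <- band_bins(band, spec$N, spec$fs)
  if (length(ks) == 0)
    stop_input(sprintf("band %s [%g, %g] Hz has no DFT bin at resolution %g Hz",
                       band$name, band$f_lo, band$f_hi, spec$fs / spec$N))
  mean(Mod(spec$coefficients[ks + 1L]))
}
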