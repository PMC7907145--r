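# Per-window, per-channel, per-band scalar features: fuzzy entropy of the
# band-filtered window, or mean FFT amplitude over the band's bins.

#' Fuzzy entropy parameters
#'
#' @param m embedding dimension (default 2).
#' @param n similarity-gradient exponent of the fuzzy membership function
#'   (default 2).
#' @param r_rel tolerance as a multiple of the series SD (default 0.25).
#' @param r_abs absolute tolerance; when given it overrides `r_rel`.
#' @return a `fuzzyen_params` list.
#' @export
fuzzyen_params <- function(m = 2L, n = 2, r_rel = 0.25, r_abs = NULL) {
  if (!is_count(m)) stop_input("m must be a positive integer")
  if (!is.numeric(n) || n <= 0) stop_input("n must be > 0")
  if (!is.null(r_abs)) {
    if (r_abs <= 0) stop_input("r_abs must be > 0")
    r_rel <- NA_real_
  } else if (!is.numeric(r_rel) || r_rel <= 0) stop_input("r_rel must be > 0")
  structure(list(m = as.integer(m), n = n, r_rel = r_rel, r_abs = r_abs),
            class = "fuzzyen_params")
}

#' Fuzzy entropy of a time series
#'
#' Measures signal irregularity as the log-ratio of average fuzzy pattern
#' similarity between embedding dimensions `m` and `m + 1`.  Embedding
#' vectors are baseline-removed (each vector has its own mean subtracted),
#' distances are Chebyshev, similarity is `exp(-d^n / r)`, and both averages
#' run over the first `N - m` vectors.  Higher values mean a more irregular
#' (less self-similar) signal.
#'
#' With the default relative tolerance the resolved r is `r_rel * sd(u)`; a constant
#' series (sd 0) returns 0 by convention.
#'
#' @param u numeric vector, length `>= m + 2`.
#' @param params a [fuzzyen_params()].
#' @return non-negative scalar (floored at 0 against `-1e-12` rounding).
#' @export
fuzzy_entropy <- function(u, params = fuzzyen_params()) {
  stopifnot(inherits(params, "fuzzyen_params"))
  N <- length(u)
  if (N < params$m + 2L)
    stop_input(sprintf("series length %d < m + 2 = %d", N, params$m + 2L))
  if (is.null(params$r_abs)) {
    s <- sd(u)
    if (s == 0) return(0)
    r <- params$r_rel * s
  } else r <- params$r_abs
  v <- fuzzyen_cpp(as.numeric(u), params$m, params$n, r)
  if (v < 0 && v > -1e-9) v <- 0  # numerical floor against rounding
  v
}

#' Per-window feature frames
#'
#' One `feature_frame` per window: a channels x bands matrix of scalar
#' features.  The `fuzzyen` path band-filters each window's channels (the
#' filtering is done per trial upstream when using [trial_features()]; here
#' each window is filtered on its own) and computes fuzzy entropy per
#' channel; the `fft` path computes the mean in-band amplitude of the raw
#' window's spectrum per channel and band.
#'
#' @param windows list of `eeg_window` objects from one trial.
#' @param bands list of [band_definition()]s (default [default_bands()]).
#' @param feature_name `"fuzzyen"` or `"fft"`.
#' @param params a [fuzzyen_params()] (fuzzyen path only).
#' @return list of `feature_frame` objects.
#' @export
feature_frames <- function(windows, bands = default_bands(),
                           feature_name = c("fuzzyen", "fft"),
                           params = fuzzyen_params()) {
  feature_name <- match.arg(feature_name)
  nch <- nrow(windows[[1]]$data)
  for (w in windows)
    if (nrow(w$data) != nch) stop_input("inconsistent channel count across windows")
  lapply(windows, function(w) {
    vals <- matrix(NA_real_, nch, length(bands),
                   dimnames = list(NULL, vapply(bands, `[[`, "", "name")))
    for (b in seq_along(bands)) {
      for (ch in seq_len(nch)) {
        vals[ch, b] <- tryCatch({
          if (feature_name == "fuzzyen") {
            xf <- bandpass(w$data[ch, ], bands[[b]], w$sampling_rate)
            fuzzy_entropy(xf, params)
          } else {
            band_feature(fft_spectrum(w$data[ch, ], fs = w$sampling_rate), bands[[b]])
          }
        }, error = function(e) {
          stop_input(sprintf("feature failed at channel %d, window %d, band %s: %s",
                             ch, w$window_index, bands[[b]]$name, conditionMessage(e)))
        })
      }
    }
    structure(list(window_index = w$window_index, values = vals,
                   feature_name = feature_name), class = "feature_frame")
  })
}

#' Fast per-trial feature extraction
#'
#' Equivalent to band-filtering the whole trial once per band (limiting edge
#' artifacts inside windows), cutting sliding windows, and computing the
#' feature per channel/band/window, with the heavy loops in compiled code
#' (fuzzyen) or batched linear algebra (fft).  This is the pipeline path;
#' [feature_frames()] is the reference per-window path.
#'
#' @param trial an `eeg_trial`.
#' @param bands list of [band_definition()]s.
#' @param feature_name `"fuzzyen"` or `"fft"`.
#' @param params a [fuzzyen_params()].
#' @param window,step window length and step in seconds.
#' @return list of `feature_frame` objects (one per window).
#' @export
trial_features <- function(trial, bands = default_bands(),
                           feature_name = c("fuzzyen", "fft"),
                           params = fuzzyen_params(),
                           window = 0.4, step = 0.2) {
  feature_name <- match.arg(feature_name)
  fs <- trial$sampling_rate
  n <- ncol(trial$data)
  wlen <- as.integer(round(window * fs))
  slen <- as.integer(round(step * fs))
  nwin <- floor((n - wlen) / slen) + 1L
  starts <- (seq_len(nwin) - 1L) * slen      # 0-based sample offsets
  nch <- nrow(trial$data)

  if (feature_name == "fuzzyen") {
    filtered <- lapply(bands, function(b) bandpass(trial$data, b, fs))
    cube <- fuzzyen_frames_cpp(filtered, starts, wlen, params$m, params$n,
                               if (is.null(params$r_abs)) params$r_rel else -1,
                               if (is.null(params$r_abs)) -1 else params$r_abs)
    # cube: nch x nbands x nwin
  } else {
    bins <- lapply(bands, band_bins, N = wlen, fs = fs)
    for (b in seq_along(bands)) if (length(bins[[b]]) == 0)
      stop_input(sprintf("band %s has no DFT bin at window length %d", bands[[b]]$name, wlen))
    ks <- unlist(bins)
    w <- exp(-2i * pi * outer(ks, 0:(wlen - 1L)) / wlen)  # needed bins only
    cube <- array(NA_real_, dim = c(nch, length(bands), nwin))
    for (k in seq_len(nwin)) {
      seg <- trial$data[, (starts[k] + 1L):(starts[k] + wlen), drop = FALSE]
      amp <- Mod(w %*% t(seg))                             # bins x channels
      off <- 0L
      for (b in seq_along(bands)) {
        nb <- length(bins[[b]])
        cube[, b, k] <- colMeans(amp[(off + 1L):(off + nb), , drop = FALSE])
        off <- off + nb
      }
    }
  }
  band_names <- vapply(bands, `[[`, "", "name")
  lapply(seq_len(nwin), function(k) {
    vals <- cube[, , k, drop = TRUE]
    if (nch == 1L) vals <- matrix(vals, nrow = 1L)
    colnames(vals) <- band_names
    structure(list(window_index = k - 1L, values = vals,
                   feature_name = feature_name), class = "feature_frame")
  })
}
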