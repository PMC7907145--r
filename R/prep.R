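# Signal preparation: channel pruning, trial segmentation, sliding windows,
# and zero-phase Butterworth band decomposition into theta/alpha/beta.

#' Construct a recording
#'
#' @param subject_id identifier.
#' @param label class label, 0 = control, 1 = patient (NA if unknown).
#' @param channel_labels character vector, one per data row.
#' @param sampling_rate Hz.
#' @param data channels x samples numeric matrix.
#' @return a `recording` object.
#' @export
new_recording <- function(subject_id, label = NA_integer_, channel_labels,
                          sampling_rate, data) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_labels))
    stop_input("row count of data must equal length of channel_labels")
  if (!all(is.finite(data))) stop_input("recording contains non-finite values")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop_input("sampling_rate must be > 0")
  structure(list(subject_id = subject_id, label = label,
                 channel_labels = as.character(channel_labels),
                 sampling_rate = sampling_rate, data = data),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s label=%s: %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$label, nrow(x$data), ncol(x$data), x$sampling_rate))
  invisible(x)
}

#' Frequency band definitions
#'
#' Default sub-bands: theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz.
#'
#' @param name band name.
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @return `band_definition` object / list of the three defaults.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  if (!(f_lo > 0 && f_hi > f_lo)) stop_input("need 0 < f_lo < f_hi")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band_definition")
}

#' @rdname band_definition
#' @export
default_bands <- function() {
  list(band_definition("theta", 4, 7),
       band_definition("alpha", 8, 13),
       band_definition("beta", 14, 30))
}

#' Remove channels from a recording
#'
#' Labels in `drop_labels` that are not present are reported with a warning
#' and ignored (so matrix fixtures without ocular channels still load);
#' channel order of the remaining rows is preserved.
#'
#' @param rec a `recording`.
#' @param drop_labels character vector of labels to remove.
#' @return the pruned `recording`.
#' @export
remove_channels <- function(rec, drop_labels) {
  stopifnot(inherits(rec, "recording"))
  if (length(drop_labels) == 0) return(rec)
  missing <- setdiff(drop_labels, rec$channel_labels)
  if (length(missing))
    warning(sprintf("labels not present (ignored): %s", paste(missing, collapse = ", ")))
  keep <- !(rec$channel_labels %in% drop_labels)
  if (!any(keep)) stop_input("removing these labels would leave an empty recording")
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$channel_labels <- rec$channel_labels[keep]
  rec
}

#' Segment a recording into fixed-length trials
#'
#' Consecutive non-overlapping segments starting at t = 0, truncated to
#' `max_trials`.
#'
#' @param rec a `recording`.
#' @param trial_length seconds (default 1.4).
#' @param max_trials maximum number of trials kept (default 55; `Inf` for all).
#' @return list of `eeg_trial` objects.
#' @export
segment_trials <- function(rec, trial_length = 1.4, max_trials = 55) {
  stopifnot(inherits(rec, "recording"))
  ns <- round(trial_length * rec$sampling_rate)
  if (abs(ns - trial_length * rec$sampling_rate) > 1e-6)
    stop_input("trial_length * sampling_rate must be an integer")
  ns <- as.integer(ns)
  total <- ncol(rec$data)
  if (total < ns) stop_input("recording shorter than one trial")
  n_trials <- min(floor(total / ns), max_trials)
  lapply(seq_len(n_trials), function(i) {
    idx <- ((i - 1L) * ns + 1L):(i * ns)
    structure(list(recording_id = rec$subject_id, trial_index = i - 1L,
                   label = rec$label, channel_labels = rec$channel_labels,
                   data = rec$data[, idx, drop = FALSE],
                   sampling_rate = rec$sampling_rate),
              class = "eeg_trial")
  })
}

#' Cut a trial into overlapping sliding windows
#'
#' Windows start at offsets `0, step, 2*step, ...`; the count is
#' `floor((duration - window) / step) + 1`.  The default 400 ms window with
#' 200 ms step yields 6 windows per 1400 ms trial.
#'
#' @param trial an `eeg_trial` (or any list with `data` and `sampling_rate`).
#' @param window window length in seconds (default 0.4).
#' @param step step between window starts in seconds (default 0.2).
#' @return list of `eeg_window` objects.
#' @export
sliding_windows <- function(trial, window = 0.4, step = 0.2) {
  fs <- trial$sampling_rate
  n <- ncol(trial$data)
  wlen <- as.integer(round(window * fs))
  slen <- as.integer(round(step * fs))
  if (slen <= 0) stop_input("step must be > 0")
  if (wlen > n) stop_input("window longer than trial")
  count <- floor((n - wlen) / slen) + 1L
  lapply(seq_len(count), function(k) {
    idx <- ((k - 1L) * slen + 1L):((k - 1L) * slen + wlen)
    structure(list(window_index = k - 1L,
                   data = trial$data[, idx, drop = FALSE],
                   sampling_rate = fs),
              class = "eeg_window")
  })
}

# ---- Butterworth band-pass (zero phase) -------------------------------------

# Analog Butterworth prototype -> band-pass zpk -> bilinear -> second-order
# sections.  Kept in zero/pole/gain form throughout so that narrow bands at
# low normalised frequency stay numerically well conditioned.
butter_bandpass_sos <- function(f_lo, f_hi, fs, order = 4L) {
  if (!(f_lo > 0 && f_hi > f_lo)) stop_input("need 0 < f_lo < f_hi")
  if (f_hi >= fs / 2) stop_input("band edge at or above Nyquist frequency")
  # analog prototype poles (Butterworth, unit cutoff)
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  gain <- 1
  # pre-warped band edges (bilinear with fs2 = 2*fs)
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * f_lo / fs)
  w2 <- fs2 * tan(pi * f_hi / fs)
  bw <- w2 - w1; w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass in s domain
  ps <- p * bw / 2
  pbp <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
  zbp <- rep(0 + 0i, order)
  gain <- gain * bw^order
  # bilinear transform
  pz <- (fs2 + pbp) / (fs2 - pbp)
  zz <- (fs2 + zbp) / (fs2 - zbp)
  gain <- gain * Re(prod(fs2 - zbp) / prod(fs2 - pbp))
  zz <- c(zz, rep(-1 + 0i, length(pz) - length(zz)))
  # pair conjugate poles into biquads; each section gets one zero at +1 and
  # one at -1 (the band-pass zeros), and an equal share of the gain
  pu <- pz[Im(pz) > 0]
  pu <- pu[order(-abs(pu))]            # poles nearest unit circle first
  nsec <- length(pu)
  g <- abs(gain)^(1 / nsec) * ifelse(gain < 0, NA, 1)
  sos <- matrix(0, nsec, 6)
  for (i in seq_len(nsec)) {
    sos[i, 1:3] <- g * c(1, 0, -1)
    sos[i, 4:6] <- c(1, -2 * Re(pu[i]), abs(pu[i])^2)
  }
  if (gain < 0) sos[1, 1:3] <- -sos[1, 1:3]
  sos
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward ("filtfilt") application of a Butterworth band-pass,
#' designed in zero/pole/gain form and applied as cascaded biquads with
#' odd-reflection edge padding and step steady-state initial conditions, so
#' the output has no phase distortion and unit passband gain.
#'
#' @param x numeric vector, or a channels x samples matrix (filtered per row).
#' @param band a [band_definition()].
#' @param fs sampling rate in Hz.
#' @param order Butterworth prototype order (default 4).
#' @return filtered data, same shape as `x`.
#' @export
bandpass <- function(x, band, fs, order = 4L) {
  stopifnot(inherits(band, "band_definition"))
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  sos <- butter_bandpass_sos(band$f_lo, band$f_hi, fs, order)
  n <- ncol(x)
  if (n <= 3L * (2L * nrow(sos) + 1L))
    stop_input("input shorter than filter warm-up")
  padlen <- min(n - 1L, 30L * nrow(sos))
  y <- sosfiltfilt_mat_cpp(x, sos, padlen)
  if (vec) drop(y) else y
}

#' Frequency response of the band-pass design
#'
#' Complex response H(f) of the (single-pass) Butterworth band-pass at the
#' requested frequencies; the zero-phase filter applies `|H(f)|^2`.
#'
#' @param band a [band_definition()].
#' @param fs sampling rate Hz.
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param order prototype order.
#' @return complex vector of responses.
#' @export
bandpass_response <- function(band, fs, freqs, order = 4L) {
  sos <- butter_bandpass_sos(band$f_lo, band$f_hi, fs, order)
  z <- exp(-1i * 2 * pi * freqs / fs)
  h <- rep(1 + 0i, length(z))
  for (s in seq_len(nrow(sos))) {
    h <- h * (sos[s, 1] + sos[s, 2] * z + sos[s, 3] * z^2) /
      (sos[s, 4] + sos[s, 5] * z + sos[s, 6] * z^2)
  }
  h
}
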