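# Independent oracles used across the suite.  Each implements its target
# definition directly (literal sums, closed forms, brute force) without
# touching the package's optimised code paths.

# Literal fuzzy-entropy: baseline-removed embeddings, Chebyshev distance,
# exponential membership exp(-d^n / r); Phi^m and Phi^{m+1} averaged over
# the first N - m vectors; explicit i/j loops.
fuzzyen_oracle <- function(u, m = 2, n = 2, r = 0.2) {
  N <- length(u)
  phi <- function(mm) {
    nv <- N - m
    emb <- sapply(seq_len(nv), function(i) {
      v <- u[i:(i + mm - 1)]
      v - mean(v)
    })
    if (is.null(dim(emb))) emb <- matrix(emb, nrow = 1)
    tot <- 0
    for (i in seq_len(nv)) {
      s <- 0
      for (j in setdiff(seq_len(nv), i)) {
        d <- max(abs(emb[, i] - emb[, j]))
        s <- s + exp(-(d^n) / r)
      }
      tot <- tot + s / (nv - 1)
    }
    tot / nv
  }
  log(phi(m)) - log(phi(m + 1))
}

# Direct O(N^2) DFT sum.
dft_oracle <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(k)
    sum(x * exp(-2i * pi * (0:(N - 1)) * k / N)), complex(1))
}

# Welch two-sample t statistic and two-tailed p, from the closed form.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# One LSTM step from the gate equations, plain R arithmetic.
lstm_oracle <- function(w, x, h, c) {
  sig <- function(z) 1 / (1 + exp(-z))
  hx <- c(h, x)
  f <- sig(w$lstm_wf %*% hx + w$lstm_bf)
  i <- sig(w$lstm_wi %*% hx + w$lstm_bi)
  g <- tanh(w$lstm_wc %*% hx + w$lstm_bc)
  o <- sig(w$lstm_wo %*% hx + w$lstm_bo)
  cn <- c * f + g * i
  hn <- tanh(cn) * o
  list(h = as.numeric(hn), c = as.numeric(cn))
}

# Layer-size recursion: conv y = (n + 2p - f)/s + 1, pool y = (n - f)/s + 1.
shape_oracle <- function(counts, channels, image_size = 32) {
  side <- image_size
  ch <- 3
  for (s in seq_along(counts)) {
    for (r in seq_len(counts[s])) {
      side <- (side + 2 * 1 - 3) / 1 + 1
      ch <- channels[s]
    }
    side <- (side - 2) / 2 + 1
  }
  c(side = side, channels = ch, flatten = side * side * ch)
}

# Closed-form parameter counts.
param_count_oracle <- function(counts, channels, image_size = 32,
                               fc = 512, hidden = 128) {
  total <- 0
  cin <- 3
  for (s in seq_along(counts)) {
    for (r in seq_len(counts[s])) {
      total <- total + (9 * cin + 1) * channels[s]
      cin <- channels[s]
    }
  }
  flat <- shape_oracle(counts, channels, image_size)[["flatten"]]
  total <- total + fc * (flat + 1)
  total <- total + 4 * (hidden * (hidden + fc) + hidden)
  total + 2 * (hidden + 1)
}

# Small helpers shared by tests.
toy_trial <- function(n_channels = 2, seconds = 1.4, fs = 500, seed = 1) {
  set.seed(seed)
  structure(list(recording_id = "toy", trial_index = 0L, label = 0L,
                 channel_labels = paste0("ch", seq_len(n_channels)),
                 data = matrix(rnorm(n_channels * seconds * fs), n_channels),
                 sampling_rate = fs),
            class = "eeg_trial")
}

random_montage <- function(n = 20, seed = 1) {
  set.seed(seed)
  z <- runif(n, 0.05, 1)
  az <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  new_m <- eegtopoclass:::new_montage(sprintf("E%02d", seq_len(n)),
                                      cbind(r * cos(az), r * sin(az), z))
  aep_project(new_m)
}
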