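# Group-difference topographies: channel-wise Welch t maps with
# Benjamini-Hochberg (FDR) and Bonferroni correction, and a Pearson
# correlation helper.

#' Channel-wise Welch t map between two groups
#'
#' Two-sided Welch (unequal-variance) t test per channel on per-subject
#' feature values, with BH-FDR and Bonferroni significance flags.
#'
#' @param groupA,groupB subjects x channels matrices (same channel sets).
#' @param alpha significance level (default 0.05).
#' @param channel_labels optional labels for the output.
#' @return a `stat_map`: list with per-channel `t`, `p`, `df`, group means,
#'   and logical flags `sig_fdr`, `sig_bonferroni`.
#' @export
t_map <- function(groupA, groupB, alpha = 0.05, channel_labels = NULL) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (ncol(groupA) != ncol(groupB)) stop_input("channel sets differ")
  if (nrow(groupA) < 2 || nrow(groupB) < 2)
    stop_input("need at least 2 subjects per group")
  na <- nrow(groupA); nb <- nrow(groupB)
  ma <- colMeans(groupA); mb <- colMeans(groupB)
  va <- apply(groupA, 2, var); vb <- apply(groupB, 2, var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  zerovar <- se2 == 0
  t[zerovar] <- 0; df[zerovar] <- na + nb - 2
  p <- 2 * pt(-abs(t), df)
  structure(list(t = t, p = p, df = df, mean_a = ma, mean_b = mb,
                 alpha = alpha,
                 sig_fdr = correct_fdr(p, alpha),
                 sig_bonferroni = correct_bonferroni(p, alpha),
                 channel_labels = channel_labels),
            class = "stat_map")
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up procedure: with ordered p-values `p(1) <= ... <= p(m)`, find the
#' largest `i` with `p(i) <= i * q / m`; all hypotheses up to it are
#' declared significant.
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @param q target false discovery rate (default 0.05).
#' @return logical vector of discoveries.
#' @export
correct_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) stop_input("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop_input("p values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  ok <- which(ps <= seq_len(m) * q / m)
  flags <- logical(m)
  if (length(ok)) flags[o[seq_len(max(ok))]] <- TRUE
  flags
}

#' Bonferroni significance flags
#'
#' Flags `p <= alpha / m` with `m` the number of tests.
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @param alpha family-wise level (default 0.05).
#' @return logical vector.
#' @export
correct_bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) stop_input("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop_input("p values must lie in [0, 1]")
  p_values <= alpha / length(p_values)
}

#' Pearson correlation with a t-based p value
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with `r`, `t`, `df`, `p` (two-tailed).
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop_input("need equal-length vectors, n >= 3")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, df = n - 2, p = 2 * pt(-abs(t), n - 2))
}

#' Render a stat map as a topographic grid
#'
#' Interpolates `-log10(p)` (or the t statistic) over the scalp through the
#' topomap machinery, mirroring contrast-map figures.
#'
#' @param sm a `stat_map`.
#' @param montage projected `eeg_montage` whose labels match the map.
#' @param what `"logp"` or `"t"`.
#' @param grid_size mesh side.
#' @return numeric grid matrix.
#' @export
stat_map_grid <- function(sm, montage, what = c("logp", "t"), grid_size = 32L) {
  what <- match.arg(what)
  v <- switch(what, logp = -log10(pmax(sm$p, 1e-300)), t = sm$t)
  interpolate_grid(montage$pos2d, v, grid_size)
}
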