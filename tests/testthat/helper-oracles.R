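# Independent brute-force oracles, written against the printed formulas and
# kept free of any package internals.

oracle_mcc <- function(tp, tn, fp, fn) {
  (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
}

oracle_wmean <- function(x, w) {
  num <- 0
  den <- 0
  for (i in seq_along(x)) {
    num <- num + w[i] * x[i]
    den <- den + w[i]
  }
  num / den
}

oracle_wcov <- function(x, y, w) {
  mx <- oracle_wmean(x, w)
  my <- oracle_wmean(y, w)
  num <- 0
  den <- 0
  for (i in seq_along(x)) {
    num <- num + w[i] * (x[i] - mx) * (y[i] - my)
    den <- den + w[i]
  }
  num / den
}

oracle_wcc <- function(x, y, w) {
  oracle_wcov(x, y, w) / sqrt(oracle_wcov(x, x, w) * oracle_wcov(y, y, w))
}

oracle_wmse <- function(x, y, w) {
  num <- 0
  den <- 0
  for (i in seq_along(x)) {
    num <- num + w[i] * (y[i] - x[i])^2
    den <- den + w[i]
  }
  num / den
}

oracle_anova_f <- function(x, y) {
  # one-way ANOVA F by explicit sums over the two groups
  groups <- split(x, y)
  n <- length(x)
  g <- length(groups)
  grand <- mean(x)
  ssb <- 0
  ssw <- 0
  for (gr in groups) {
    ssb <- ssb + length(gr) * (mean(gr) - grand)^2
    ssw <- ssw + sum((gr - mean(gr))^2)
  }
  (ssb / (g - 1)) / (ssw / (n - g))
}

# analytic bin means of A*sin(2*pi*f*t - phase) + offset over [a, b]
oracle_sine_bin_mean <- function(A, f, phase, offset, a, b) {
  (-A / (2 * pi * f)) * (cos(2 * pi * f * b - phase) - cos(2 * pi * f * a - phase)) /
    (b - a) + offset
}

# quiet background with enough structure to define zero crossings
carrier_signal <- function(duration_s, fs, amp = 1, freq = 0.5) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq * t)
}

# plant a biphasic SO pulse (negative then positive half-sine) at t_trough
plant_pulse <- function(x, fs, t_trough, trough_uv = -100, hw = 0.5,
                        pos_frac = 0.5, pos_dur = 0.45) {
  n_neg <- round(hw * fs)
  n_pos <- round(pos_dur * fs)
  pulse <- c(
    trough_uv * sin(pi * seq_len(n_neg) / (n_neg + 1)),
    -pos_frac * trough_uv * sin(pi * seq_len(n_pos) / (n_pos + 1))
  )
  onset <- round((t_trough - hw / 2) * fs)
  ix <- onset + seq_along(pulse)
  ok <- ix >= 1 & ix <= length(x)
  x[ix[ok]] <- x[ix[ok]] + pulse[ok]
  x
}

make_recording <- function(signals, fs, stage = "SWS") {
  n_epochs <- ceiling(ncol(signals) / (30 * fs))
  eeg_recording(signals, fs, hypnogram = rep(stage, n_epochs))
}

# fraction of planted deflections recovered / emitted events matching truth
match_events <- function(events, truth, tol = 0.15) {
  recall <- vapply(seq_len(nrow(truth)), function(i) {
    any(events$channel == truth$channel[i] &
      abs(events$t_trough - truth$t_trough[i]) <= tol)
  }, logical(1))
  precision <- vapply(seq_len(nrow(events)), function(i) {
    any(truth$channel == events$channel[i] &
      abs(truth$t_trough - events$t_trough[i]) <= tol)
  }, logical(1))
  list(recall = mean(recall), precision = mean(precision))
}

# best assignment agreement between cluster labels and ground truth for k=3
label_match_agreement <- function(assign, truth_id) {
  perms <- list(
    c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
  )
  max(vapply(perms, function(p) mean(p[assign] == truth_id), numeric(1)))
}
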