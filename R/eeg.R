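#' Multichannel stage-scored sleep EEG recording
#'
#' The container for raw or filtered sleep EEG: a channels-by-samples
#' signal matrix in microvolts, its sampling rate, a per-30-s-epoch
#' hypnogram and optional scorer-marked artifact epochs. Signals are
#' assumed referenced (e.g., to contralateral mastoids) before entry; if
#' mastoid channels (A1/A2, M1/M2) are present a warning notes that no
#' re-referencing is applied automatically.
#'
#' @param signals Numeric matrix, channels x samples, microvolts, finite.
#' @param fs Sampling rate in Hz.
#' @param channel_names Channel labels, one per row of `signals` (default
#'   taken from `rownames(signals)`).
#' @param hypnogram Character vector of stage labels in
#'   `{Wake, S1, S2, SWS, REM}`, one per 30-s epoch
#'   (`ceiling(samples / (30 * fs))` entries).
#' @param excluded_epochs Logical vector, one per epoch, `TRUE` where the
#'   scorer marked an artifact (default all `FALSE`).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signals, fs, channel_names = rownames(signals),
                          hypnogram, excluded_epochs = NULL) {
  signals <- as.matrix(signals)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop_sostim("fs must be a single positive number")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(signals)))
  }
  if (length(channel_names) != nrow(signals)) {
    stop_sostim(
      "%d channel names for %d signal rows",
      length(channel_names), nrow(signals)
    )
  }
  if (!all(is.finite(signals))) stop_sostim("signal values must all be finite")
  n_epochs <- ceiling(ncol(signals) / (30 * fs))
  stages <- c("Wake", "S1", "S2", "SWS", "REM")
  hypnogram <- as.character(hypnogram)
  if (length(hypnogram) != n_epochs) {
    stop_sostim(
      "hypnogram has %d epochs; recording spans %d 30-s epochs",
      length(hypnogram), n_epochs
    )
  }
  if (!all(hypnogram %in% stages)) {
    stop_sostim(
      "unknown stage label(s): %s",
      paste(setdiff(unique(hypnogram), stages), collapse = ", ")
    )
  }
  if (is.null(excluded_epochs)) excluded_epochs <- rep(FALSE, n_epochs)
  if (length(excluded_epochs) != n_epochs || !is.logical(excluded_epochs)) {
    stop_sostim("excluded_epochs must be logical with one entry per epoch")
  }
  if (any(channel_names %in% c("A1", "A2", "M1", "M2"))) {
    rlang::warn(paste(
      "mastoid channels present; signals are assumed already referenced -",
      "no automatic re-referencing is applied"
    ))
  }
  rownames(signals) <- channel_names
  structure(
    list(
      signals = signals, fs = fs, channel_names = channel_names,
      hypnogram = hypnogram, excluded_epochs = excluded_epochs
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(
    "<eeg_recording>", nrow(x$signals), "channels x", ncol(x$signals),
    "samples @", x$fs, "Hz (", round(ncol(x$signals) / x$fs / 60, 1),
    "min ),", length(x$hypnogram), "epochs\n"
  )
  invisible(x)
}

eeg_duration <- function(rec) ncol(rec$signals) / rec$fs

#' Zero-phase band-pass filter for slow-oscillation detection
#'
#' Applies a second-order Butterworth band-pass (default 0.1-4 Hz) forwards
#' and backwards (`signal::filtfilt`) to every channel, removing DC and
#' fast activity without phase distortion.
#'
#' @param rec An `eeg_recording`.
#' @param band Passband in Hz, strictly inside (0, fs/2).
#' @param order Butterworth order (default 2; applied twice by filtfilt).
#' @return The recording with filtered signals; the band is recorded in the
#'   `band` attribute.
#' @export
filter_slow <- function(rec, band = c(0.1, 4), order = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_band(band, rec$fs)
  bf <- signal::butter(order, band / (rec$fs / 2), type = "pass")
  out <- rec
  out$signals <- t(apply(rec$signals, 1, function(x) {
    signal::filtfilt(bf, x)
  }))
  rownames(out$signals) <- rec$channel_names
  attr(out, "band") <- band
  out
}

check_band <- function(band, fs) {
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2] ||
    band[2] >= fs / 2) {
    stop_sostim(
      "band must satisfy 0 < low < high < fs/2 = %g Hz; got [%s]",
      fs / 2, paste(band, collapse = ", ")
    )
  }
  invisible(band)
}

# band-limited per-bin signal amplitude (default RMS), channels x bins
bin_band_power <- function(rec, band, bin_s,
                           measure = c("rms", "variance", "sum_abs")) {
  measure <- match.arg(measure)
  check_band(band, rec$fs)
  bf <- signal::butter(4, band / (rec$fs / 2), type = "pass")
  spb <- as.integer(round(bin_s * rec$fs))
  n_bins <- floor(ncol(rec$signals) / spb)
  if (n_bins == 0) stop_sostim("recording shorter than one %g-s bin", bin_s)
  P <- matrix(0, nrow(rec$signals), n_bins,
    dimnames = list(rec$channel_names, NULL)
  )
  for (i in seq_len(nrow(rec$signals))) {
    xf <- signal::filtfilt(bf, rec$signals[i, ])
    xb <- matrix(xf[seq_len(n_bins * spb)], nrow = spb)
    P[i, ] <- switch(measure,
      rms = sqrt(colMeans(xb^2)),
      variance = apply(xb, 2, stats::var),
      sum_abs = colSums(abs(xb))
    )
  }
  structure(P, bin_s = bin_s)
}

#' Muscle-artifact masks
#'
#' Two standard high-frequency artifact screens, computed per channel on
#' the unfiltered recording. `brunner_mask()` band-passes at 26.25-32 Hz,
#' splits the signal into 4-s bins and flags bins whose amplitude exceeds
#' 4 times the median of the 45 surrounding bins (about 3 min; at record
#' edges the available part of the window is used, minimum 11 bins).
#' `wang_mask()` band-passes at 4-50 Hz, uses 5-s bins and flags bins
#' exceeding 6 times the median over all bins of the channel. A zero
#' median never flags (all-quiet records produce empty masks). Bin
#' amplitude is RMS by default.
#'
#' @param rec An `eeg_recording` (raw, not slow-filtered).
#' @param measure Bin amplitude summary: `"rms"` (default), `"variance"`
#'   or `"sum_abs"`.
#' @return Logical matrix channels x bins with attribute `bin_s`.
#' @export
brunner_mask <- function(rec, measure = "rms") {
  P <- bin_band_power(rec, band = c(26.25, 32), bin_s = 4, measure = measure)
  n_bins <- ncol(P)
  half <- 22 # 45-bin window, centred
  M <- matrix(FALSE, nrow(P), n_bins, dimnames = dimnames(P))
  for (b in seq_len(n_bins)) {
    win <- max(1, b - half):min(n_bins, b + half)
    meds <- apply(P[, win, drop = FALSE], 1, stats::median)
    M[, b] <- meds > 0 & P[, b] > 4 * meds
  }
  structure(M, bin_s = 4)
}

#' @rdname brunner_mask
#' @export
wang_mask <- function(rec, measure = "rms") {
  P <- bin_band_power(rec, band = c(4, 50), bin_s = 5, measure = measure)
  meds <- apply(P, 1, stats::median)
  M <- sweep(P, 1, 6 * meds, `>`) & meds > 0
  structure(M, bin_s = 5)
}

# TRUE where the [t0, t1] interval of `channel` touches a flagged bin
mask_overlaps <- function(mask, channel, t0, t1) {
  bin_s <- attr(mask, "bin_s")
  b0 <- pmax(1, floor(t0 / bin_s) + 1)
  b1 <- pmin(ncol(mask), floor(t1 / bin_s) + 1)
  vapply(seq_along(t0), function(i) {
    if (b0[i] > b1[i]) {
      return(FALSE) # interval beyond the binned extent
    }
    any(mask[channel[i], b0[i]:b1[i]])
  }, logical(1))
}
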