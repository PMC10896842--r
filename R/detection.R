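#' Slow-oscillation detection parameters
#'
#' Thresholds for the amplitude/duration detection criteria and the
#' artifact screens. Defaults follow the established SO-detection
#' convention for NREM sleep EEG:
#' * the trough must reach -80 uV or deeper (`trough_max`);
#' * the max-minus-min range over the event must be at least 80 uV
#'   (`min_range`);
#' * the negative half-wave (first to second zero crossing) must last
#'   300-1000 ms (`half_wave_bounds`);
#' * the whole event may last at most 10 s (`max_duration`).
#' Detected events are further screened by a two-pass amplitude-outlier
#' rule (`outlier_sd` standard deviations above the mean of trough
#' amplitudes referenced to the mean signal within `ref_halfwindow`
#' seconds of the trough).
#'
#' @param band Detection filter passband in Hz.
#' @param trough_max Maximum (most positive) admissible trough amplitude,
#'   microvolts (negative).
#' @param min_range Minimum peak-to-peak range over the event, microvolts.
#' @param half_wave_bounds Admissible negative-half-wave duration, seconds.
#' @param max_duration Maximum event duration, seconds.
#' @param outlier_sd Outlier screening threshold in SD units.
#' @param ref_halfwindow Half-width of the trough-referencing window,
#'   seconds.
#' @param codetect_delay Co-detection delay used downstream, seconds.
#' @param edge_s Seconds excluded from candidate search at each record edge
#'   (filter settling).
#' @param power_measure Bin amplitude summary for the artifact masks.
#' @return A list of class `so_detection_params`.
#' @export
so_detection_params <- function(band = c(0.1, 4), trough_max = -80,
                                min_range = 80,
                                half_wave_bounds = c(0.3, 1.0),
                                max_duration = 10, outlier_sd = 4,
                                ref_halfwindow = 10, codetect_delay = 0.4,
                                edge_s = 2, power_measure = "rms") {
  stopifnot(
    band[1] < band[2], trough_max < 0, min_range > 0,
    half_wave_bounds[1] < half_wave_bounds[2], max_duration > 0,
    outlier_sd > 0, ref_halfwindow > 0, codetect_delay > 0
  )
  structure(
    list(
      band = band, trough_max = trough_max, min_range = min_range,
      half_wave_bounds = half_wave_bounds, max_duration = max_duration,
      outlier_sd = outlier_sd, ref_halfwindow = ref_halfwindow,
      codetect_delay = codetect_delay, edge_s = edge_s,
      power_measure = power_measure
    ),
    class = "so_detection_params"
  )
}

# candidate events on one filtered channel signal; times in seconds, 0-based
channel_candidates <- function(x, fs, edge_s) {
  n <- length(x)
  p2n <- which(x[-n] > 0 & x[-1] <= 0) + 1 # first sample at/below zero
  n2p <- which(x[-n] < 0 & x[-1] >= 0) + 1 # first sample at/above zero
  if (length(p2n) < 2 || length(n2p) == 0) {
    return(NULL)
  }
  out <- vector("list", length(p2n))
  for (i in seq_along(p2n)) {
    s0 <- p2n[i]
    j <- n2p[n2p > s0]
    if (length(j) == 0) next
    s1 <- j[1]
    k <- p2n[p2n > s1]
    if (length(k) == 0) next
    s2 <- k[1]
    tr <- s0 - 1 + which.min(x[s0:(s1 - 1)])
    out[[i]] <- c(s0 = s0, s1 = s1, s2 = s2, tr = tr)
  }
  cand <- do.call(rbind, out)
  if (is.null(cand)) {
    return(NULL)
  }
  lo <- edge_s * fs + 1
  hi <- n - edge_s * fs
  cand[cand[, "s0"] >= lo & cand[, "s2"] <= hi, , drop = FALSE]
}

#' Detect slow oscillations in stage-scored sleep EEG
#'
#' Per channel independently: the recording is zero-phase band-pass
#' filtered (default 0.1-4 Hz) and candidate events are taken as segments
#' from a positive-to-negative zero crossing, through the negative
#' half-wave, to the next positive-to-negative crossing. Candidates must
#' satisfy the four amplitude/duration criteria (see
#' [so_detection_params()]); events overlapping scorer-excluded epochs or
#' bins flagged by [brunner_mask()]/[wang_mask()] are discarded; two-pass
#' amplitude-outlier screening is applied ([screen_outliers()]); and only
#' events whose start and end both lie in epochs scored as the requested
#' stage are kept.
#'
#' @param rec An `eeg_recording` (raw; filtering and artifact masking are
#'   internal).
#' @param params An `so_detection_params`.
#' @param stage Sleep stage to detect in: `"SWS"` or `"S2"`.
#' @return Tibble of events sorted by trough time, with columns `channel`,
#'   `t_start`, `t_trough`, `t_mid`, `t_end` (seconds), `trough_amp`,
#'   `range_amp` (microvolts) and `stage`.
#' @export
detect_sos <- function(rec, params = so_detection_params(), stage = "SWS") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(length(stage) == 1 && stage %in% c("S2", "SWS"))) {
    stop_sostim("stage must be \"S2\" or \"SWS\"")
  }
  empty <- tibble::tibble(
    channel = character(), t_start = numeric(), t_trough = numeric(),
    t_mid = numeric(), t_end = numeric(), trough_amp = numeric(),
    range_amp = numeric(), stage = character()
  )
  fs <- rec$fs
  if (ncol(rec$signals) < (2 * params$edge_s + 1) * fs) {
    return(empty)
  }
  filt <- filter_slow(rec, params$band)
  bmask <- brunner_mask(rec, measure = params$power_measure)
  wmask <- wang_mask(rec, measure = params$power_measure)

  rows <- lapply(rec$channel_names, function(ch) {
    x <- filt$signals[ch, ]
    cand <- channel_candidates(x, fs, params$edge_s)
    if (is.null(cand) || nrow(cand) == 0) {
      return(NULL)
    }
    t_start <- (cand[, "s0"] - 1) / fs
    t_mid <- (cand[, "s1"] - 1) / fs
    t_end <- (cand[, "s2"] - 1) / fs
    t_trough <- (cand[, "tr"] - 1) / fs
    trough_amp <- x[cand[, "tr"]]
    range_amp <- vapply(seq_len(nrow(cand)), function(i) {
      seg <- x[cand[i, "s0"]:cand[i, "s2"]]
      max(seg) - min(seg)
    }, numeric(1))
    keep <- trough_amp <= params$trough_max &
      range_amp >= params$min_range &
      (t_mid - t_start) >= params$half_wave_bounds[1] &
      (t_mid - t_start) <= params$half_wave_bounds[2] &
      (t_end - t_start) <= params$max_duration
    if (!any(keep)) {
      return(NULL)
    }
    tibble::tibble(
      channel = ch, t_start = t_start[keep], t_trough = t_trough[keep],
      t_mid = t_mid[keep], t_end = t_end[keep],
      trough_amp = trough_amp[keep], range_amp = range_amp[keep]
    )
  })
  ev <- dplyr::bind_rows(rows)
  if (nrow(ev) == 0) {
    return(empty)
  }

  # artifact exclusions: scorer epochs, then the two muscle-artifact masks
  ep0 <- floor(ev$t_start / 30) + 1
  ep1 <- floor(ev$t_end / 30) + 1
  excl <- vapply(seq_len(nrow(ev)), function(i) {
    any(rec$excluded_epochs[ep0[i]:ep1[i]])
  }, logical(1))
  ev <- ev[!excl &
    !mask_overlaps(bmask, ev$channel, ev$t_start, ev$t_end) &
    !mask_overlaps(wmask, ev$channel, ev$t_start, ev$t_end), ]
  if (nrow(ev) == 0) {
    return(empty)
  }

  # stage containment: epochs covering both endpoints carry the stage label
  ev$stage <- rec$hypnogram[pmin(floor(ev$t_start / 30) + 1, length(rec$hypnogram))]
  stage_end <- rec$hypnogram[pmin(floor(ev$t_end / 30) + 1, length(rec$hypnogram))]
  ev <- ev[ev$stage == stage & stage_end == stage, ]
  if (nrow(ev) == 0) {
    return(empty)
  }

  ev <- screen_outliers(ev, filt, params)
  dplyr::arrange(ev, .data$t_trough)
}

#' Two-pass amplitude-outlier screening of detected events
#'
#' For every event the trough amplitude is referenced to the mean of the
#' (filtered) signal within +/- `ref_halfwindow` seconds of the trough;
#' the screening statistic is the magnitude of that referenced amplitude.
#' Pass 1 discards, per electrode, events exceeding the electrode's mean
#' by more than `outlier_sd` standard deviations (electrodes with a single
#' event are left unscreened, the SD being undefined); pass 2 repeats the
#' rule on the survivors pooled across electrodes. The referenced
#' amplitude is used for screening only; reported event fields are
#' unchanged.
#'
#' @param events Event tibble as returned by the detection step.
#' @param rec The band-pass filtered `eeg_recording` the events came from.
#' @param params An `so_detection_params`.
#' @return The surviving subset of `events`.
#' @export
screen_outliers <- function(events, rec, params = so_detection_params()) {
  if (nrow(events) == 0) {
    return(events)
  }
  fs <- rec$fs
  n <- ncol(rec$signals)
  half <- as.integer(round(params$ref_halfwindow * fs))
  size <- vapply(seq_len(nrow(events)), function(i) {
    s <- as.integer(round(events$t_trough[i] * fs)) + 1
    win <- max(1, s - half):min(n, s + half)
    abs(events$trough_amp[i] - mean(rec$signals[events$channel[i], win]))
  }, numeric(1))

  flag_outliers <- function(v) {
    if (length(v) < 2) {
      return(rep(FALSE, length(v)))
    }
    v > mean(v) + params$outlier_sd * stats::sd(v)
  }
  keep1 <- !stats::ave(size, events$channel, FUN = flag_outliers)
  events <- events[as.logical(keep1), ]
  size <- size[as.logical(keep1)]
  if (nrow(events) == 0) {
    return(events)
  }
  events[!flag_outliers(size), ]
}
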