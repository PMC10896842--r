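#' Default synthetic scalp montage: 16 channels, half frontal, half posterior
#'
#' @return List with `channels`, `frontal`, `posterior`.
#' @export
synth_channel_set <- function() {
  frontal <- c("Fp1", "Fp2", "AF3", "AF4", "F3", "F4", "F7", "F8")
  posterior <- c("P3", "P4", "P7", "P8", "PO3", "PO4", "O1", "O2")
  list(
    channels = c(frontal, posterior),
    frontal = frontal, posterior = posterior
  )
}

# 1/f-shaped background noise via spectral shaping of white noise
pink_noise <- function(n, fs, rms) {
  z <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)
  shape <- 1 / sqrt(pmax(f_fold, 0.3)) # flatten below 0.3 Hz to bound drift
  shape[1] <- 0 # no DC
  x <- Re(stats::fft(stats::fft(z) * shape, inverse = TRUE)) / n
  x * rms / sqrt(mean(x^2))
}

# biphasic SO pulse: negative half-sine (duration hw) then positive half-sine
so_pulse <- function(fs, trough_uv, hw = 0.5, pos_frac = 0.55, pos_dur = 0.45) {
  n_neg <- round(hw * fs)
  n_pos <- round(pos_dur * fs)
  c(
    trough_uv * sin(pi * seq_len(n_neg) / (n_neg + 1)),
    -pos_frac * trough_uv * sin(pi * seq_len(n_pos) / (n_pos + 1))
  )
}

#' Generate synthetic sleep EEG with planted slow oscillations
#'
#' Multichannel EEG emulating the features the detection and clustering
#' pipeline relies on: 1/f-like background noise plus planted biphasic SO
#' events of three spatial types. `global` events appear on every channel
#' with per-channel delays spanning at most `global_delay_spread` seconds
#' (within the 400 ms co-detection window); `frontal` events appear on the
#' frontal channels only; `local` events on one seed channel and its two
#' nearest neighbours. By default the three types are equally frequent, so
#' global events make up about one third of events and the global:non-global
#' label ratio is about 1:2.
#'
#' @param n_channels Number of channels (default 16, half frontal/half
#'   posterior; see [synth_channel_set()]).
#' @param duration_s Recording length in seconds (default 240).
#' @param fs Sampling rate in Hz (default 128).
#' @param events_per_min Planted event rate per minute (default 5).
#' @param type_mix Probabilities of (global, frontal, local) types.
#' @param global_delay_spread Max spread of per-channel trough delays for
#'   widespread events, seconds (default 0.3).
#' @param trough_uv Nominal trough amplitude, microvolts (default -120).
#' @param half_wave_s Negative half-wave duration, seconds (default 0.5).
#' @param noise_rms Background noise RMS, microvolts (default 12).
#' @param amp_jitter Relative per-channel amplitude jitter (default 0.15).
#' @param stage Stage label written to the hypnogram (default `"SWS"`).
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @return A list of class `synth_eeg`: `recording` (an `eeg_recording`),
#'   `truth` (tibble of planted per-channel deflections: `event_id`,
#'   `type`, `channel`, `t_trough`, `trough_uv`), `events` (one row per
#'   planted event), `frontal`, `posterior`.
#' @export
synth_eeg <- function(n_channels = 16, duration_s = 240, fs = 128,
                      events_per_min = 5,
                      type_mix = c(global = 1 / 3, frontal = 1 / 3, local = 1 / 3),
                      global_delay_spread = 0.3, trough_uv = -120,
                      half_wave_s = 0.5, noise_rms = 12, amp_jitter = 0.15,
                      stage = "SWS", seed = NULL) {
  chans <- synth_channel_set()
  if (n_channels != length(chans$channels)) {
    if (n_channels < 4 || n_channels %% 2 != 0) {
      stop_sostim("n_channels must be an even number >= 4")
    }
    half <- n_channels / 2
    chans <- list(
      channels = c(chans$frontal[seq_len(half)], chans$posterior[seq_len(half)]),
      frontal = chans$frontal[seq_len(half)],
      posterior = chans$posterior[seq_len(half)]
    )
  }
  stopifnot(abs(sum(type_mix) - 1) < 1e-8, fs > 8, trough_uv < 0)
  n <- round(duration_s * fs)
  n_events <- round(events_per_min * duration_s / 60)
  margin <- 12 # keep events clear of edges and reference windows
  min_gap <- 4
  spacing <- (duration_s - 2 * margin) / max(n_events, 1)
  if (n_events > 0 && spacing < min_gap) {
    stop_sostim(
      "event rate too high: %d events need %.1f s spacing, have %.1f s",
      n_events, min_gap, spacing
    )
  }
  layout <- scalp_electrodes()
  pos <- layout[match(chans$channels, layout$name), c("x", "y")]

  with_seed(seed, {
    sig <- t(vapply(
      seq_len(n_channels), function(i) pink_noise(n, fs, noise_rms),
      numeric(n)
    ))
    rownames(sig) <- chans$channels
    truth <- list()
    events <- list()
    if (n_events > 0) {
      t0 <- margin + (seq_len(n_events) - 1) * spacing +
        stats::runif(n_events, 0, max(spacing - min_gap, 0))
      types <- sample(names(type_mix), n_events, replace = TRUE, prob = type_mix)
      for (e in seq_len(n_events)) {
        on_ch <- switch(types[e],
          global = seq_len(n_channels),
          frontal = match(chans$frontal, chans$channels),
          local = {
            seed_ch <- sample.int(n_channels, 1)
            d <- (pos$x - pos$x[seed_ch])^2 + (pos$y - pos$y[seed_ch])^2
            order(d)[1:3]
          }
        )
        delays <- stats::runif(
          length(on_ch), -global_delay_spread / 2, global_delay_spread / 2
        )
        amps <- trough_uv * stats::runif(
          length(on_ch), 1 - amp_jitter, 1 + amp_jitter
        )
        for (j in seq_along(on_ch)) {
          pulse <- so_pulse(fs, amps[j], hw = half_wave_s)
          onset <- round((t0[e] + delays[j] - half_wave_s / 2) * fs)
          ix <- onset + seq_along(pulse)
          ok <- ix >= 1 & ix <= n
          sig[on_ch[j], ix[ok]] <- sig[on_ch[j], ix[ok]] + pulse[ok]
          truth[[length(truth) + 1]] <- tibble::tibble(
            event_id = e, type = types[e],
            channel = chans$channels[on_ch[j]],
            t_trough = t0[e] + delays[j], trough_uv = amps[j]
          )
        }
        events[[e]] <- tibble::tibble(
          event_id = e, type = types[e], t_trough = t0[e],
          n_channels = length(on_ch)
        )
      }
    }
    n_epochs <- ceiling(n / (30 * fs))
    rec <- eeg_recording(
      sig, fs,
      channel_names = chans$channels,
      hypnogram = rep(stage, n_epochs)
    )
    structure(
      list(
        recording = rec, truth = dplyr::bind_rows(truth),
        events = dplyr::bind_rows(events), frontal = chans$frontal,
        posterior = chans$posterior, seed = seed
      ),
      class = "synth_eeg"
    )
  })
}

#' @export
print.synth_eeg <- function(x, ...) {
  cat(
    "<synth_eeg>", nrow(x$recording$signals), "channels,",
    nrow(x$events), "planted events (",
    paste(names(table(x$events$type)), table(x$events$type),
      sep = ":", collapse = ", "
    ), ")\n"
  )
  invisible(x)
}

#' Generate a labeled synthetic current-density dataset
#'
#' Emulates the discriminative structure of global vs non-global SO current
#' densities: every observation is a shared SO-like time-by-region profile
#' plus i.i.d. Gaussian noise; the global class additionally receives a
#' mean shift of `effect` noise-SD units on the features within
#' `effect_window_ms` of the trough in the `effect_regions` (class
#' separation concentrated near the trough, as in real global SOs). The
#' default class sizes give the 1:2 global:non-global imbalance typical of
#' sleep data.
#'
#' @param n_global,n_nonglobal Observations per class (defaults 150/300).
#' @param dt_ms Time-bin width (default 100).
#' @param effect Class-mean shift in noise-SD units (default 3; 0 gives an
#'   uninformative dataset).
#' @param noise_sd Feature noise SD (default 1).
#' @param regions Region labels (default [so_regions()]).
#' @param effect_regions Regions carrying the class difference.
#' @param effect_window_ms Half-width of the discriminative time window
#'   around the trough, ms (default 100).
#' @param seed Integer seed.
#' @return List of class `synth_cd`: `X` (observations x features, flattened
#'   time-major), `y` (factor global/non_global), `dt_ms`, `regions`,
#'   `effect_mask` (logical per feature), `feature_grid`.
#' @export
synth_cd_dataset <- function(n_global = 150, n_nonglobal = 300, dt_ms = 100,
                             effect = 3, noise_sd = 1,
                             regions = so_regions(),
                             effect_regions = c(
                               "cortex_L", "cortex_R", "thalamus_L",
                               "thalamus_R", "hippocampus_L", "hippocampus_R"
                             ),
                             effect_window_ms = 100, seed = NULL) {
  check_dt(dt_ms)
  stopifnot(n_global >= 10, n_nonglobal >= 10, effect >= 0, noise_sd > 0)
  grid <- cd_feature_grid(dt_ms, regions)
  n_feat <- nrow(grid)
  mask <- abs(grid$time_ms) <= effect_window_ms & grid$region %in% effect_regions
  # shared SO-like temporal dip, scaled per region
  base_t <- -exp(-(grid$time_ms / 200)^2)
  region_load <- stats::setNames(
    0.5 + 0.5 * (seq_along(regions) %% 5) / 4, regions
  )
  base <- base_t * region_load[grid$region]
  k <- n_global + n_nonglobal
  with_seed(seed, {
    X <- matrix(base, k, n_feat, byrow = TRUE) +
      matrix(stats::rnorm(k * n_feat, sd = noise_sd), k, n_feat)
    X[seq_len(n_global), mask] <- X[seq_len(n_global), mask] + effect * noise_sd
    colnames(X) <- grid$name
    y <- factor(rep(c("global", "non_global"), c(n_global, n_nonglobal)),
      levels = c("global", "non_global")
    )
    perm <- sample.int(k)
    structure(
      list(
        X = X[perm, , drop = FALSE], y = y[perm], dt_ms = dt_ms,
        regions = regions, effect_mask = mask, feature_grid = grid
      ),
      class = "synth_cd"
    )
  })
}

#' Synthesize a labeled CD dataset anchored to a target paradigm
#'
#' Used by the end-to-end pipeline as a stand-in for per-event source
#' estimation: the global class consists of amplitude-jittered noisy copies
#' of the target CD (the average global-SO profile), while the non-global
#' class consists of CDs elicited by decoy paradigms (random admissible
#' sine waveforms on other montages) with matching jitter and noise. The
#' classifier trained on this set separates the target's time-by-region
#' signature from what other montages can produce.
#'
#' @param target A `cd_matrix` (the global-SO average).
#' @param tm A `transfer_model`.
#' @param decoy_montages List of `so_montage` objects used for the
#'   non-global class.
#' @param n_global,n_nonglobal Class sizes (default 60/120, keeping the 1:2
#'   imbalance).
#' @param amp_jitter Relative amplitude jitter (default 0.2).
#' @param noise_frac Additive noise SD as a fraction of the target's
#'   feature SD (default 0.2).
#' @param seed Integer seed.
#' @return Same shape as [synth_cd_dataset()] (class `synth_cd`).
#' @export
synth_cd_paradigms <- function(target, tm, decoy_montages,
                               n_global = 60, n_nonglobal = 120,
                               amp_jitter = 0.2, noise_frac = 0.2,
                               seed = NULL) {
  stopifnot(inherits(target, "cd_matrix"), length(decoy_montages) > 0)
  dt_ms <- cd_dt(target)
  regions <- cd_region_names(target)
  tgt <- cd_flatten(target)
  sd_t <- stats::sd(tgt)
  bounds <- waveform_bounds("sine")
  k <- n_global + n_nonglobal
  with_seed(seed, {
    G <- matrix(tgt, n_global, length(tgt), byrow = TRUE) *
      stats::runif(n_global, 1 - amp_jitter, 1 + amp_jitter)
    NG <- t(vapply(seq_len(n_nonglobal), function(i) {
      m <- decoy_montages[[sample.int(length(decoy_montages), 1)]]
      par <- stats::runif(nrow(bounds), bounds$lower, bounds$upper)
      p <- paradigm(m, waveform("sine", par), dt_ms)
      v <- cd_flatten(estimate_paradigm_cd(p, tm, resolution = 1e-3))
      # scale decoys to the target's overall magnitude so amplitude alone
      # cannot separate the classes
      v * sd_t / max(stats::sd(v), 1e-9) *
        stats::runif(1, 1 - amp_jitter, 1 + amp_jitter)
    }, numeric(length(tgt))))
    X <- rbind(G, NG) +
      matrix(stats::rnorm(k * length(tgt), sd = noise_frac * sd_t),
        k, length(tgt)
      )
    colnames(X) <- names(tgt)
    y <- factor(rep(c("global", "non_global"), c(n_global, n_nonglobal)),
      levels = c("global", "non_global")
    )
    perm <- sample.int(k)
    structure(
      list(
        X = X[perm, , drop = FALSE], y = y[perm], dt_ms = dt_ms,
        regions = regions, feature_grid = cd_feature_grid(dt_ms, regions)
      ),
      class = "synth_cd"
    )
  })
}

#' @export
print.synth_cd <- function(x, ...) {
  cat(
    "<synth_cd>", nrow(x$X), "observations x", ncol(x$X), "features, dt =",
    x$dt_ms, "ms (", paste(names(table(x$y)), table(x$y),
      sep = ":", collapse = ", "
    ), ")\n"
  )
  invisible(x)
}
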