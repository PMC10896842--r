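# deterministic background with genuine content in every screened band:
# slow carrier for zero crossings plus small 10 Hz and 28 Hz components so
# the ratio-to-median artifact screens see a uniform in-band floor
detection_background <- function(duration_s, fs = 128) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  sin(2 * pi * 0.5 * t) + 0.8 * sin(2 * pi * 10 * t) +
    0.8 * sin(2 * pi * 28 * t)
}

one_channel_rec <- function(x, fs = 128, stage = "SWS") {
  make_recording(matrix(x, 1, dimnames = list("C3", NULL)), fs, stage)
}

test_that("the slow band-pass removes DC and fast activity, keeps 1 Hz", {
  fs <- 128
  n <- 60 * fs
  rec <- one_channel_rec(rep(50, n), fs)
  filt <- filter_slow(rec)
  # away from the slow high-pass settling transient the DC is gone
  expect_lt(max(abs(filt$signals[1, (20 * fs):(40 * fs)])), 0.5)

  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  mid <- (10 * fs):(50 * fs)
  f1 <- filter_slow(one_channel_rec(sin(2 * pi * 1 * t), fs))
  expect_gt(max(abs(f1$signals[1, mid])), 0.9) # within 10% of unit input
  f30 <- filter_slow(one_channel_rec(sin(2 * pi * 30 * t), fs))
  expect_lt(max(abs(f30$signals[1, mid])), 0.05)
  expect_error(filter_slow(rec, band = c(0.1, 70)), "fs/2")
})

test_that("a planted biphasic SO is detected at its trough and the criteria gate it", {
  fs <- 128
  bg <- detection_background(90, fs)
  ev <- detect_sos(one_channel_rec(plant_pulse(bg, fs, 45, trough_uv = -100), fs))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$t_trough - 45), 1.5 / fs) # planted trough +- 1 sample
  expect_lte(ev$trough_amp, -80)
  expect_gte(ev$range_amp, 80)

  # criterion (1): a -60 uV trough is too shallow
  shallow <- detect_sos(one_channel_rec(plant_pulse(bg, fs, 45, trough_uv = -60), fs))
  expect_equal(nrow(shallow), 0)
  # criterion (3): a 200 ms negative half-wave is too short
  short <- detect_sos(one_channel_rec(
    plant_pulse(bg, fs, 45, trough_uv = -100, hw = 0.2), fs
  ))
  expect_equal(nrow(short), 0)
  # unknown stage label
  expect_error(detect_sos(one_channel_rec(bg, fs), stage = "N2"), "S2")
  # empty/short recording yields an empty table
  expect_equal(nrow(detect_sos(one_channel_rec(bg[1:(2 * fs)], fs))), 0)
})

test_that("detection is translation-equivariant", {
  fs <- 128
  bg <- detection_background(120, fs)
  e1 <- detect_sos(one_channel_rec(plant_pulse(bg, fs, 45, trough_uv = -100), fs))
  e2 <- detect_sos(one_channel_rec(plant_pulse(bg, fs, 49, trough_uv = -100), fs))
  expect_equal(nrow(e1), 1)
  expect_equal(nrow(e2), 1)
  expect_equal(e2$t_trough - e1$t_trough, 4, tolerance = 2 / fs / 4)
})

test_that("events are confined to the requested stage", {
  fs <- 128
  bg <- detection_background(120, fs)
  x <- plant_pulse(bg, fs, 45, trough_uv = -100) # epoch 2 (30-60 s)
  x <- plant_pulse(x, fs, 75, trough_uv = -100) # epoch 3 (60-90 s)
  hyp <- c("SWS", "SWS", "S2", "Wake")
  rec <- eeg_recording(matrix(x, 1, dimnames = list("C3", NULL)), fs,
    hypnogram = hyp
  )
  sws <- detect_sos(rec, stage = "SWS")
  s2 <- detect_sos(rec, stage = "S2")
  expect_equal(nrow(sws), 1)
  expect_lt(abs(sws$t_trough - 45), 0.1)
  expect_equal(nrow(s2), 1)
  expect_lt(abs(s2$t_trough - 75), 0.1)
  # scorer-excluded epochs remove the event entirely
  rec_ex <- eeg_recording(matrix(x, 1, dimnames = list("C3", NULL)), fs,
    hypnogram = hyp, excluded_epochs = c(FALSE, TRUE, FALSE, FALSE)
  )
  expect_equal(nrow(detect_sos(rec_ex, stage = "SWS")), 0)
})

test_that("the high-frequency artifact screens flag the constructed bins", {
  fs <- 128
  n <- 300 * fs
  set.seed(10)
  xq <- rnorm(n, sd = 2)
  tb <- seq(0, 4 - 1 / fs, by = 1 / fs)
  i0 <- 196 * fs # 4-s bin number 50
  xq[(i0 + 1):(i0 + 4 * fs)] <- xq[(i0 + 1):(i0 + 4 * fs)] +
    20 * sin(2 * pi * 30 * tb)
  rec <- one_channel_rec(xq, fs)
  bm <- brunner_mask(rec)
  expect_equal(which(bm[1, ]), 50)
  # direct bin-power verification of the flag
  P <- sostim:::bin_band_power(rec, c(26.25, 32), 4)
  win <- 28:72
  expect_gt(P[1, 50], 4 * median(P[1, win]))
  # uniform scaling leaves the ratio criterion unchanged
  expect_equal(
    unname(which(brunner_mask(one_channel_rec(5 * xq, fs))[1, ])), 50
  )

  # quiet slow signal: nothing flagged by either screen
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  slow <- one_channel_rec(100 * sin(2 * pi * 1 * t) + 0.5 * rnorm(n), fs)
  expect_equal(sum(brunner_mask(slow)), 0)

  # Wang: one 5-s segment at 10x amplitude
  xw <- rnorm(n, sd = 2)
  j0 <- 100 * fs # 5-s bin number 21
  xw[(j0 + 1):(j0 + 5 * fs)] <- xw[(j0 + 1):(j0 + 5 * fs)] * 10
  expect_equal(which(wang_mask(one_channel_rec(xw, fs))[1, ]), 21)
  # stationary noise: false-positive rate below 1%
  expect_lt(mean(wang_mask(one_channel_rec(rnorm(n, sd = 2), fs))), 0.01)
  # all-zero record: zero median never flags
  zero <- one_channel_rec(rep(0, 60 * fs), fs)
  expect_equal(sum(wang_mask(zero)), 0)
  expect_equal(sum(brunner_mask(zero)), 0)
})

test_that("masking already-masked (zeroed) bins flags nothing new", {
  fs <- 128
  n <- 300 * fs
  set.seed(11)
  xw <- rnorm(n, sd = 2)
  j0 <- 100 * fs
  xw[(j0 + 1):(j0 + 5 * fs)] <- xw[(j0 + 1):(j0 + 5 * fs)] * 10
  m1 <- wang_mask(one_channel_rec(xw, fs))
  x2 <- xw
  for (b in which(m1[1, ])) x2[((b - 1) * 5 * fs + 1):(b * 5 * fs)] <- 0
  m2 <- wang_mask(one_channel_rec(x2, fs))
  expect_false(any(m2 & !m1))
})

test_that("two-pass outlier screening removes only extreme referenced amplitudes", {
  fs <- 128
  quiet <- make_recording(
    matrix(0, 2, 120 * fs, dimnames = list(c("C3", "C4"), NULL)), fs
  )
  ev <- tibble::tibble(
    channel = rep("C3", 100),
    t_start = seq(1, 100), t_trough = seq(1, 100) + 0.25,
    t_mid = seq(1, 100) + 0.5, t_end = seq(1, 100) + 0.9,
    trough_amp = rep(-100, 100), range_amp = rep(150, 100),
    stage = "SWS"
  )
  # identical amplitudes: SD is 0, nothing exceeds mean + 4 SD
  expect_equal(nrow(screen_outliers(ev, quiet)), 100)
  # one enormous event on the same electrode is removed in pass 1
  ev2 <- ev
  ev2$trough_amp[50] <- -10000
  kept <- screen_outliers(ev2, quiet)
  expect_equal(nrow(kept), 99)
  expect_false(any(kept$trough_amp == -10000))
  # an electrode with a single event is kept (SD undefined)
  ev3 <- dplyr::bind_rows(ev, tibble::tibble(
    channel = "C4", t_start = 50, t_trough = 50.25, t_mid = 50.5,
    t_end = 50.9, trough_amp = -90, range_amp = 140, stage = "SWS"
  ))
  expect_equal(nrow(screen_outliers(ev3, quiet)), 101)
})

test_that("every emitted event satisfies the four criteria field-by-field", {
  se <- synth_eeg(duration_s = 120, seed = 99)
  ev <- detect_sos(se$recording)
  p <- so_detection_params()
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$trough_amp <= p$trough_max))
  expect_true(all(ev$range_amp >= p$min_range))
  expect_true(all(ev$t_mid - ev$t_start >= p$half_wave_bounds[1]))
  expect_true(all(ev$t_mid - ev$t_start <= p$half_wave_bounds[2]))
  expect_true(all(ev$t_end - ev$t_start <= p$max_duration))
  expect_true(all(ev$t_start < ev$t_trough))
  expect_true(all(ev$t_trough < ev$t_mid))
  expect_true(all(ev$t_mid <= ev$t_end))
  expect_true(all(ev$stage == "SWS"))
  expect_false(is.unsorted(ev$t_trough))
})
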