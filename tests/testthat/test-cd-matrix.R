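test_that("CD matrix dimensions are locked to dt and the region set", {
  cd20 <- cd_matrix(matrix(0, 50, 17), 20)
  expect_equal(length(cd_flatten(cd20)), 850)
  expect_equal(dim(cd20), c(50, 17))
  cd200 <- cd_matrix(matrix(1, 5, 17), 200)
  expect_equal(length(cd_flatten(cd200)), 85)
  expect_error(cd_matrix(matrix(0, 33, 17), 30), "20, 50, 100, 200")
  expect_error(cd_matrix(matrix(0, 49, 17), 20), "50 time bins")
  expect_error(cd_matrix(matrix(0, 50, 16), 20), "16 columns")
  expect_error(cd_matrix(matrix(c(NA, rep(0, 849)), 50, 17), 20), "finite")
  expect_length(so_regions(), 17)
  expect_equal(sum(so_regions() == "brainstem"), 1)
  expect_false(anyDuplicated(so_regions()) > 0)
})

test_that("cd_average is the element-wise mean", {
  m <- cd_matrix(matrix(rnorm(85), 5, 17), 200)
  expect_equal(cd_average(list(m)), m)
  neg <- cd_matrix(-unclass(m), 200)
  expect_equal(max(abs(cd_average(list(m, neg)))), 0)
  set.seed(7)
  ms <- lapply(1:50, function(i) cd_matrix(matrix(rnorm(85), 5, 17), 200))
  avg <- cd_average(ms)
  brute <- Reduce(`+`, lapply(ms, unclass)) / 50
  expect_equal(unclass(avg), brute, ignore_attr = TRUE)
  other <- cd_matrix(matrix(0, 10, 17), 100)
  expect_error(cd_average(list(m, other)), "share dt")
})

test_that("flattening is time-major and round-trips", {
  vals <- outer(1:5 * 100, 1:17, `+`) # vals[b, r] = 100 b + r
  cd <- cd_matrix(vals, 200)
  flat <- cd_flatten(cd)
  # first 17 features are bin 1 across regions, then bin 2, ...
  expect_equal(unname(flat[1:17]), 100 + 1:17)
  expect_equal(unname(flat[18:34]), 200 + 1:17)
  expect_equal(names(flat)[1], paste0("t1_", so_regions()[1]))
  expect_equal(cd_unflatten(flat, 200), cd)
  g <- cd_feature_grid(200)
  expect_equal(nrow(g), 85)
  expect_equal(g$time_ms[1:17], rep(-400, 17)) # first bin centre
  expect_equal(g$time_ms[nrow(g)], 400)
  expect_equal(g$name, names(flat))
})

test_that("paradigm CD estimation is the binned-waveform outer product", {
  tm <- synth_transfer(seed = 5)
  m <- montage(c("F3", "F4", "P3", "P4"))
  tv <- transfer_vector(tm, m)

  zero <- paradigm(m, waveform("poly", c(0, 0, 0, 0, 0)), 100)
  expect_equal(max(abs(estimate_paradigm_cd(zero, tm))), 0)

  const <- paradigm(m, waveform("poly", c(0, 0, 0, 0.3, 0)), 100)
  cdc <- estimate_paradigm_cd(const, tm)
  for (b in 1:10) expect_equal(unclass(cdc)[b, ], 0.3 * tv)

  w <- waveform("sine", c(0.2, 0.9, pi / 2, 0.05))
  cds <- estimate_paradigm_cd(paradigm(m, w, 100), tm)
  exact <- vapply(1:10, function(b) {
    oracle_sine_bin_mean(0.2, 0.9, pi / 2, 0.05, (b - 1) / 10, b / 10)
  }, numeric(1))
  expect_equal(unclass(cds), outer(exact, tv), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("paradigm CD is linear in amplitude and additive over superposition", {
  tm <- synth_transfer(seed = 6)
  m <- montage(c("F7", "F8", "O1", "O2"))
  set.seed(13)
  for (i in 1:5) {
    p <- runif(4, c(0, 0.01, -pi, 0), c(1, 4, pi, 1))
    a <- runif(1, 0.2, 3)
    w <- waveform("sine", p)
    wa <- waveform("sine", c(a * p[1], p[2], p[3], a * p[4]))
    cd1 <- estimate_paradigm_cd(paradigm(m, w, 100), tm, resolution = 1e-3)
    cda <- estimate_paradigm_cd(paradigm(m, wa, 100), tm, resolution = 1e-3)
    expect_equal(unclass(cda), a * unclass(cd1), tolerance = 1e-10)
    # superposition: a sine plus a constant equals the sum of their CDs
    const <- waveform("poly", c(0, 0, 0, 0.4, 0))
    wsum <- waveform("sine", c(p[1], p[2], p[3], p[4] + 0.4))
    cdsum <- estimate_paradigm_cd(paradigm(m, wsum, 100), tm, resolution = 1e-3)
    cdconst <- estimate_paradigm_cd(paradigm(m, const, 100), tm, resolution = 1e-3)
    expect_equal(
      unclass(cdsum), unclass(cd1) + unclass(cdconst),
      tolerance = 1e-10
    )
  }
})
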