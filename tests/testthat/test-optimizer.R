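test_that("montage enumeration follows the product rule with zero-sum polarity", {
  q7 <- default_quartiles(7)
  expect_true(all(lengths(q7) == 7))
  m7 <- enumerate_montages(q7)
  expect_equal(nrow(m7), 7^4) # 2401 electrode combinations
  expect_true(all(vapply(
    m7$montage, function(m) sum(m$polarity), numeric(1)
  ) == 0))

  q1 <- lapply(default_quartiles(1), identity)
  expect_equal(nrow(enumerate_montages(q1)), 1)
  expect_equal(nrow(enumerate_montages(q1, polarity = "all")), 6)

  qdup <- default_quartiles(2)
  qdup$right_anterior[1] <- qdup$left_anterior[1]
  expect_error(enumerate_montages(qdup), "more than one quartile")
  expect_error(montage(c("F3", "F4", "P3", "P4"), c(1, 1, 1, -1)), "summing to zero")
  expect_error(montage(c("F3", "F3", "P3", "P4")), "distinct")
})

test_that("the vectorized objective agrees with the scalar CD route", {
  tm <- synth_transfer(seed = 8)
  m <- montage(c("F3", "F4", "P3", "P4"))
  target <- estimate_paradigm_cd(
    paradigm(m, waveform("sine", c(0.3, 1.1, 0.2, 0.1)), 100), tm
  )
  w <- runif(170, 0.1, 2)
  obj <- paradigm_objective("sine", m, 100, target, tm, weights = w)
  set.seed(9)
  P <- cbind(runif(6), runif(6, 0.01, 4), runif(6, -pi, pi), runif(6))
  eps_vec <- obj(P)
  for (i in 1:6) {
    cd_i <- estimate_paradigm_cd(
      paradigm(m, waveform("sine", P[i, ]), 100), tm
    )
    expect_equal(
      eps_vec[i],
      objective_epsilon(cd_flatten(cd_i), cd_flatten(target), w),
      tolerance = 1e-10
    )
  }
  # the true parameters achieve (near) zero discrepancy
  expect_lt(obj(matrix(c(0.3, 1.1, 0.2, 0.1), 1)), 1e-12)
  expect_error(
    paradigm_objective("sine", m, 200, target, tm),
    "dt = 100 ms"
  )
})

test_that("GA recovery: a known paradigm's CD is matched to high fidelity", {
  tm <- synth_transfer(seed = 1)
  m <- montage(c("F3", "F4", "P3", "P4"))
  target <- estimate_paradigm_cd(
    paradigm(m, waveform("sine", c(0.2, 0.9, pi / 2, 0.05)), 100), tm
  )
  cand <- optimize_waveform("sine", m, 100, target, tm,
    config = ga_config(pop_size = 60, seed = 10, max_generations = 120)
  )
  expect_gte(cand$wcc, 0.95)
  expect_true(all(diff(cand$ga$trace) <= 1e-12))
})

test_that("a zero transfer vector degenerates gracefully", {
  m <- montage(c("F3", "F4", "P3", "P4"))
  tm0 <- transfer_model_from_table(
    tibble::as_tibble(c(
      list(key = m$key),
      as.list(stats::setNames(rep(0, 17), so_regions()))
    ))
  )
  target <- cd_matrix(matrix(rnorm(170), 10, 17), 100)
  cand <- optimize_waveform("sine", m, 100, target, tm0,
    config = ga_config(pop_size = 20, seed = 11, max_generations = 5)
  )
  # every waveform elicits zero CD, so the best epsilon is the zero-CD error
  expect_equal(
    cand$epsilon,
    objective_epsilon(rep(0, 170), cd_flatten(target), 1),
    tolerance = 1e-10
  )
  expect_true(is.na(cand$wcc))
})

test_that("grid optimization records failures and reproduces per-cell seeds", {
  tm <- synth_transfer(seed = 12)
  mons <- list(
    montage(c("F3", "F4", "P3", "P4")),
    montage(c("F7", "F8", "O1", "O2"))
  )
  target <- estimate_paradigm_cd(
    paradigm(mons[[1]], waveform("sine", c(0.4, 1, 0, 0.1)), 200), tm
  )
  cfg <- ga_config(pop_size = 20, seed = 13, max_generations = 10)
  grid <- optimize_grid(mons, c("sine", "poly"), 200, target, tm, config = cfg)
  expect_equal(nrow(grid), 4)
  expect_true(all(grid$status == "ok"))
  expect_true(all(is.finite(grid$epsilon)))
  grid2 <- optimize_grid(mons, c("sine", "poly"), 200, target, tm, config = cfg)
  expect_equal(grid2$epsilon, grid$epsilon)

  # an imported transfer model lacking one montage fails only that cell
  tmi <- transfer_model_from_table(tibble::as_tibble(c(
    list(key = mons[[1]]$key),
    as.list(stats::setNames(transfer_vector(tm, mons[[1]]), so_regions()))
  )))
  mixed <- optimize_grid(mons, "sine", 200, target, tmi, config = cfg)
  expect_equal(mixed$status[mixed$montage_key == mons[[1]]$key], "ok")
  expect_equal(mixed$status[mixed$montage_key == mons[[2]]$key], "failed")
  expect_match(
    mixed$message[mixed$status == "failed"], "unknown to the imported"
  )
})

test_that("protocol selection maximizes the posterior among global paradigms", {
  tm <- synth_transfer(seed = 14)
  mons <- list(
    montage(c("F3", "F4", "P3", "P4")),
    montage(c("F7", "F8", "O1", "O2")),
    montage(c("AF3", "F8", "P7", "PO4"))
  )
  true_p <- paradigm(mons[[1]], waveform("sine", c(0.3, 1, 0.5, 0.1)), 200)
  target <- estimate_paradigm_cd(true_p, tm)
  d <- synth_cd_paradigms(target, tm, mons[-1],
    n_global = 40, n_nonglobal = 80, seed = 15
  )
  model <- train_so_classifier(d$X, d$y, seed = 16)
  w <- anova_f_weights(d$X, d$y)
  grid <- optimize_grid(mons, "sine", 200, target, tm,
    weights = w,
    config = ga_config(pop_size = 40, seed = 17, max_generations = 60)
  )
  sel <- select_protocol(grid, model)
  expect_false(sel$no_global)
  expect_equal(sel$selected$montage_key, mons[[1]]$key)
  expect_equal(
    sel$selected$posterior, max(sel$results$posterior, na.rm = TRUE)
  )
  # selection is invariant to the order of the result rows
  sel_r <- select_protocol(grid[rev(seq_len(nrow(grid))), ], model)
  expect_equal(sel_r$selected$montage_key, sel$selected$montage_key)
})
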