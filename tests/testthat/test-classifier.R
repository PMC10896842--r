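test_that("ANOVA-F weights match explicit sums and their invariances", {
  set.seed(20)
  y <- rep(c("global", "non_global"), c(40, 60))
  X <- cbind(
    same = rnorm(100), # no group difference
    shifted = rnorm(100) + 5 * (y == "global"),
    scaled = rnorm(100, sd = 3)
  )
  w <- anova_f_weights(X, y)
  expect_lt(w["same"], 5)
  expect_gt(w["shifted"], 100)
  for (j in 1:3) {
    expect_equal(unname(w[j]), oracle_anova_f(X[, j], y), tolerance = 1e-12)
    # cross-check against the stats ANOVA machinery
    fit <- anova(aov(X[, j] ~ factor(y)))
    expect_equal(unname(w[j]), fit$`F value`[1], tolerance = 1e-10)
  }
  # invariant under adding a constant and under rescaling a feature
  expect_equal(anova_f_weights(X + 7, y), w, tolerance = 1e-9)
  expect_equal(anova_f_weights(X * 3.7, y), w, tolerance = 1e-9)
  expect_error(anova_f_weights(X, rep("global", 100)), "both classes")
})

test_that("weights localize on the planted discriminative window", {
  d <- synth_cd_dataset(n_global = 40, n_nonglobal = 80, seed = 21)
  w <- anova_f_weights(d$X, d$y)
  top <- order(-w)[1:sum(d$effect_mask)]
  expect_gt(mean(abs(d$feature_grid$time_ms[top]) <= 100), 0.8)
  expect_true(abs(d$feature_grid$time_ms[which.max(w)]) <= 100)
})

test_that("bagged trees separate clustered classes and expose posteriors", {
  set.seed(22)
  n <- 60
  X <- rbind(
    matrix(rnorm(n * 4, mean = 0), n, 4),
    matrix(rnorm(n * 4, mean = 4), n, 4)
  )
  y <- rep(c("global", "non_global"), each = n)
  model <- train_so_classifier(X, y, seed = 1)
  pred <- predict(model, X)
  cm <- sostim:::confusion_counts(y, pred)
  expect_equal(mcc(cm$tp, cm$tn, cm$fp, cm$fn), 1)
  post <- posterior_global(model, X)
  expect_true(all(post >= 0 & post <= 1))

  # determinism under a fixed seed
  model2 <- train_so_classifier(X, y, seed = 1)
  expect_equal(posterior_global(model2, X), post)

  # ensemble posterior equals the brute-force mean over individual trees
  per_tree <- predict(model$forest,
    newdata = `colnames<-`(X, model$feature_names), predict.all = TRUE
  )
  expect_equal(unname(rowMeans(per_tree$individual)), unname(post),
    tolerance = 1e-12
  )

  # duplicating the dataset leaves the posterior function close to unchanged
  modeld <- train_so_classifier(rbind(X, X), c(y, y), seed = 1)
  expect_lt(mean(abs(posterior_global(modeld, X) - post)), 0.1)

  expect_error(posterior_global(model, rnorm(3)), "does not match")
  expect_error(train_so_classifier(X[1, , drop = FALSE], y[1]), "2 training rows")
})

test_that("uninformative features give a posterior near the class prior", {
  X <- matrix(1, 90, 5)
  y <- rep(c("global", "non_global"), c(30, 60))
  model <- train_so_classifier(X, y, seed = 3)
  expect_equal(posterior_global(model, rep(1, 5)), 1 / 3, tolerance = 0.05)
})

test_that("cross-validated MCC separates signal from permuted labels", {
  d <- synth_cd_dataset(n_global = 50, n_nonglobal = 100, seed = 30)
  cv <- crossval_mcc(d$X, d$y, seed = 31)
  expect_gte(cv$mcc, 0.8)
  expect_equal(
    with(cv$confusion, tp + tn + fp + fn), nrow(d$X)
  )
  yp <- withr::with_seed(32, sample(d$y))
  cvp <- crossval_mcc(d$X, yp, seed = 31)
  expect_lt(abs(cvp$mcc), 0.2)
  # determinism of the pooled MCC under a fixed seed
  expect_equal(crossval_mcc(d$X, d$y, seed = 31)$mcc, cv$mcc)
})

test_that("leave-one-out cross validation runs and returns a finite value", {
  set.seed(33)
  X <- rbind(
    matrix(rnorm(40, mean = 0), 10, 4),
    matrix(rnorm(40, mean = 3), 10, 4)
  )
  y <- rep(c("global", "non_global"), each = 10)
  cv <- crossval_mcc(X, y, folds = 20, seed = 1, n_trees = 25)
  expect_true(is.finite(cv$mcc))
})

test_that("randomized hyperparameter search returns an inner-CV winner", {
  d <- synth_cd_dataset(n_global = 30, n_nonglobal = 60, dt_ms = 200, seed = 35)
  tuned <- tune_so_classifier(d$X, d$y, seed = 36, n_candidates = 3,
    inner_folds = 3
  )
  expect_true(all(c("min_node", "mtry", "mcc") %in% names(tuned$best)))
  expect_equal(max(tuned$trace$mcc), tuned$best$mcc)
})
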