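test_that("co-detection rows follow the symmetric delay rule", {
  one <- tibble::tibble(channel = "F3", t_trough = 10)
  M <- build_codetection(one, electrodes = c("F3", "F4", "P3"))
  expect_equal(unname(M[1, ]), c(1L, 0L, 0L))

  two <- tibble::tibble(channel = c("F3", "F4"), t_trough = c(10, 10.1))
  M2 <- build_codetection(two, electrodes = c("F3", "F4"))
  expect_equal(unclass(unname(M2)), matrix(1L, 2, 2), ignore_attr = TRUE)

  far <- tibble::tibble(channel = c("F3", "F4"), t_trough = c(10, 10.6))
  M3 <- build_codetection(far, electrodes = c("F3", "F4"), delay = 0.4)
  expect_equal(unclass(unname(M3)), diag(2) * 1L, ignore_attr = TRUE)

  # exactly at the delay boundary counts as co-detected
  edge <- tibble::tibble(channel = c("F3", "F4"), t_trough = c(10, 10.25))
  expect_equal(
    sum(build_codetection(edge, electrodes = c("F3", "F4"), delay = 0.25)), 4
  )

  expect_equal(nrow(build_codetection(one[0, ], electrodes = "F3")), 0)
  expect_error(build_codetection(one, electrodes = "F4"), "not in electrode")
})

make_patterns <- function() {
  p <- 12
  rbind(
    rep(1, p), # widespread
    c(rep(1, 5), rep(0, 7)), # frontal block
    c(rep(0, 10), 1, 1) # small posterior patch
  )
}

test_that("Hamming k-means recovers separable binary patterns exactly", {
  pat <- make_patterns()
  X <- pat[rep(1:3, each = 40), ]
  colnames(X) <- paste0("e", 1:12)
  km <- kmeans_hamming(X, k = 3, replicates = 20, seed = 1)
  expect_equal(km$inertia, 0)
  # centroids equal the generating patterns up to cluster order
  ord <- apply(sostim:::hamming_distances(pat, km$centroids), 1, which.min)
  expect_equal(sort(ord), 1:3)
  expect_equal(km$centroids[ord, ], pat, ignore_attr = TRUE)
  expect_equal(unname(km$sizes[ord]), rep(40, 3))
})

test_that("Hamming k-means tolerates bit flips and behaves monotonically", {
  pat <- make_patterns()
  truth <- rep(1:3, each = 60)
  X <- pat[truth, ]
  set.seed(5)
  flips <- matrix(runif(length(X)) < 0.05, nrow(X))
  X <- abs(X - flips)
  km <- kmeans_hamming(X, k = 3, replicates = 50, seed = 2)
  expect_gte(label_match_agreement(km$cluster, truth), 0.95)
  # Lloyd cost never increases within the winning replicate
  expect_true(all(diff(km$cost_trace) <= 0))
  # the reported best is at least as good as every replicate
  expect_true(all(km$inertia <= km$replicate_costs))
  # permuting event order leaves centroids (as a set) and cost unchanged
  perm <- sample(nrow(X))
  km_p <- kmeans_hamming(X[perm, ], k = 3, replicates = 50, seed = 2)
  expect_equal(km_p$inertia, km$inertia)
  key <- function(C) paste(sort(apply(C, 1, paste, collapse = "")), collapse = "|")
  expect_equal(key(km_p$centroids), key(km$centroids))
  # determinism under a fixed seed
  km_r <- kmeans_hamming(X, k = 3, replicates = 50, seed = 2)
  expect_identical(km_r$cluster, km$cluster)

  expect_error(
    kmeans_hamming(matrix(rep(c(0, 1), 10), 10, 2), k = 3),
    "distinct rows"
  )
})

test_that("centroid labeling follows the scalp-coverage rules", {
  els <- paste0("e", 1:12)
  frontal <- els[1:6]
  posterior <- els[7:12]
  pat <- make_patterns()
  X <- pat[rep(1:3, each = 30), ]
  colnames(X) <- els
  km <- kmeans_hamming(X, k = 3, replicates = 20, seed = 3)
  km <- label_clusters(km, frontal, posterior)
  ord <- apply(sostim:::hamming_distances(pat, km$centroids), 1, which.min)
  expect_equal(km$type_map[ord], c("Global", "Frontal", "Local"))
  expect_equal(sort(km$type_map), sort(c("Global", "Frontal", "Local")))
  expect_equal(km$is_global, km$so_type == "Global")

  # consistent column+partition permutation leaves event labels unchanged
  perm <- sample(12)
  Xp <- X[, perm]
  km_p <- kmeans_hamming(Xp, k = 3, replicates = 20, seed = 3)
  km_p <- label_clusters(km_p, intersect(colnames(Xp), frontal),
    intersect(colnames(Xp), posterior)
  )
  expect_equal(km_p$so_type, km$so_type)
})

test_that("planted SO types are recovered end-to-end from synthetic EEG", {
  se <- synth_eeg(duration_s = 240, seed = 42)
  ev <- detect_sos(se$recording)
  cl <- cluster_so_events(ev, se$frontal, se$posterior,
    electrodes = se$recording$channel_names, replicates = 50, seed = 7
  )
  # map each detected event back to its planted type
  planted <- vapply(seq_len(nrow(ev)), function(i) {
    j <- which(se$truth$channel == ev$channel[i] &
      abs(se$truth$t_trough - ev$t_trough[i]) <= 0.15)
    if (length(j)) se$truth$type[j[1]] else NA_character_
  }, character(1))
  known <- !is.na(planted)
  agreement <- mean(tolower(cl$events$so_type[known]) == planted[known])
  expect_gte(agreement, 0.9)
})
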