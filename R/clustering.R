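#' Build the binary event-by-electrode co-detection matrix
#'
#' Each detected SO seeds one row; column `c` of row `r` is 1 if some event
#' on electrode `c` has its trough within `delay` seconds (symmetric
#' window) of row `r`'s trough. The seeding electrode itself is always 1.
#' Rows therefore describe how widely each SO was co-detected across the
#' scalp.
#'
#' @param events Event tibble (one subject, one stage) with at least
#'   `channel` and `t_trough`.
#' @param electrodes Ordered electrode labels forming the columns (default:
#'   sorted unique event channels). Every event channel must be present.
#' @param delay Co-detection delay in seconds (default 0.4).
#' @return Binary matrix events x electrodes of class `codetection_matrix`
#'   with attributes `electrodes` and `delay`.
#' @export
build_codetection <- function(events, electrodes = NULL, delay = 0.4) {
  stopifnot(is.data.frame(events))
  if (is.null(electrodes)) electrodes <- sort(unique(events$channel))
  if (nrow(events) == 0) {
    M <- matrix(0L, 0, length(electrodes), dimnames = list(NULL, electrodes))
    return(structure(M,
      electrodes = electrodes, delay = delay,
      class = c("codetection_matrix", "matrix", "array")
    ))
  }
  missing <- setdiff(unique(events$channel), electrodes)
  if (length(missing) > 0) {
    stop_sostim(
      "event channel(s) not in electrode list: %s",
      paste(missing, collapse = ", ")
    )
  }
  troughs_by_el <- split(events$t_trough, factor(events$channel, levels = electrodes))
  M <- matrix(0L, nrow(events), length(electrodes),
    dimnames = list(NULL, electrodes)
  )
  for (c_i in seq_along(electrodes)) {
    tc <- sort(troughs_by_el[[c_i]])
    if (length(tc) == 0) next
    # nearest trough on electrode c for every event trough
    idx <- findInterval(events$t_trough, tc)
    lo <- pmax(idx, 1)
    hi <- pmin(idx + 1, length(tc))
    nearest <- pmin(
      abs(events$t_trough - tc[lo]),
      abs(events$t_trough - tc[hi])
    )
    M[, c_i] <- as.integer(nearest <= delay)
  }
  M[cbind(seq_len(nrow(events)), match(events$channel, electrodes))] <- 1L
  structure(M,
    electrodes = electrodes, delay = delay,
    class = c("codetection_matrix", "matrix", "array")
  )
}

hamming_distances <- function(X, C) {
  # rows of X vs rows of C; d(x, c) = x %*% (1 - c) + (1 - x) %*% c
  X %*% t(1 - C) + (1 - X) %*% t(C)
}

#' k-means clustering of binary co-detection rows under Hamming distance
#'
#' Lloyd-style alternation specialized to binary data: rows are assigned to
#' the nearest centroid by Hamming distance and centroids are updated by
#' per-electrode majority vote (ties resolved toward 1), so centroids stay
#' binary. The best of `replicates` seeded random initializations (k
#' distinct rows each) by total Hamming cost is returned. Clusters emptied
#' during iteration are re-seeded with the row currently farthest from its
#' assigned centroid. The per-iteration cost of the winning replicate is
#' non-increasing and exposed as `cost_trace`.
#'
#' @param x A `codetection_matrix` (or any binary matrix).
#' @param k Number of clusters (default 3: global / frontal / local).
#' @param replicates Random restarts (default 200).
#' @param max_iter Maximum Lloyd iterations per replicate (default 10000).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return An object of class `so_cluster_model` with fields `centroids`
#'   (k x electrodes binary), `cluster` (assignment per row), `inertia`
#'   (total Hamming cost), `cost_trace`, `replicate_costs`, `sizes`.
#' @export
kmeans_hamming <- function(x, k = 3, replicates = 200, max_iter = 10000,
                           seed = NULL) {
  X <- unclass(as.matrix(x))
  storage.mode(X) <- "double"
  if (!all(X %in% c(0, 1))) stop_sostim("co-detection entries must be 0/1")
  n <- nrow(X)
  distinct <- unique(X)
  if (nrow(distinct) < k) {
    stop_sostim(
      "need at least %d distinct rows for k = %d clusters; got %d",
      k, k, nrow(distinct)
    )
  }

  run_one <- function() {
    C <- X[sample.int(n, k * 4, replace = TRUE), , drop = FALSE]
    C <- unique(C)
    while (nrow(C) < k) { # pad with further distinct rows if needed
      C <- unique(rbind(C, X[sample.int(n, k), , drop = FALSE]))
    }
    C <- C[seq_len(k), , drop = FALSE]
    assign_prev <- rep(0L, n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      D <- hamming_distances(X, C)
      assign <- max.col(-D, ties.method = "first")
      # re-seed empty clusters with the worst-fit row
      for (cl in which(tabulate(assign, k) == 0)) {
        far <- which.max(D[cbind(seq_len(n), assign)])
        C[cl, ] <- X[far, ]
        assign[far] <- cl
      }
      for (cl in seq_len(k)) {
        C[cl, ] <- as.numeric(colMeans(X[assign == cl, , drop = FALSE]) >= 0.5)
      }
      D <- hamming_distances(X, C)
      assign <- max.col(-D, ties.method = "first")
      trace <- c(trace, sum(D[cbind(seq_len(n), assign)]))
      if (identical(assign, assign_prev)) break
      assign_prev <- assign
    }
    list(
      centroids = C, cluster = assign, inertia = trace[length(trace)],
      trace = trace
    )
  }

  runs <- with_seed(seed, replicate(replicates, run_one(), simplify = FALSE))
  costs <- vapply(runs, `[[`, numeric(1), "inertia")
  best <- runs[[which.min(costs)]]
  structure(
    list(
      centroids = best$centroids, cluster = best$cluster,
      inertia = best$inertia, cost_trace = best$trace,
      replicate_costs = costs, sizes = tabulate(best$cluster, k), k = k,
      electrodes = colnames(X)
    ),
    class = "so_cluster_model"
  )
}

#' @export
print.so_cluster_model <- function(x, ...) {
  cat(
    "<so_cluster_model> k =", x$k, "| sizes:",
    paste(x$sizes, collapse = "/"), "| inertia:", x$inertia, "\n"
  )
  if (!is.null(x$type_map)) {
    cat(" types:", paste(x$type_map, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Label co-detection clusters as Global / Frontal / Local
#'
#' The cluster whose centroid has the greatest mean co-detection across all
#' electrodes is Global (widespread SOs); of the remaining two, the one
#' with the larger frontal-minus-posterior centroid mean is Frontal and the
#' last is Local. Ties for Global are broken toward the larger cluster
#' (logged via a warning).
#'
#' @param model An `so_cluster_model` with `k = 3`.
#' @param frontal,posterior Electrode names forming the frontal and
#'   posterior scalp partitions.
#' @return The model with `type_map` (cluster -> label), per-event
#'   `so_type` and logical `is_global` added.
#' @export
label_clusters <- function(model, frontal, posterior) {
  stopifnot(inherits(model, "so_cluster_model"))
  if (model$k != 3) stop_sostim("cluster labeling requires k = 3")
  C <- model$centroids
  els <- model$electrodes
  f_ix <- match(intersect(frontal, els), els)
  p_ix <- match(intersect(posterior, els), els)
  if (length(f_ix) == 0 || length(p_ix) == 0) {
    stop_sostim("frontal/posterior partitions must each match some electrodes")
  }
  overall <- rowMeans(C)
  top <- max(overall)
  cand <- which(overall == top)
  if (length(cand) > 1) {
    rlang::warn("tie for the Global centroid; broken by cluster size")
    cand <- cand[order(-model$sizes[cand])]
  }
  global <- cand[1]
  rest <- setdiff(1:3, global)
  frontality <- rowMeans(C[rest, f_ix, drop = FALSE]) -
    rowMeans(C[rest, p_ix, drop = FALSE])
  frontal_cl <- rest[order(-frontality, rest)][1]
  local_cl <- setdiff(rest, frontal_cl)
  type_map <- character(3)
  type_map[c(global, frontal_cl, local_cl)] <- c("Global", "Frontal", "Local")
  model$type_map <- type_map
  model$so_type <- type_map[model$cluster]
  model$is_global <- model$so_type == "Global"
  model
}

#' Cluster detected SOs into space-time types
#'
#' Convenience pipeline: build the co-detection matrix from an event table,
#' run Hamming k-means, label the clusters and return the events augmented
#' with `cluster_id`, `so_type` and `is_global`.
#'
#' @param events Event tibble from [detect_sos()].
#' @param frontal,posterior Electrode partition used for labeling.
#' @param electrodes Column electrodes (default union of the partition).
#' @param delay Co-detection delay, seconds.
#' @param k,replicates,seed Passed to [kmeans_hamming()].
#' @return List with `events` (augmented tibble) and `model`
#'   (the labeled `so_cluster_model`).
#' @export
cluster_so_events <- function(events, frontal, posterior,
                              electrodes = NULL, delay = 0.4, k = 3,
                              replicates = 200, seed = NULL) {
  if (is.null(electrodes)) {
    electrodes <- unique(c(frontal, posterior, events$channel))
  }
  M <- build_codetection(events, electrodes, delay)
  model <- kmeans_hamming(M, k = k, replicates = replicates, seed = seed)
  model <- label_clusters(model, frontal, posterior)
  events$cluster_id <- model$cluster
  events$so_type <- model$so_type
  events$is_global <- model$is_global
  list(events = events, model = model)
}

#' @export
tidy.so_cluster_model <- function(x, ...) {
  out <- tibble::tibble(
    cluster = seq_len(x$k),
    size = x$sizes,
    mean_codetection = rowMeans(x$centroids)
  )
  if (!is.null(x$type_map)) out$so_type <- x$type_map
  out
}

#' @export
glance.so_cluster_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, inertia = x$inertia, iterations = length(x$cost_trace),
    replicates = length(x$replicate_costs)
  )
}

#' @export
autoplot.so_cluster_model <- function(object, ...) {
  df <- tibble::as_tibble(object$centroids)
  df$cluster <- if (!is.null(object$type_map)) {
    object$type_map
  } else {
    paste("cluster", seq_len(object$k))
  }
  long <- tidyr::pivot_longer(df, -"cluster",
    names_to = "electrode", values_to = "codetection"
  )
  long$electrode <- factor(long$electrode, levels = object$electrodes)
  ggplot2::ggplot(long, ggplot2::aes(.data$electrode, .data$cluster,
    fill = .data$codetection
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "cluster centroids") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
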