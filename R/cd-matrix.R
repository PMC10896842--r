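#' Default brain region set for current-density profiles
#'
#' Seventeen regions: eight structures split into left/right components
#' (cortex, hippocampus, thalamus, caudate, putamen, pallidum, amygdala,
#' nucleus accumbens) plus the unpaired brainstem. The ordering is fixed and
#' shared by every consumer of flattened features.
#'
#' @return Character vector of length 17.
#' @export
so_regions <- function() {
  paired <- c(
    "cortex", "hippocampus", "thalamus", "caudate",
    "putamen", "pallidum", "amygdala", "accumbens"
  )
  c(as.vector(t(outer(paired, c("L", "R"), paste, sep = "_"))), "brainstem")
}

#' Time-by-region current-density matrix
#'
#' The common representation of both a sleep slow oscillation and a
#' simulated stimulation paradigm: current density in a 1-s window centred
#' on the SO trough (-500 ms to +500 ms), discretized into `1000 / dt_ms`
#' time bins (rows) by brain regions (columns). Units are arbitrary but
#' must be kept consistent across a pipeline run; the synthetic transfer
#' operator is normalized to unit mean magnitude.
#'
#' @param values Numeric matrix, `1000 / dt_ms` rows by `length(regions)`
#'   columns, all finite.
#' @param dt_ms Time-bin width in ms; one of 20, 50, 100, 200.
#' @param regions Ordered region labels (default [so_regions()]).
#' @return An object of class `cd_matrix`.
#' @examples
#' cd <- cd_matrix(matrix(0, 50, 17), dt_ms = 20)
#' length(cd_flatten(cd)) # 850
#' @export
cd_matrix <- function(values, dt_ms, regions = so_regions()) {
  check_dt(dt_ms)
  values <- as.matrix(values)
  m <- as.integer(round(1000 / dt_ms))
  if (nrow(values) != m) {
    stop_sostim(
      "CD matrix at dt = %d ms must have %d time bins, got %d rows",
      dt_ms, m, nrow(values)
    )
  }
  if (ncol(values) != length(regions)) {
    stop_sostim(
      "CD matrix has %d columns but %d regions were named",
      ncol(values), length(regions)
    )
  }
  if (!all(is.finite(values))) stop_sostim("CD values must all be finite")
  dimnames(values) <- list(NULL, regions)
  structure(values,
    dt_ms = as.numeric(dt_ms), regions = regions,
    class = c("cd_matrix", "matrix", "array")
  )
}

#' @export
print.cd_matrix <- function(x, ...) {
  cat(
    "<cd_matrix>", nrow(x), "time bins x", ncol(x), "regions, dt =",
    attr(x, "dt_ms"), "ms (", length(x), "elements )\n"
  )
  invisible(x)
}

#' @rdname cd_matrix
#' @param x A `cd_matrix`.
#' @export
cd_dt <- function(x) attr(x, "dt_ms")

#' @rdname cd_matrix
#' @export
cd_region_names <- function(x) attr(x, "regions")

#' Element-wise average of current-density matrices
#'
#' Produces, e.g., the average global-SO CD used as the optimization target.
#'
#' @param cds A list of `cd_matrix` objects sharing `dt_ms` and regions.
#' @return A single `cd_matrix`.
#' @export
cd_average <- function(cds) {
  if (inherits(cds, "cd_matrix")) cds <- list(cds)
  if (length(cds) == 0) stop_sostim("cannot average an empty list of CD matrices")
  stopifnot(all(vapply(cds, inherits, logical(1), "cd_matrix")))
  dts <- vapply(cds, cd_dt, numeric(1))
  if (length(unique(dts)) != 1) {
    stop_sostim(
      "all CD matrices must share dt; got {%s}",
      paste(unique(dts), collapse = ", ")
    )
  }
  regs <- lapply(cds, cd_region_names)
  if (!all(vapply(regs, identical, logical(1), regs[[1]]))) {
    stop_sostim("all CD matrices must share the same region set")
  }
  avg <- Reduce(`+`, lapply(cds, unclass)) / length(cds)
  cd_matrix(avg, dts[[1]], regs[[1]])
}

#' Flatten a CD matrix to the shared time-major feature vector
#'
#' Feature order is time-major: all regions of bin 1, then all regions of
#' bin 2, and so on. Every consumer of flattened features (classifier,
#' ANOVA-F weights, optimization objective) uses this order.
#'
#' @param x A `cd_matrix`.
#' @return Named numeric vector of length `nbins * nregions`.
#' @export
cd_flatten <- function(x) {
  stopifnot(inherits(x, "cd_matrix"))
  v <- as.vector(t(unclass(x)))
  names(v) <- cd_feature_names(cd_dt(x), cd_region_names(x))
  v
}

#' @rdname cd_flatten
#' @param v Flattened feature vector (time-major).
#' @param dt_ms Bin width in ms.
#' @param regions Region labels.
#' @export
cd_unflatten <- function(v, dt_ms, regions = so_regions()) {
  m <- as.integer(round(1000 / dt_ms))
  if (length(v) != m * length(regions)) {
    stop_sostim(
      "feature vector length %d does not match %d bins x %d regions",
      length(v), m, length(regions)
    )
  }
  cd_matrix(matrix(v, nrow = m, byrow = TRUE), dt_ms, regions)
}

cd_feature_names <- function(dt_ms, regions = so_regions()) {
  m <- as.integer(round(1000 / dt_ms))
  paste0("t", rep(seq_len(m), each = length(regions)), "_", rep(regions, m))
}

#' Feature index grid for flattened CD vectors
#'
#' Maps each flattened feature to its time bin, bin-centre time relative to
#' the SO trough, and region.
#'
#' @param dt_ms Bin width in ms.
#' @param regions Region labels.
#' @return Tibble with columns `feature`, `name`, `bin`, `time_ms`, `region`.
#' @export
cd_feature_grid <- function(dt_ms, regions = so_regions()) {
  check_dt(dt_ms)
  m <- as.integer(round(1000 / dt_ms))
  n <- length(regions)
  bin <- rep(seq_len(m), each = n)
  tibble::tibble(
    feature = seq_len(m * n),
    name = cd_feature_names(dt_ms, regions),
    bin = bin,
    time_ms = -500 + (bin - 0.5) * dt_ms,
    region = rep(regions, m)
  )
}

#' @export
tidy.cd_matrix <- function(x, ...) {
  g <- cd_feature_grid(cd_dt(x), cd_region_names(x))
  g$value <- cd_flatten(x)
  g
}

#' @export
autoplot.cd_matrix <- function(object, ...) {
  df <- tidy.cd_matrix(object)
  df$region <- factor(df$region, levels = rev(cd_region_names(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$region, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(
      x = "time from trough (ms)", y = NULL, fill = "CD",
      title = paste0("current density (dt = ", cd_dt(object), " ms)")
    ) +
    ggplot2::theme_minimal()
}
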