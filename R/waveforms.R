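#' Stimulation waveform families
#'
#' Four parametric waveform families are available for the 1-s stimulation
#' window: a single sinusoid (`sine`), a sum of three sinusoids (`sine3`),
#' a duty-cycled square wave (`square`) and a shifted cubic polynomial
#' (`poly`). Amplitudes and offsets are expressed in units of the
#' unit-amplitude transfer operator (dimensionless scaling), frequencies in
#' Hz, phases in radians and the duty cycle in percent.
#'
#' Parameter vectors are ordered as:
#' * `sine`: amplitude, frequency, phase, offset;
#' * `sine3`: three amplitudes, three frequencies, three phases, offset;
#' * `square`: amplitude, frequency, phase, duty cycle, offset;
#' * `poly`: four polynomial coefficients (cubic to constant), shift.
#'
#' @param kind One of `"sine"`, `"sine3"`, `"square"`, `"poly"`.
#' @param params Numeric parameter vector of the length required by `kind`
#'   (4, 10, 5 and 5 respectively).
#' @return An object of class `so_waveform`.
#' @examples
#' w <- waveform("sine", c(A = 0.2, f = 0.9, phase = pi / 2, offset = 0.05))
#' eval_waveform(w, c(0, 0.25, 0.5))
#' @export
waveform <- function(kind, params) {
  kind <- match.arg(kind, waveform_kinds())
  nm <- waveform_param_names(kind)
  params <- as.numeric(params)
  if (length(params) != length(nm)) {
    stop_sostim(
      "waveform kind '%s' takes %d parameters (%s), got %d",
      kind, length(nm), paste(nm, collapse = ", "), length(params)
    )
  }
  if (!all(is.finite(params))) stop_sostim("waveform parameters must be finite")
  structure(list(kind = kind, params = setNames(params, nm)),
    class = "so_waveform"
  )
}

#' @export
print.so_waveform <- function(x, ...) {
  cat("<so_waveform> kind:", x$kind, "\n")
  print(round(x$params, 4))
  invisible(x)
}

#' @rdname waveform
#' @export
waveform_kinds <- function() c("sine", "sine3", "square", "poly")

#' @rdname waveform
#' @export
waveform_param_names <- function(kind) {
  kind <- match.arg(kind, waveform_kinds())
  switch(kind,
    sine = c("A", "f", "phase", "offset"),
    sine3 = c(
      "A1", "A2", "A3", "f1", "f2", "f3",
      "phase1", "phase2", "phase3", "offset"
    ),
    square = c("A", "f", "phase", "duty", "offset"),
    poly = c("p1", "p2", "p3", "p4", "shift")
  )
}

#' Default optimization bounds per waveform family
#'
#' Amplitudes and offsets are searched in \[0, 1\], frequencies in
#' \[0.01, 4\] Hz, phases (and the polynomial shift) in \[-pi, pi\], the
#' square-wave duty cycle in \[0, 100\] percent and polynomial coefficients
#' in \[-1, 1\].
#'
#' @param kind Waveform family, see [waveform()].
#' @return A tibble with columns `param`, `lower`, `upper`.
#' @export
waveform_bounds <- function(kind) {
  kind <- match.arg(kind, waveform_kinds())
  nm <- waveform_param_names(kind)
  bound1 <- function(p) {
    if (grepl("^A", p) || p == "offset") {
      c(0, 1)
    } else if (grepl("^f", p)) {
      c(0.01, 4)
    } else if (grepl("^phase", p) || p == "shift") {
      c(-pi, pi)
    } else if (p == "duty") {
      c(0, 100)
    } else { # polynomial coefficients
      c(-1, 1)
    }
  }
  b <- vapply(nm, bound1, numeric(2))
  tibble::tibble(param = nm, lower = unname(b[1, ]), upper = unname(b[2, ]))
}

#' Evaluate a waveform on the 1-s stimulation window
#'
#' @param w An `so_waveform`.
#' @param t Time points in seconds, all within \[0, 1\].
#' @return Numeric amplitudes, one per element of `t`.
#' @export
eval_waveform <- function(w, t) {
  stopifnot(inherits(w, "so_waveform"))
  t <- as.numeric(t)
  if (any(t < 0 | t > 1)) {
    stop_sostim("waveforms are defined on [0, 1] s; got t outside that range")
  }
  drop(eval_waveform_matrix(w$kind, matrix(w$params, nrow = 1), t))
}

# vectorized evaluation: P is (candidates x n_params), t a time vector;
# returns a (candidates x length(t)) amplitude matrix. Column-wise recycling
# of per-row parameter vectors is relied on throughout.
eval_waveform_matrix <- function(kind, P, t) {
  nt <- length(t)
  switch(kind,
    sine = {
      P[, 1] * sin(2 * pi * outer(P[, 2], t) - P[, 3]) + P[, 4]
    },
    sine3 = {
      Y <- matrix(P[, 10], nrow(P), nt)
      for (j in 1:3) {
        Y <- Y + P[, j] * sin(2 * pi * outer(P[, 3 + j], t) - P[, 6 + j])
      }
      Y
    },
    square = {
      u <- (outer(P[, 2], t) - P[, 3] / (2 * pi)) %% 1
      s <- (u < P[, 4] / 100) * 2 - 1
      P[, 1] * s + P[, 5]
    },
    poly = {
      X <- matrix(t, nrow(P), nt, byrow = TRUE) - P[, 5]
      P[, 1] * X^3 + P[, 2] * X^2 + P[, 3] * X + P[, 4]
    },
    stop_sostim("unknown waveform kind '%s'", kind)
  )
}

#' Time-bin a waveform at one of the supported bin widths
#'
#' The waveform is evaluated on a dense midpoint grid (0.1 ms steps by
#' default) over \[0, 1\] s and averaged within consecutive bins of width
#' `dt_ms`, yielding the piecewise-constant representation used by the
#' linear forward model.
#'
#' @param w An `so_waveform`.
#' @param dt_ms Bin width in ms; one of 20, 50, 100, 200.
#' @param resolution Evaluation grid step in seconds (default 1e-4, i.e.
#'   0.1 ms).
#' @return An object of class `binned_waveform` with fields `dt_ms` and
#'   `means` (vector of `1000 / dt_ms` bin averages).
#' @export
bin_waveform <- function(w, dt_ms, resolution = 1e-4) {
  check_dt(dt_ms)
  m <- as.integer(round(1000 / dt_ms))
  npts <- as.integer(round(1 / resolution))
  if (npts %% m != 0) {
    stop_sostim("resolution %g does not divide the %d bins evenly", resolution, m)
  }
  tg <- bin_time_grid(resolution)
  y <- eval_waveform(w, tg)
  means <- colMeans(matrix(y, nrow = npts / m))
  structure(list(dt_ms = dt_ms, means = as.numeric(means)),
    class = "binned_waveform"
  )
}

#' @export
print.binned_waveform <- function(x, ...) {
  cat(
    "<binned_waveform> dt:", x$dt_ms, "ms,", length(x$means), "bins\n",
    "means:", paste(round(x$means, 4), collapse = " "), "\n"
  )
  invisible(x)
}

# midpoint grid over [0, 1] s
bin_time_grid <- function(resolution = 1e-4) {
  npts <- as.integer(round(1 / resolution))
  (seq_len(npts) - 0.5) * resolution
}

# dense-grid -> bin-average operator (npts x m), reused across a GA run
bin_average_matrix <- function(dt_ms, resolution = 1e-4) {
  m <- as.integer(round(1000 / dt_ms))
  npts <- as.integer(round(1 / resolution))
  ppb <- npts / m
  B <- matrix(0, npts, m)
  for (b in seq_len(m)) B[((b - 1) * ppb + 1):(b * ppb), b] <- 1 / ppb
  B
}

check_dt <- function(dt_ms) {
  if (!(length(dt_ms) == 1 && dt_ms %in% c(20, 50, 100, 200))) {
    stop_sostim(
      "dt must be one of 20, 50, 100, 200 ms; got %s",
      paste(dt_ms, collapse = ",")
    )
  }
  invisible(dt_ms)
}

#' Export a waveform as a two-column CSV for arbitrary waveform generators
#'
#' @param w An `so_waveform`.
#' @param path Output CSV path (columns `t`, `amplitude`).
#' @param resolution Grid step in seconds.
#' @return The path, invisibly.
#' @export
write_waveform_csv <- function(w, path, resolution = 1e-4) {
  tg <- bin_time_grid(resolution)
  readr::write_csv(tibble::tibble(t = tg, amplitude = eval_waveform(w, tg)), path)
  invisible(path)
}

#' @export
autoplot.so_waveform <- function(object, dt_ms = NULL, resolution = 1e-3, ...) {
  tg <- bin_time_grid(resolution)
  df <- tibble::tibble(t = tg, amplitude = eval_waveform(object, tg))
  p <- ggplot2::ggplot(df, ggplot2::aes(t, .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)", y = "amplitude",
      title = paste0("waveform (", object$kind, ")")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(dt_ms)) {
    bw <- bin_waveform(object, dt_ms)
    m <- length(bw$means)
    steps <- tibble::tibble(
      t = (seq_len(m) - 1) / m,
      amplitude = bw$means
    )
    p <- p + ggplot2::geom_step(data = steps, colour = "red")
  }
  p
}
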