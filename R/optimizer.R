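#' Vectorized GA objective for one paradigm cell
#'
#' Builds the fitness closure minimized when tuning one waveform family on
#' one montage at one time resolution: candidate parameter rows are
#' evaluated on the dense waveform grid, bin-averaged, pushed through the
#' linear transfer model into flattened time-major CD features, and scored
#' with the weighted objective against the target CD.
#'
#' @param kind Waveform family.
#' @param montage An `so_montage`.
#' @param dt_ms Time resolution in ms.
#' @param target A `cd_matrix` with matching `dt_ms` (the average global-SO
#'   CD).
#' @param tm A `transfer_model`.
#' @param weights Feature weights (default uniform), length matching the
#'   flattened target.
#' @param loss `"squared"` or `"absolute"` residuals.
#' @param resolution Waveform grid step in seconds.
#' @return Function mapping a parameter matrix to a fitness vector.
#' @export
paradigm_objective <- function(kind, montage, dt_ms, target, tm,
                               weights = NULL, loss = c("squared", "absolute"),
                               resolution = 1e-4) {
  loss <- match.arg(loss)
  kind <- match.arg(kind, waveform_kinds())
  stopifnot(inherits(target, "cd_matrix"))
  if (cd_dt(target) != dt_ms) {
    stop_sostim(
      "target CD has dt = %g ms but the paradigm uses dt = %g ms",
      cd_dt(target), dt_ms
    )
  }
  tv <- transfer_vector(tm, montage)
  tgt <- cd_flatten(target)
  n_reg <- length(tv)
  m <- as.integer(round(1000 / dt_ms))
  w <- if (is.null(weights)) rep(1, length(tgt)) else as.numeric(weights)
  if (length(w) != length(tgt)) {
    stop_sostim(
      "weights length %d does not match %d CD features",
      length(w), length(tgt)
    )
  }
  if (sum(w) <= 0) stop_sostim("weights must not sum to zero")
  tg <- bin_time_grid(resolution)
  B <- bin_average_matrix(dt_ms, resolution)
  tv_rep <- rep(tv, m) # time-major expansion
  sw <- sum(w)

  function(P) {
    P <- as.matrix(P)
    means <- eval_waveform_matrix(kind, P, tg) %*% B # candidates x m
    feats <- means[, rep(seq_len(m), each = n_reg), drop = FALSE] *
      matrix(tv_rep, nrow(P), m * n_reg, byrow = TRUE)
    R <- sweep(feats, 2, tgt)
    if (loss == "squared") {
      drop((R * R) %*% w) / sw
    } else {
      drop(abs(R) %*% w) / sw
    }
  }
}

#' Optimize one waveform family for one montage and time resolution
#'
#' Runs the genetic algorithm over the family's parameter box (see
#' [waveform_bounds()]) minimizing the weighted objective against the
#' target CD, and reports the tuned paradigm with its fitness, estimated
#' CD, and weighted correlation / weighted MSE against the target.
#'
#' @inheritParams paradigm_objective
#' @param config A [ga_config()].
#' @param bounds Optional bounds tibble overriding [waveform_bounds()].
#' @return A list of class `so_candidate`: `paradigm`, `epsilon`, `cd`,
#'   `wcc`, `wmse`, `ga` (the full `ga_result`).
#' @export
optimize_waveform <- function(kind, montage, dt_ms, target, tm,
                              weights = NULL, config = ga_config(),
                              bounds = NULL, loss = "squared",
                              resolution = 1e-4) {
  kind <- match.arg(kind, waveform_kinds())
  bounds <- bounds %||% waveform_bounds(kind)
  fit <- paradigm_objective(kind, montage, dt_ms, target, tm,
    weights = weights, loss = loss, resolution = resolution
  )
  ga <- run_ga(fit, bounds, config)
  p <- paradigm(montage, waveform(kind, ga$par), dt_ms)
  cd <- estimate_paradigm_cd(p, tm, resolution)
  x <- cd_flatten(target)
  y <- cd_flatten(cd)
  w <- if (is.null(weights)) 1 else weights
  structure(
    list(
      paradigm = p, epsilon = ga$value, cd = cd,
      wcc = tryCatch(wcc(x, y, w), error = function(e) NA_real_),
      wmse = wmse(x, y, w), ga = ga
    ),
    class = "so_candidate"
  )
}

#' @export
print.so_candidate <- function(x, ...) {
  cat(
    "<so_candidate>", paradigm_key(x$paradigm), "| epsilon:",
    signif(x$epsilon, 4), "| WCC:", round(x$wcc, 4), "| WMSE:",
    signif(x$wmse, 4), "\n"
  )
  invisible(x)
}

#' Optimize a grid of stimulation paradigms
#'
#' One GA run per (montage, waveform kind, dt) cell. Failed cells (e.g., a
#' montage unknown to an imported transfer model) are recorded with their
#' failure message rather than dropped. Per-cell seeds are derived from the
#' master seed and the cell index, so results are reproducible and
#' independent of evaluation order.
#'
#' @param montages A tibble from [enumerate_montages()] (or a list of
#'   `so_montage`).
#' @param kinds Waveform families to tune.
#' @param dts Time resolutions (ms); the target for each must be available.
#' @param target A `cd_matrix` (single dt) or a list of targets named by dt
#'   (e.g., `list("100" = cd100)`).
#' @param tm A `transfer_model`.
#' @param weights Feature weights shared by all cells of a dt (vector for a
#'   single dt, or a list named by dt).
#' @param config A [ga_config()]; its `seed` seeds the whole grid.
#' @param loss,resolution Passed to the objective.
#' @return Tibble with one row per cell: `cell`, `montage_key`, `kind`,
#'   `dt_ms`, `status`, `epsilon`, `wcc`, `wmse`, `message` and a
#'   `candidate` list-column holding each `so_candidate`.
#' @export
optimize_grid <- function(montages, kinds, dts, target, tm, weights = NULL,
                          config = ga_config(), loss = "squared",
                          resolution = 1e-4) {
  mons <- if (is.data.frame(montages)) montages$montage else montages
  if (inherits(mons, "so_montage")) mons <- list(mons)
  if (length(mons) == 0 || length(kinds) == 0 || length(dts) == 0) {
    stop_sostim("the optimization grid must be non-empty")
  }
  targets <- if (inherits(target, "cd_matrix")) {
    stats::setNames(list(target), as.character(cd_dt(target)))
  } else {
    target
  }
  wlist <- if (is.null(weights) || is.list(weights)) {
    weights
  } else {
    stats::setNames(list(weights), as.character(dts[1]))
  }
  grid <- expand.grid(
    mi = seq_along(mons), kind = kinds, dt_ms = dts,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mi <- grid$mi[i]
    kind <- grid$kind[i]
    dt <- grid$dt_ms[i]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    res <- tryCatch(
      {
        tgt <- targets[[as.character(dt)]]
        if (is.null(tgt)) stop_sostim("no target CD provided for dt = %g ms", dt)
        cand <- optimize_waveform(kind, mons[[mi]], dt, tgt, tm,
          weights = wlist[[as.character(dt)]], config = cfg,
          loss = loss, resolution = resolution
        )
        tibble::tibble(
          cell = i, montage_key = mons[[mi]]$key, kind = kind, dt_ms = dt,
          status = "ok", epsilon = cand$epsilon, wcc = cand$wcc,
          wmse = cand$wmse, message = NA_character_, candidate = list(cand)
        )
      },
      error = function(e) {
        tibble::tibble(
          cell = i, montage_key = mons[[mi]]$key, kind = kind, dt_ms = dt,
          status = "failed", epsilon = NA_real_, wcc = NA_real_,
          wmse = NA_real_, message = conditionMessage(e),
          candidate = list(NULL)
        )
      }
    )
    res
  })
  dplyr::bind_rows(rows)
}

#' Select the final stimulation protocol by classifier posterior
#'
#' Classifies each optimized cell's estimated CD with the sleep-trained
#' global/non-global classifier and returns, among the cells predicted
#' global, the one with the highest posterior probability (ties broken by
#' the first cell in stable grid order). If no cell is classified global,
#' the best posterior overall is returned with `no_global = TRUE`.
#'
#' @param results Grid tibble from [optimize_grid()].
#' @param model An `so_classifier` whose feature count matches the cells'
#'   flattened CDs.
#' @return A list of class `so_selection`: `selected` (one-row tibble),
#'   `results` (the grid augmented with `posterior` and `predicted`),
#'   `no_global`.
#' @export
select_protocol <- function(results, model) {
  stopifnot(is.data.frame(results), inherits(model, "so_classifier"))
  ok <- results$status == "ok"
  if (!any(ok)) stop_sostim("no successfully optimized cells to select from")
  results$posterior <- NA_real_
  feats <- do.call(rbind, lapply(results$candidate[ok], function(cand) {
    cd_flatten(cand$cd)
  }))
  results$posterior[ok] <- posterior_global(model, feats)
  results$predicted <- ifelse(
    is.na(results$posterior), NA_character_,
    ifelse(results$posterior >= 0.5, model$positive,
      setdiff(model$levels, model$positive)
    )
  )
  is_global <- !is.na(results$predicted) & results$predicted == model$positive
  pool <- if (any(is_global)) which(is_global) else which(ok)
  sel <- pool[order(-results$posterior[pool], results$cell[pool])][1]
  structure(
    list(
      selected = results[sel, ], results = results,
      no_global = !any(is_global)
    ),
    class = "so_selection"
  )
}

#' @export
print.so_selection <- function(x, ...) {
  s <- x$selected
  cat(
    "<so_selection>", s$montage_key, "|", s$kind, "| dt =", s$dt_ms,
    "ms | posterior:", round(s$posterior, 4), "| WCC:", round(s$wcc, 4),
    "\n"
  )
  if (x$no_global) cat(" NOTE: no paradigm classified global; best posterior returned\n")
  invisible(x)
}

#' @export
tidy.so_selection <- function(x, ...) {
  dplyr::select(x$results, -"candidate")
}

#' @export
glance.so_selection <- function(x, ...) {
  s <- x$selected
  tibble::tibble(
    montage_key = s$montage_key, kind = s$kind, dt_ms = s$dt_ms,
    epsilon = s$epsilon, posterior = s$posterior, wcc = s$wcc,
    wmse = s$wmse, no_global = x$no_global
  )
}
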