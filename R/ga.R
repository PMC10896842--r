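#' Genetic-algorithm configuration
#'
#' Population-based stochastic minimizer used to tune waveform parameters.
#' The algorithm uses tournament selection (size 2), blend crossover,
#' bounded Gaussian mutation with a schedule that tightens over
#' generations, and elitism of 2. It terminates when the average relative
#' change of the best fitness over `stall_generations` consecutive
#' generations is at most `stall_tol`, or when the generation count reaches
#' `max_generations` (default 100 times the number of parameters).
#'
#' @param pop_size Population size (default 200, minimum 10).
#' @param crossover_fraction Fraction of non-elite offspring produced by
#'   crossover (default 0.8); the rest by mutation.
#' @param elitism Individuals copied unchanged each generation (default 2).
#' @param mutation_sd Initial mutation SD as a fraction of each parameter's
#'   range (default 0.15; decays to 10% of itself by the final generation).
#' @param stall_generations Stall window length (default 50).
#' @param stall_tol Stall tolerance on the average relative change of best
#'   fitness (default 1e-6).
#' @param max_generations Hard cap on generations (default `NULL` =
#'   100 x number of parameters).
#' @param seed Integer seed for reproducible runs.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 200, crossover_fraction = 0.8, elitism = 2,
                      mutation_sd = 0.15, stall_generations = 50,
                      stall_tol = 1e-6, max_generations = NULL, seed = NULL) {
  if (pop_size < 10) stop_sostim("population size must be at least 10")
  if (stall_tol <= 0) stop_sostim("stall tolerance must be positive")
  stopifnot(
    crossover_fraction >= 0, crossover_fraction <= 1,
    elitism >= 0, elitism < pop_size
  )
  structure(
    list(
      pop_size = as.integer(pop_size),
      crossover_fraction = crossover_fraction,
      elitism = as.integer(elitism), mutation_sd = mutation_sd,
      stall_generations = as.integer(stall_generations),
      stall_tol = stall_tol, max_generations = max_generations, seed = seed
    ),
    class = "ga_config"
  )
}

#' Run the genetic algorithm
#'
#' Minimizes `fitness` over a box-bounded parameter space. `fitness` must
#' accept a matrix (candidates x parameters) and return one value per row;
#' vectorizing over the population is what makes waveform optimization
#' affordable. Elitism makes the best-fitness trace non-increasing; with
#' `max_generations = 1` the result is the best of the random initial
#' population.
#'
#' @param fitness Function: matrix (candidates x parameters) -> numeric.
#' @param bounds Tibble/data frame with columns `lower` and `upper`, one
#'   row per parameter (see [waveform_bounds()]); all bounds must be
#'   finite.
#' @param config A [ga_config()].
#' @return An object of class `ga_result`: `par` (best parameters),
#'   `value` (best fitness), `trace` (best fitness per generation),
#'   `generations`, `converged` (`"stall"` or `"max_generations"`).
#' @export
run_ga <- function(fitness, bounds, config = ga_config()) {
  stopifnot(is.function(fitness), is.data.frame(bounds))
  lo <- as.numeric(bounds$lower)
  hi <- as.numeric(bounds$upper)
  if (anyNA(lo) || anyNA(hi) || any(!is.finite(lo)) || any(!is.finite(hi))) {
    stop_sostim("all parameters must have finite bounds before the search")
  }
  if (any(lo >= hi)) stop_sostim("each lower bound must be below its upper bound")
  np <- length(lo)
  maxgen <- config$max_generations %||% (100L * np)
  pop <- config$pop_size
  rng <- hi - lo

  clip <- function(P) {
    P <- pmax(P, matrix(lo, nrow(P), np, byrow = TRUE))
    pmin(P, matrix(hi, nrow(P), np, byrow = TRUE))
  }
  tournament <- function(f, n) {
    a <- sample.int(pop, n, replace = TRUE)
    b <- sample.int(pop, n, replace = TRUE)
    ifelse(f[a] <= f[b], a, b)
  }

  with_seed(config$seed, {
    P <- matrix(stats::runif(pop * np), pop, np)
    P <- sweep(sweep(P, 2, rng, `*`), 2, lo, `+`)
    f <- as.numeric(fitness(P))
    trace <- min(f)
    gen <- 1L
    converged <- "max_generations"
    while (gen < maxgen) {
      ord <- order(f)
      elite <- P[ord[seq_len(config$elitism)], , drop = FALSE]
      n_off <- pop - config$elitism
      n_x <- round(config$crossover_fraction * n_off)
      n_m <- n_off - n_x
      children <- NULL
      if (n_x > 0) {
        p1 <- P[tournament(f, n_x), , drop = FALSE]
        p2 <- P[tournament(f, n_x), , drop = FALSE]
        alpha <- matrix(stats::runif(n_x * np, -0.25, 1.25), n_x, np)
        children <- clip(alpha * p1 + (1 - alpha) * p2)
      }
      mutants <- NULL
      if (n_m > 0) {
        base <- P[tournament(f, n_m), , drop = FALSE]
        sdg <- config$mutation_sd * (1 - 0.9 * gen / maxgen)
        noise <- matrix(stats::rnorm(n_m * np), n_m, np) *
          matrix(sdg * rng, n_m, np, byrow = TRUE)
        mutants <- clip(base + noise)
      }
      P <- rbind(elite, children, mutants)
      f <- as.numeric(fitness(P))
      gen <- gen + 1L
      trace <- c(trace, min(f))
      sw <- config$stall_generations
      if (gen > sw) {
        recent <- trace[(gen - sw):gen]
        rel <- abs(diff(recent)) / pmax(abs(recent[-length(recent)]), 1e-12)
        if (mean(rel) <= config$stall_tol) {
          converged <- "stall"
          break
        }
      }
    }
    best <- which.min(f)
    structure(
      list(
        par = P[best, ], value = f[best], trace = trace,
        generations = gen, converged = converged, config = config
      ),
      class = "ga_result"
    )
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(
    "<ga_result> best fitness:", signif(x$value, 6), "after",
    x$generations, "generations (", x$converged, ")\n"
  )
  invisible(x)
}

#' @export
tidy.ga_result <- function(x, ...) {
  tibble::tibble(generation = seq_along(x$trace), best_fitness = x$trace)
}

#' @export
glance.ga_result <- function(x, ...) {
  tibble::tibble(
    value = x$value, generations = x$generations, converged = x$converged
  )
}

#' @export
autoplot.ga_result <- function(object, ...) {
  ggplot2::ggplot(
    tidy.ga_result(object),
    ggplot2::aes(.data$generation, .data$best_fitness)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "generation", y = "best fitness",
      title = "GA best-fitness trace"
    ) +
    ggplot2::theme_minimal()
}
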