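#' Linear montage-to-region transfer models
#'
#' A transfer model maps a stimulation montage at unit waveform amplitude to
#' a per-region current-density vector; the CD elicited by a paradigm is
#' this vector scaled by the (binned) waveform amplitude. The linearity is
#' definitional inside this package: the transfer vectors would normally be
#' computed once by a finite-element forward solver and imported; the
#' synthetic constructor below stands in for those outputs.
#'
#' `synth_transfer()` draws, per region, a smooth random field over
#' electrode positions (a Gaussian-process sample with squared-exponential
#' covariance over the 2-D layout), so nearby electrodes produce correlated
#' region vectors. A montage's vector is the polarity-signed sum of its
#' electrodes' field values, and the field is scaled so the mean absolute
#' entry over a seeded probe set of montages is 1 (unit mean magnitude).
#'
#' @param seed Integer seed; the operator is deterministic given the seed.
#' @param electrodes Electrode layout tibble (see [scalp_electrodes()]).
#' @param regions Region labels (default [so_regions()]).
#' @param length_scale Correlation length of the spatial field, in layout
#'   units (head radius about 1).
#' @param n_probe Number of probe montages used for normalization.
#' @return An object of class `transfer_model` with `provenance = "synthetic"`.
#' @examples
#' tm <- synth_transfer(seed = 1)
#' v <- transfer_vector(tm, montage(c("F3", "F4", "P3", "P4")))
#' length(v) # 17
#' @export
synth_transfer <- function(seed = 1, electrodes = scalp_electrodes(),
                           regions = so_regions(), length_scale = 0.6,
                           n_probe = 100) {
  stopifnot(is.data.frame(electrodes), all(c("name", "x", "y") %in% names(electrodes)))
  pos <- as.matrix(electrodes[, c("x", "y")])
  d2 <- as.matrix(stats::dist(pos))^2
  K <- exp(-d2 / (2 * length_scale^2)) + diag(1e-6, nrow(pos))
  L <- chol(K)
  G <- with_seed(seed, {
    Z <- matrix(stats::rnorm(nrow(pos) * length(regions)), nrow(pos))
    crossprod(L, Z)
  })
  dimnames(G) <- list(electrodes$name, regions)
  tm <- structure(
    list(
      G = G, electrodes = electrodes, regions = regions,
      provenance = "synthetic", seed = seed
    ),
    class = "transfer_model"
  )
  # normalize to unit mean magnitude over a seeded probe montage set
  probes <- with_seed(derive_seed(seed, 1), {
    qs <- default_quartiles(electrodes = electrodes)
    replicate(n_probe, montage(vapply(qs, sample, character(1), size = 1)),
      simplify = FALSE
    )
  })
  V <- vapply(probes, function(m) transfer_vector(tm, m), numeric(length(regions)))
  tm$G <- G / mean(abs(V))
  tm
}

#' Build a transfer model from an imported table of montage vectors
#'
#' For transfer data computed externally (e.g., by a finite-element forward
#' solver) and exported as one row per montage.
#'
#' @param table Data frame with a `key` column (montage key as produced by
#'   [montage()]) and one numeric column per region.
#' @param regions Expected region labels (default [so_regions()]).
#' @return A `transfer_model` with `provenance = "imported"`; montages
#'   absent from the table raise a lookup error naming the montage.
#' @export
transfer_model_from_table <- function(table, regions = so_regions()) {
  stopifnot(is.data.frame(table), "key" %in% names(table))
  missing_regions <- setdiff(regions, names(table))
  if (length(missing_regions) > 0) {
    stop_sostim(
      "transfer table lacks region column(s): %s (expected %d regions)",
      paste(missing_regions, collapse = ", "), length(regions)
    )
  }
  V <- as.matrix(table[, regions])
  if (!all(is.finite(V))) stop_sostim("transfer vectors must be finite")
  structure(
    list(
      table = stats::setNames(
        lapply(seq_len(nrow(V)), function(i) stats::setNames(V[i, ], regions)),
        table$key
      ),
      regions = regions, provenance = "imported"
    ),
    class = "transfer_model"
  )
}

#' @rdname transfer_model_from_table
#' @param path CSV file with columns `key` plus one per region.
#' @export
read_transfer_csv <- function(path, regions = so_regions()) {
  transfer_model_from_table(
    readr::read_csv(path, show_col_types = FALSE),
    regions = regions
  )
}

#' Evaluate a transfer model for one montage
#'
#' @param tm A `transfer_model`.
#' @param m An `so_montage`.
#' @return Named numeric region vector (CD per unit waveform amplitude).
#' @export
transfer_vector <- function(tm, m) {
  stopifnot(inherits(tm, "transfer_model"), inherits(m, "so_montage"))
  if (tm$provenance == "imported") {
    v <- tm$table[[m$key]]
    if (is.null(v)) {
      stop_sostim("montage '%s' is unknown to the imported transfer model", m$key)
    }
    return(v)
  }
  missing <- setdiff(m$electrodes, rownames(tm$G))
  if (length(missing) > 0) {
    stop_sostim(
      "electrode(s) %s not in the transfer model layout",
      paste(missing, collapse = ", ")
    )
  }
  stats::setNames(
    drop(m$polarity %*% tm$G[m$electrodes, , drop = FALSE]),
    tm$regions
  )
}

#' @export
print.transfer_model <- function(x, ...) {
  cat(
    "<transfer_model>", x$provenance, "-", length(x$regions), "regions",
    if (x$provenance == "imported") {
      paste0("(", length(x$table), " montages)")
    } else {
      paste0("(", nrow(x$G), " electrodes)")
    }, "\n"
  )
  invisible(x)
}

#' Estimate the CD matrix elicited by a stimulation paradigm
#'
#' Bins the paradigm's waveform at its `dt_ms` and scales the montage's
#' transfer vector by each bin-average amplitude:
#' `CD[bin, region] = transfer[region] * mean_amplitude[bin]`. Linear in
#' waveform amplitude and additive over waveform superposition by
#' construction.
#'
#' @param p An `so_paradigm` (see [paradigm()]).
#' @param tm A `transfer_model`.
#' @param resolution Waveform evaluation grid step in seconds.
#' @return A `cd_matrix`.
#' @export
estimate_paradigm_cd <- function(p, tm, resolution = 1e-4) {
  stopifnot(inherits(p, "so_paradigm"))
  tv <- transfer_vector(tm, p$montage)
  bw <- bin_waveform(p$waveform, p$dt_ms, resolution)
  cd_matrix(outer(bw$means, tv), p$dt_ms, regions = names(tv))
}

#' Stimulation paradigm: montage + waveform + time resolution
#'
#' @param montage An `so_montage`.
#' @param waveform An `so_waveform`.
#' @param dt_ms Time-bin width in ms (20, 50, 100 or 200).
#' @return An object of class `so_paradigm`.
#' @export
paradigm <- function(montage, waveform, dt_ms) {
  stopifnot(inherits(montage, "so_montage"), inherits(waveform, "so_waveform"))
  check_dt(dt_ms)
  structure(list(montage = montage, waveform = waveform, dt_ms = dt_ms),
    class = "so_paradigm"
  )
}

#' @export
print.so_paradigm <- function(x, ...) {
  cat(
    "<so_paradigm>", x$montage$key, "|", x$waveform$kind, "| dt =",
    x$dt_ms, "ms\n"
  )
  invisible(x)
}

paradigm_key <- function(p) {
  paste0(p$montage$key, " | ", p$waveform$kind, " | dt", p$dt_ms)
}
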