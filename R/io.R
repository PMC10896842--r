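#' Read and write SO event tables
#'
#' Events are exchanged as TSV with columns `channel`, `t_start`,
#' `t_trough`, `t_mid`, `t_end`, `trough_amp`, `range_amp`, `stage` (plus
#' any clustering columns already added).
#'
#' @param events Event tibble.
#' @param path File path.
#' @return `write_events_tsv` returns the path invisibly;
#'   `read_events_tsv` returns the tibble.
#' @export
write_events_tsv <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a plain-text hypnogram (one stage label per 30-s epoch)
#'
#' @param path Text file, one of `Wake`, `S1`, `S2`, `SWS`, `REM` per line.
#' @return Character vector of stage labels.
#' @export
read_hypnogram <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Read an EEG recording from a CSV signal matrix with a JSON header
#'
#' The CSV holds one column per channel and one row per sample (values in
#' microvolts); the JSON sidecar must contain `fs` and may contain
#' `channel_names` (defaults to the CSV header).
#'
#' @param signal_csv CSV path.
#' @param header_json JSON sidecar path with at least `{"fs": ...}`.
#' @param hypnogram Stage labels per epoch, or a path readable by
#'   [read_hypnogram()].
#' @param excluded_epochs Optional logical vector.
#' @return An `eeg_recording`.
#' @export
read_eeg_csv <- function(signal_csv, header_json, hypnogram,
                         excluded_epochs = NULL) {
  hdr <- jsonlite::read_json(header_json, simplifyVector = TRUE)
  if (is.null(hdr$fs)) stop_sostim("header JSON must contain fs")
  sig <- as.matrix(readr::read_csv(signal_csv, show_col_types = FALSE))
  chn <- hdr$channel_names %||% colnames(sig)
  if (length(hypnogram) == 1 && is.character(hypnogram) &&
    file.exists(hypnogram)) {
    hypnogram <- read_hypnogram(hypnogram)
  }
  eeg_recording(t(sig), hdr$fs,
    channel_names = chn, hypnogram = hypnogram,
    excluded_epochs = excluded_epochs
  )
}

#' Read a frontal/posterior electrode partition from YAML
#'
#' @param path YAML file with top-level keys `frontal` and `posterior`.
#' @return List with `frontal` and `posterior` character vectors.
#' @export
read_partition_yaml <- function(path) {
  p <- yaml::read_yaml(path)
  if (is.null(p$frontal) || is.null(p$posterior)) {
    stop_sostim("partition YAML must define 'frontal' and 'posterior'")
  }
  list(
    frontal = as.character(p$frontal),
    posterior = as.character(p$posterior)
  )
}

#' Write and read labeled CD datasets as flat CSV stores
#'
#' One flattened (time-major) row per SO plus a `label` column; feature
#' columns are named `t<bin>_<region>` so the bin width and region set are
#' recovered from the header on read.
#'
#' @param X Feature matrix with `t<bin>_<region>` column names (e.g., from
#'   [synth_cd_dataset()] or built with [cd_flatten()]).
#' @param y Labels, one per row.
#' @param path CSV path.
#' @return `write_cd_store` returns the path invisibly; `read_cd_store`
#'   returns a list `X`, `y`, `dt_ms`, `regions`.
#' @export
write_cd_store <- function(X, y, path) {
  stopifnot(nrow(X) == length(y), !is.null(colnames(X)))
  df <- tibble::as_tibble(as.data.frame(X))
  df <- dplyr::bind_cols(tibble::tibble(label = as.character(y)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_cd_store
#' @param regions Expected region set; reading fails, naming the expected
#'   count, if the file's regions differ. Use `NULL` to accept any region
#'   set.
#' @export
read_cd_store <- function(path, regions = so_regions()) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"label" %in% names(df)) stop_sostim("CD store must have a 'label' column")
  feats <- setdiff(names(df), "label")
  m <- regmatches(feats, regexec("^t([0-9]+)_(.+)$", feats))
  if (any(lengths(m) != 3)) {
    stop_sostim("feature columns must be named t<bin>_<region>")
  }
  bins <- as.integer(vapply(m, `[`, character(1), 2))
  regs <- vapply(m, `[`, character(1), 3)
  n_bins <- max(bins)
  file_regions <- regs[bins == 1]
  expected <- cd_feature_names(1000 / n_bins, file_regions)
  if (!(1000 / n_bins) %in% c(20, 50, 100, 200) ||
    !identical(feats, expected)) {
    stop_sostim(paste(
      "malformed CD store: columns must enumerate every region for each of",
      "a supported bin count (20/50/100/200 ms bins) in time-major order"
    ))
  }
  if (!is.null(regions) && !identical(file_regions, regions)) {
    stop_sostim(
      "CD store has %d regions (%s...) but %d were expected",
      length(file_regions), paste(utils::head(file_regions, 3), collapse = ", "),
      length(regions)
    )
  }
  list(
    X = as.matrix(df[, feats]), y = df$label,
    dt_ms = 1000 / n_bins, regions = file_regions
  )
}

#' Write the selected protocol as JSON
#'
#' @param selection An `so_selection` from [select_protocol()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_protocol_json <- function(selection, path) {
  stopifnot(inherits(selection, "so_selection"))
  s <- selection$selected
  cand <- s$candidate[[1]]
  out <- list(
    montage = list(
      electrodes = cand$paradigm$montage$electrodes,
      polarity = cand$paradigm$montage$polarity
    ),
    waveform = list(
      kind = cand$paradigm$waveform$kind,
      params = as.list(cand$paradigm$waveform$params)
    ),
    dt_ms = s$dt_ms, epsilon = s$epsilon, posterior = s$posterior,
    wcc = s$wcc, wmse = s$wmse, no_global = selection$no_global
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
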