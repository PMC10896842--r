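#' Standard scalp electrode layout
#'
#' An approximate 2-D projection of 10-20 / 10-10 electrode positions used
#' by the synthetic transfer operator and for quartile assignment. The
#' scalp is split into four quartiles (left/right by the midline,
#' anterior/posterior by the central row); electrodes on the central row
#' are labeled `"central"` and excluded from montage search, matching the
#' practice of disregarding central-region electrodes when composing
#' stimulation montages.
#'
#' @return Tibble with columns `name`, `x` (left negative), `y` (anterior
#'   positive) and `quartile` (`left_anterior`, `right_anterior`,
#'   `left_posterior`, `right_posterior` or `central`).
#' @export
scalp_electrodes <- function() {
  rows <- list(
    Fp = list(y = 0.85, cols = c(1, 2)),
    AF = list(y = 0.65, cols = c(7, 3, 4, 8)),
    F = list(y = 0.45, cols = c(7, 5, 3, 1, 2, 4, 6, 8)),
    FC = list(y = 0.22, cols = c(5, 3, 1, 2, 4, 6)),
    C = list(y = 0.00, cols = c(5, 3, 1, 2, 4, 6)),
    CP = list(y = -0.22, cols = c(5, 3, 1, 2, 4, 6)),
    P = list(y = -0.45, cols = c(7, 5, 3, 1, 2, 4, 6, 8)),
    PO = list(y = -0.65, cols = c(7, 3, 4, 8)),
    O = list(y = -0.85, cols = c(1, 2))
  )
  col_x <- c(`1` = 0.15, `2` = 0.15, `3` = 0.35, `4` = 0.35,
             `5` = 0.55, `6` = 0.55, `7` = 0.75, `8` = 0.75)
  out <- purrr::imap(rows, function(r, prefix) {
    tibble::tibble(
      name = paste0(prefix, r$cols),
      x = ifelse(r$cols %% 2 == 1, -1, 1) * col_x[as.character(r$cols)],
      y = r$y
    )
  })
  df <- dplyr::bind_rows(out)
  df$quartile <- dplyr::case_when(
    abs(df$y) < 0.1 ~ "central",
    df$x < 0 & df$y > 0 ~ "left_anterior",
    df$x > 0 & df$y > 0 ~ "right_anterior",
    df$x < 0 ~ "left_posterior",
    TRUE ~ "right_posterior"
  )
  df
}

#' Default per-quartile candidate electrode lists
#'
#' @param n Optional number of electrodes per quartile (first `n` of each
#'   quartile in layout order); default keeps all non-central electrodes.
#' @param electrodes Electrode layout table, see [scalp_electrodes()].
#' @return Named list with elements `left_anterior`, `right_anterior`,
#'   `left_posterior`, `right_posterior`.
#' @export
default_quartiles <- function(n = NULL, electrodes = scalp_electrodes()) {
  qs <- c("left_anterior", "right_anterior", "left_posterior", "right_posterior")
  out <- lapply(qs, function(q) electrodes$name[electrodes$quartile == q])
  names(out) <- qs
  if (!is.null(n)) out <- lapply(out, utils::head, n)
  out
}

#' Four-electrode stimulation montage
#'
#' A montage is four scalp electrodes, one per quartile, two driven anodally
#' (+1) and two cathodally (-1) so electrode voltages sum to zero. The
#' physical realization in the forward model uses 5 x 5 cm pads at +/- 1 V;
#' inside this package the montage only indexes the linear transfer
#' operator.
#'
#' @param electrodes Character vector of 4 distinct electrode names, ordered
#'   (left-anterior, right-anterior, left-posterior, right-posterior).
#' @param polarity Numeric vector of +1/-1 per electrode; exactly two of
#'   each (default anterior pair anodal).
#' @return An object of class `so_montage`.
#' @export
montage <- function(electrodes, polarity = c(1, 1, -1, -1)) {
  electrodes <- as.character(electrodes)
  if (length(electrodes) != 4 || anyDuplicated(electrodes)) {
    stop_sostim("a montage needs exactly 4 distinct electrodes")
  }
  polarity <- as.numeric(polarity)
  if (length(polarity) != 4 || !all(polarity %in% c(-1, 1)) ||
    sum(polarity) != 0) {
    stop_sostim("polarity must be four values in {-1, +1} summing to zero")
  }
  structure(
    list(
      electrodes = electrodes, polarity = polarity,
      key = paste0(ifelse(polarity > 0, "+", "-"), electrodes, collapse = " ")
    ),
    class = "so_montage"
  )
}

#' @export
print.so_montage <- function(x, ...) {
  cat("<so_montage>", x$key, "\n")
  invisible(x)
}

#' Enumerate candidate stimulation montages
#'
#' Takes the Cartesian product of one-electrode-per-quartile choices. By
#' default the two anterior electrodes are anodal and the two posterior
#' cathodal; `polarity = "all"` instead expands each electrode combination
#' into all six zero-sum two-anodal/two-cathodal sign patterns.
#'
#' @param quartiles Named list of candidate electrode names per quartile
#'   (see [default_quartiles()]).
#' @param polarity `"anterior_anodal"` (default) or `"all"`.
#' @return Tibble with one row per montage: the four electrode columns, a
#'   `polarity` pattern string, a stable `key` and a `montage` list-column.
#' @examples
#' nrow(enumerate_montages(default_quartiles(2))) # 2^4 = 16
#' @export
enumerate_montages <- function(quartiles = default_quartiles(),
                               polarity = c("anterior_anodal", "all")) {
  polarity <- match.arg(polarity)
  qs <- c("left_anterior", "right_anterior", "left_posterior", "right_posterior")
  if (!all(qs %in% names(quartiles))) {
    stop_sostim("quartiles must name: %s", paste(qs, collapse = ", "))
  }
  quartiles <- quartiles[qs]
  if (any(lengths(quartiles) == 0)) stop_sostim("every quartile list must be non-empty")
  all_names <- unlist(quartiles, use.names = FALSE)
  if (anyDuplicated(all_names)) {
    stop_sostim(
      "electrode(s) assigned to more than one quartile: %s",
      paste(unique(all_names[duplicated(all_names)]), collapse = ", ")
    )
  }
  grid <- expand.grid(
    left_anterior = quartiles$left_anterior,
    right_anterior = quartiles$right_anterior,
    left_posterior = quartiles$left_posterior,
    right_posterior = quartiles$right_posterior,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  pols <- if (polarity == "anterior_anodal") {
    list(c(1, 1, -1, -1))
  } else {
    pos_pairs <- utils::combn(4, 2, simplify = FALSE)
    lapply(pos_pairs, function(ix) {
      p <- rep(-1, 4)
      p[ix] <- 1
      p
    })
  }
  rows <- purrr::map(pols, function(p) {
    g <- tibble::as_tibble(grid)
    g$polarity <- paste(ifelse(p > 0, "+", "-"), collapse = "")
    g$montage <- purrr::pmap(
      grid,
      function(left_anterior, right_anterior, left_posterior, right_posterior) {
        montage(
          c(left_anterior, right_anterior, left_posterior, right_posterior), p
        )
      }
    )
    g
  })
  out <- dplyr::bind_rows(rows)
  out$key <- purrr::map_chr(out$montage, "key")
  out
}
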