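#' Matthews correlation coefficient
#'
#' Balanced binary-classification metric in \[-1, 1\], robust to class
#' imbalance:
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' If any of the four denominator factors is zero the value is undefined;
#' the conventional value 0 is returned with a warning.
#'
#' @param tp,tn,fp,fn Non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return A number in \[-1, 1\].
#' @examples
#' mcc(3, 4, 1, 2)
#' @export
mcc <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_sostim("confusion-matrix counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop_sostim("confusion matrix is empty")
  denom <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(denom == 0)) {
    rlang::warn("MCC undefined (a confusion-matrix margin is zero); returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(prod(as.numeric(denom)))
}

weighted_mean_w <- function(x, w) sum(w * x) / sum(w)

weighted_cov_w <- function(x, y, w) {
  mx <- weighted_mean_w(x, w)
  my <- weighted_mean_w(y, w)
  sum(w * (x - mx) * (y - my)) / sum(w)
}

check_weights <- function(x, y, w) {
  if (length(x) != length(y)) {
    stop_sostim("x and y must have equal length (%d vs %d)", length(x), length(y))
  }
  if (length(w) == 1) w <- rep(w, length(x))
  if (length(w) != length(x)) {
    stop_sostim("weights length %d does not match data length %d", length(w), length(x))
  }
  if (any(w < 0) || !all(is.finite(w))) stop_sostim("weights must be finite and >= 0")
  if (sum(w) <= 0) stop_sostim("weights must not sum to zero")
  w
}

#' Weighted correlation coefficient
#'
#' Weighted Pearson correlation between two feature vectors:
#' \eqn{WCC = cov(x, y; w) / \sqrt{cov(x, x; w)\, cov(y, y; w)}} with
#' \eqn{cov(x, y; w) = \sum_i w_i (x_i - m(x; w))(y_i - m(y; w)) / \sum_i w_i}
#' and \eqn{m(x; w) = \sum_i w_i x_i / \sum_i w_i}. With equal weights this
#' is the ordinary Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length (data and prediction).
#' @param w Non-negative weights (importance per feature); a scalar is
#'   recycled.
#' @return A number in \[-1, 1\].
#' @export
wcc <- function(x, y, w = 1) {
  w <- check_weights(x, y, w)
  vx <- weighted_cov_w(x, x, w)
  vy <- weighted_cov_w(y, y, w)
  if (vx <= 0 || vy <= 0) {
    stop_sostim("WCC undefined: zero weighted variance in x or y")
  }
  weighted_cov_w(x, y, w) / sqrt(vx * vy)
}

#' Weighted mean squared error
#'
#' \eqn{WMSE = \sum_i w_i\, d(y_i, x_i) / \sum_i w_i} with
#' \eqn{d = (y - x)^2} by default (`loss = "squared"`) or \eqn{|y - x|}
#' (`loss = "absolute"`). The weight normalization makes the value invariant
#' to rescaling all weights.
#'
#' @inheritParams wcc
#' @param loss Residual transform, `"squared"` (default) or `"absolute"`.
#' @return A non-negative number.
#' @export
wmse <- function(x, y, w = 1, loss = c("squared", "absolute")) {
  loss <- match.arg(loss)
  w <- check_weights(x, y, w)
  d <- if (loss == "squared") (y - x)^2 else abs(y - x)
  sum(w * d) / sum(w)
}

#' Weighted objective for waveform optimization
#'
#' The fitness minimized by the genetic algorithm: the weighted mean
#' discrepancy between the simulated CD feature vector and the target
#' (average global SO) CD feature vector,
#' \eqn{\epsilon = \sum_i \omega_i\, d(x_i, x^*_i) / \sum_i \omega_i},
#' where \eqn{\omega_i} are the ANOVA-F feature weights and `d` is the
#' squared (default) or absolute difference.
#'
#' @param x_sim Flattened simulated CD features.
#' @param x_target Flattened target CD features.
#' @param w Non-negative feature weights; a scalar is recycled.
#' @param loss `"squared"` (default) or `"absolute"`.
#' @return A non-negative number; 0 iff the weighted features coincide.
#' @export
objective_epsilon <- function(x_sim, x_target, w = 1,
                              loss = c("squared", "absolute")) {
  wmse(x = x_target, y = x_sim, w = w, loss = loss)
}

# confusion counts for a binary problem with a designated positive class
confusion_counts <- function(truth, pred, positive = "global") {
  truth <- as.character(truth)
  pred <- as.character(pred)
  list(
    tp = sum(truth == positive & pred == positive),
    tn = sum(truth != positive & pred != positive),
    fp = sum(truth != positive & pred == positive),
    fn = sum(truth == positive & pred != positive)
  )
}
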