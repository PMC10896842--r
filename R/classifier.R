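#' ANOVA-F univariate feature weights
#'
#' Per flattened CD feature, the one-way ANOVA F statistic between the two
#' label groups (between-group mean square over within-group mean square),
#' used both as a univariate feature ranking and as the weight vector of
#' the optimization objective. F is invariant to adding a constant to a
#' feature and to rescaling a feature, and is 0 where group means
#' coincide.
#'
#' @param X Numeric matrix, observations x features (flattened time-major
#'   CD vectors).
#' @param y Binary labels (factor/character/logical), both classes present,
#'   at least 3 observations.
#' @return Named non-negative numeric vector, one weight per feature.
#' @export
anova_f_weights <- function(X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop_sostim("both classes must be present to compute F")
  if (nrow(X) < 3) stop_sostim("need at least 3 observations")
  if (length(y) != nrow(X)) stop_sostim("length(y) must equal nrow(X)")
  g <- nlevels(y)
  ns <- tabulate(y)
  grand <- colMeans(X)
  ssb <- 0
  ssw <- 0
  for (lev in seq_len(g)) {
    Xi <- X[as.integer(y) == lev, , drop = FALSE]
    mi <- colMeans(Xi)
    ssb <- ssb + ns[lev] * (mi - grand)^2
    ssw <- ssw + colSums(sweep(Xi, 2, mi)^2)
  }
  msb <- ssb / (g - 1)
  msw <- ssw / (nrow(X) - g)
  f <- ifelse(msw == 0, ifelse(msb == 0, 0, NA_real_), msb / msw)
  if (anyNA(f)) {
    stop_sostim("zero within-group variance with distinct group means; F undefined")
  }
  stats::setNames(f, colnames(X))
}

#' Train the bagged-trees global/non-global SO classifier
#'
#' An ensemble of `n_trees` regression trees on a 0/1 encoding of the
#' class, each grown on a with-replacement bootstrap of the training rows,
#' with every feature available at every split (`mtry = ncol(X)`, i.e.,
#' pure bootstrap aggregation). Each tree's leaf value is the bootstrap
#' class frequency in that leaf, so the ensemble posterior for an instance
#' is the average of the per-tree class-probability estimates; the
#' predicted class is the one with the larger average. With uninformative
#' features the posterior collapses to the class prior.
#'
#' @param X Feature matrix, observations x flattened CD features.
#' @param y Binary labels; `positive` names the class whose posterior is
#'   reported (default `"global"`).
#' @param seed Integer seed; training is deterministic given the seed.
#' @param n_trees Ensemble size (default 100).
#' @param mtry Features considered per split (default all = bagging).
#' @param min_node Minimum terminal-node size (default 5).
#' @param positive Positive class label.
#' @return An object of class `so_classifier`.
#' @export
train_so_classifier <- function(X, y, seed = NULL, n_trees = 100,
                                mtry = NULL, min_node = 5,
                                positive = "global") {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_sostim("need at least 2 training rows")
  y <- factor(as.character(y))
  if (nlevels(y) != 2) {
    stop_sostim(
      "need exactly 2 classes; got: %s",
      paste(levels(y), collapse = ", ")
    )
  }
  if (!positive %in% levels(y)) {
    stop_sostim("positive class '%s' not among labels", positive)
  }
  if (is.null(mtry)) mtry <- ncol(X)
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  y01 <- as.numeric(y == positive)
  # regression trees on the 0/1 class encoding are intentional: leaf means
  # are class frequencies, so averaging trees yields a probability
  forest <- with_seed(seed, withCallingHandlers(
    randomForest::randomForest(
      x = X, y = y01, ntree = n_trees, mtry = mtry, nodesize = min_node,
      replace = TRUE
    ),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  ))
  structure(
    list(
      forest = forest, levels = levels(y), positive = positive,
      feature_names = colnames(X), n_features = ncol(X),
      n_trees = n_trees, mtry = mtry, min_node = min_node, seed = seed
    ),
    class = "so_classifier"
  )
}

#' @export
print.so_classifier <- function(x, ...) {
  cat(
    "<so_classifier>", x$n_trees, "bagged trees,", x$n_features,
    "features, positive class:", x$positive, "\n"
  )
  invisible(x)
}

#' Posterior probability of the global class
#'
#' @param model An `so_classifier`.
#' @param x A feature vector, or a matrix with one row per instance, whose
#'   feature count matches the training features.
#' @return Probabilities in \[0, 1\], one per instance.
#' @export
posterior_global <- function(model, x) {
  stopifnot(inherits(model, "so_classifier"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_features) {
    stop_sostim(
      "feature length %d does not match the %d training features",
      ncol(x), model$n_features
    )
  }
  colnames(x) <- model$feature_names
  p <- unname(predict(model$forest, newdata = x))
  pmin(pmax(p, 0), 1)
}

#' @export
predict.so_classifier <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- posterior_global(object, newdata)
  if (type == "prob") {
    return(p)
  }
  neg <- setdiff(object$levels, object$positive)
  ifelse(p >= 0.5, object$positive, neg)
}

stratified_folds <- function(y, folds, seed = NULL) {
  y <- factor(y)
  with_seed(seed, {
    ids <- integer(length(y))
    if (min(table(y)) < folds) {
      # too few members of one class to stratify (e.g., leave-one-out):
      # fall back to plain random folds; training folds are checked below
      ids <- sample(rep_len(seq_len(folds), length(y)))
    } else {
      for (lev in levels(y)) {
        ix <- which(y == lev)
        ids[ix] <- sample(rep_len(seq_len(folds), length(ix)))
      }
    }
    ids
  })
}

#' Cross-validated MCC of the bagged-trees classifier
#'
#' Stratified k-fold cross validation; out-of-fold predictions are pooled
#' into a single confusion matrix from which one MCC is computed (pooling
#' is stable under class imbalance).
#'
#' @inheritParams train_so_classifier
#' @param folds Number of folds (default 5).
#' @param ... Further arguments to [train_so_classifier()].
#' @return An object of class `so_cv` with fields `mcc`, `confusion`
#'   (tp/tn/fp/fn), `fold` (assignments) and `posterior` (out-of-fold).
#' @export
crossval_mcc <- function(X, y, folds = 5, seed = NULL, positive = "global",
                         ...) {
  X <- as.matrix(X)
  y <- factor(as.character(y))
  fold <- stratified_folds(y, folds, seed = derive_seed(seed, 0) %||% NULL)
  post <- numeric(nrow(X))
  for (f in seq_len(folds)) {
    hold <- fold == f
    if (nlevels(droplevels(y[!hold])) < 2) {
      stop_sostim("both classes must be present in every training fold")
    }
    model <- train_so_classifier(X[!hold, , drop = FALSE], y[!hold],
      seed = derive_seed(seed, f), positive = positive, ...
    )
    post[hold] <- posterior_global(model, X[hold, , drop = FALSE])
  }
  neg <- setdiff(levels(y), positive)
  pred <- ifelse(post >= 0.5, positive, neg)
  cm <- confusion_counts(y, pred, positive)
  structure(
    list(
      mcc = mcc(cm$tp, cm$tn, cm$fp, cm$fn), confusion = cm,
      fold = fold, posterior = post, folds = folds, positive = positive
    ),
    class = "so_cv"
  )
}

#' @export
print.so_cv <- function(x, ...) {
  cat(
    "<so_cv>", x$folds, "folds | pooled MCC:", round(x$mcc, 4),
    sprintf(
      "| TP %d TN %d FP %d FN %d\n", x$confusion$tp, x$confusion$tn,
      x$confusion$fp, x$confusion$fn
    )
  )
  invisible(x)
}

#' @export
tidy.so_cv <- function(x, ...) {
  tibble::tibble(
    metric = c("tp", "tn", "fp", "fn"),
    count = unlist(x$confusion[c("tp", "tn", "fp", "fn")])
  )
}

#' @export
glance.so_cv <- function(x, ...) {
  tibble::tibble(mcc = x$mcc, folds = x$folds, n = length(x$fold))
}

#' @export
tidy.so_classifier <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble::tibble(feature = rownames(imp), importance = imp[, 1])
}

#' @export
glance.so_classifier <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees, mtry = x$mtry, min_node = x$min_node,
    n_features = x$n_features
  )
}

#' Seeded randomized hyperparameter search for the SO classifier
#'
#' Samples candidate (`min_node`, `mtry`) pairs and scores each by inner
#' stratified cross-validated MCC, returning the best pair and the search
#' trace. A simple, reproducible stand-in for more elaborate hyperparameter
#' optimizers; the contract (hyperparameters chosen by inner CV) is the
#' same.
#'
#' @inheritParams crossval_mcc
#' @param n_candidates Number of sampled configurations (default 8).
#' @param inner_folds Inner CV folds (default 5).
#' @return List with `best` (a one-row tibble) and `trace` (all candidates
#'   with their inner MCC).
#' @export
tune_so_classifier <- function(X, y, seed = NULL, n_candidates = 8,
                               inner_folds = 5, positive = "global") {
  p <- ncol(X)
  cand <- with_seed(seed, tibble::tibble(
    min_node = sample(c(1L, 5L, 10L, 20L, 50L), n_candidates, replace = TRUE),
    mtry = pmax(1L, sample(
      c(p, ceiling(p / 3), ceiling(sqrt(p))), n_candidates,
      replace = TRUE
    ))
  ))
  cand <- dplyr::distinct(cand)
  cand$mcc <- vapply(seq_len(nrow(cand)), function(i) {
    crossval_mcc(X, y,
      folds = inner_folds, seed = derive_seed(seed, 100 + i),
      positive = positive, min_node = cand$min_node[i], mtry = cand$mtry[i]
    )$mcc
  }, numeric(1))
  list(best = cand[which.max(cand$mcc), ], trace = cand)
}
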