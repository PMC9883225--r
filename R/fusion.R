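## Feature fusion, selection, gradient-boosted classification, and
## record-level majority voting.

#' Gradient-boosting hyperparameters
#'
#' Defaults are the tuned operating point of the method: 600 trees of depth
#' 7, minimum leaf weight 1, L1 coefficient 1, L2 coefficient 3, learning
#' rate 0.01, three-class softmax objective.
#'
#' @param n_trees,max_depth,min_leaf_weight,l1,l2,learning_rate Booster
#'   hyperparameters.
#' @param seed RNG seed passed to the booster.
#' @return A list of class `boost_config`.
#' @export
boost_config <- function(n_trees = 600L, max_depth = 7L, min_leaf_weight = 1,
                         l1 = 1, l2 = 3, learning_rate = 0.01, seed = 1L) {
  structure(as.list(environment()), class = "boost_config")
}

#' Variance filter
#'
#' Drops feature columns whose sample variance is strictly below the
#' threshold (a column with variance exactly 0.05 is kept). Variances are
#' computed on the supplied (training) matrix only; the returned keep-mask
#' is replayed verbatim at inference.
#'
#' @param table Numeric feature matrix (rows = cycles).
#' @param threshold Variance threshold, default 0.05.
#' @return `list(matrix, keep)` where `keep` is a named logical mask.
#' @export
variance_filter <- function(table, threshold = 0.05) {
  stopifnot(is.matrix(table), nrow(table) > 0L)
  v <- apply(table, 2L, stats::var)
  keep <- v >= threshold
  if (!any(keep)) stop("variance_filter: all columns dropped")
  list(matrix = table[, keep, drop = FALSE], keep = keep)
}

#' Importance-based feature selection
#'
#' Fits an auxiliary boosted-tree model, ranks features by total gain, and
#' keeps the `target_dim` best. Columns named `deep_*` (the CNN block) are
#' exempt from removal, so the deep block survives intact; the remaining
#' budget goes to the top-ranked time-frequency features. Features the
#' auxiliary model never used rank below all used ones.
#'
#' @param table Numeric feature matrix (after [variance_filter()]).
#' @param labels Class labels (character/factor).
#' @param config A [boost_config()].
#' @param target_dim Target dimensionality, default 212.
#' @return `list(matrix, keep, ranking)`; `keep` is a named logical mask
#'   with attribute `flagged` when `target_dim` exceeded the available count.
#' @export
importance_select <- function(table, labels, config = boost_config(),
                              target_dim = 212L) {
  stopifnot(is.matrix(table))
  nf <- ncol(table)
  flagged <- FALSE
  if (target_dim >= nf) {
    keep <- rep(TRUE, nf); names(keep) <- colnames(table)
    flagged <- target_dim > nf
    attr(keep, "flagged") <- flagged
    return(list(matrix = table, keep = keep, ranking = colnames(table)))
  }
  booster <- fit_booster(table, labels, config)
  imp <- xgboost::xgb.importance(model = booster$model)
  gain <- stats::setNames(rep(0, nf), colnames(table))
  gain[imp$Feature] <- imp$Gain
  ## stable ranking: gain desc, original order breaks ties
  ord <- order(-gain, seq_len(nf))
  ranked <- colnames(table)[ord]
  is_deep <- grepl("^deep_", colnames(table))
  keep <- is_deep
  budget <- target_dim - sum(is_deep)
  if (budget < 0L) budget <- 0L
  for (nm in ranked) {
    if (budget == 0L) break
    j <- match(nm, colnames(table))
    if (!keep[j]) { keep[j] <- TRUE; budget <- budget - 1L }
  }
  names(keep) <- colnames(table)
  attr(keep, "flagged") <- flagged
  list(matrix = table[, keep, drop = FALSE], keep = keep, ranking = ranked)
}

## Shared booster fit used by both selection and classification.
fit_booster <- function(table, labels, config) {
  labels <- factor(as.character(labels), levels = pah_classes())
  y <- as.integer(labels) - 1L
  if (length(unique(y)) < 2L) stop("fit_booster: degenerate labels")
  dtrain <- xgboost::xgb.DMatrix(table, label = y)
  params <- list(objective = "multi:softprob", num_class = length(pah_classes()),
                 eta = config$learning_rate, max_depth = config$max_depth,
                 min_child_weight = config$min_leaf_weight,
                 alpha = config$l1, lambda = config$l2,
                 nthread = 1L, seed = config$seed)
  model <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = config$n_trees, verbose = 0)
  list(model = model, classes = pah_classes())
}

#' Train the three-class cycle classifier
#'
#' Gradient-boosted trees (XGBoost) with the configured hyperparameters on
#' the selected fusion features. One row per cardiac cycle.
#'
#' @param table Selected feature matrix.
#' @param labels Class label per row.
#' @param config A [boost_config()].
#' @return An object of class `pah_booster`.
#' @export
train_classifier <- function(table, labels, config = boost_config()) {
  fit <- fit_booster(table, labels, config)
  structure(list(model = fit$model, classes = fit$classes,
                 feature_names = colnames(table), config = config),
            class = "pah_booster")
}

#' Predict cycle classes
#'
#' @param object A `pah_booster`.
#' @param newdata Feature matrix with the model's columns.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Character vector of classes, or a probability matrix.
#' @export
predict.pah_booster <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata))
  newdata <- newdata[, object$feature_names, drop = FALSE]
  pr <- predict(object$model, xgboost::xgb.DMatrix(newdata))
  if (!is.matrix(pr))  # older xgboost returns a flat row-major vector
    pr <- matrix(pr, ncol = length(object$classes), byrow = TRUE)
  colnames(pr) <- object$classes
  if (type == "prob") return(pr)
  object$classes[max.col(pr, ties.method = "first")]
}

#' Majority vote over cycle labels
#'
#' Single-pass candidate/counter (Boyer-Moore) vote: with counter at zero
#' adopt the current element; increment on agreement, decrement on
#' disagreement. Because the single pass can return a non-modal element when
#' no strict majority exists, a verification pass counts the candidate; if
#' it is not a strict majority, the highest-count class wins, ties broken
#' deterministically by class order (Normal < CHD < CHD-PAH), and the result
#' is flagged.
#'
#' @param labels Non-empty character vector of cycle labels.
#' @return The winning label, with attributes `counts` (per-class counts)
#'   and `fallback` (`TRUE` when the verification pass overrode the
#'   single-pass candidate or no strict majority existed).
#' @export
majority_vote <- function(labels) {
  stopifnot(length(labels) > 0L)
  m <- labels[1L]; i <- 0L
  for (x in labels) {
    if (i == 0L) { m <- x; i <- 1L }
    else if (identical(m, x)) i <- i + 1L
    else i <- i - 1L
  }
  counts <- table(factor(labels, levels = union(pah_classes(), unique(labels))))
  counts <- counts[counts > 0 | names(counts) %in% unique(labels)]
  fallback <- FALSE
  if (counts[[m]] * 2L <= length(labels)) {
    fallback <- TRUE
    ordered_classes <- intersect(pah_classes(), names(counts))
    extra <- setdiff(names(counts), ordered_classes)
    cand <- c(ordered_classes, extra)
    cc <- counts[cand]
    m <- cand[which.max(cc)]
  }
  structure(m, counts = counts, fallback = fallback)
}
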