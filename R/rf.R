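#' Fit a random-forest classifier (binary, Gini splitting)
#'
#' A compact CART random forest grown to purity (nodesize 1) with `mtry`
#' split candidates per node, bootstrap bagging, mean-decrease-Gini
#' importance and out-of-bag error. Deterministic for a given `seed`,
#' independently of R's RNG state.
#'
#' @param x numeric matrix of predictors (no missing values).
#' @param y binary response: logical or 0/1 vector of length `nrow(x)`.
#' @param ntree number of trees.
#' @param mtry number of candidate features per split (default
#'   `floor(sqrt(ncol(x)))`).
#' @param nodesize minimum node size eligible for splitting is `2 * nodesize`.
#' @param seed integer seed for the forest's own RNG.
#' @param xtest optional matrix to predict during training (cheaper than a
#'   separate [predict] call when the forest itself is not needed).
#' @param keep_forest store the trees for later prediction?
#' @param bootstrap draw a bootstrap sample per tree? Setting `FALSE` (with
#'   `mtry = ncol(x)`) yields a deterministic single CART tree, used by the
#'   test-suite oracle.
#' @return an `rf_model`: list with `importance` (mean decrease in Gini per
#'   feature), `oob_error`, `oob_prob`, optionally `test_prob` and the
#'   forest.
#' @export
rf_fit <- function(x, y, ntree = 500, mtry = NULL, nodesize = 1, seed = 1,
                   xtest = NULL, keep_forest = TRUE, bootstrap = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("x must not contain missing values")
  y <- as.integer(as.logical(y))
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (length(unique(y)) < 2) stop("y must contain both classes")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  mtry <- min(max(1L, as.integer(mtry)), ncol(x))
  if (!is.null(xtest)) {
    xtest <- as.matrix(xtest)
    storage.mode(xtest) <- "double"
  }
  res <- .rf_train_cpp(x, y, as.integer(ntree), mtry, as.integer(nodesize),
                       as.double(seed), xtest, keep_forest, bootstrap)
  names(res$importance) <- colnames(x)
  res$mtry <- mtry
  res$ntree <- as.integer(ntree)
  if (!is.null(res$test_prob) && !is.null(rownames(xtest)))
    names(res$test_prob) <- rownames(xtest)
  class(res) <- "rf_model"
  res
}

#' Predict class-1 probabilities from a fitted forest
#'
#' @param object an `rf_model` fitted with `keep_forest = TRUE`.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of averaged tree probabilities in \[0, 1\].
#' @export
predict.rf_model <- function(object, newdata, ...) {
  if (is.null(object$forest)) stop("model was fitted with keep_forest = FALSE")
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  p <- .rf_predict_cpp(object$forest, newdata)
  names(p) <- rownames(newdata)
  p
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("rf_model: %d trees, mtry %d, OOB error %.4f\n",
              x$ntree, x$mtry, x$oob_error))
  invisible(x)
}
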