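#' Configuration of the positive-unlabeled bagging ensemble
#'
#' @param n_models number of bagged models, each trained against a fresh
#'   pseudo-negative sample (production default 10,000; the averaged score
#'   stabilizes long before that, so tests use 100-200).
#' @param n_trees trees per random-forest model (default 1000).
#' @param mtry `"auto"` (`floor(sqrt(p))`) or an integer.
#' @param seed master seed; per-replicate seeds are derived from it
#'   deterministically so results do not depend on execution order.
#' @param step_factor multiplicative step for [tune_mtry()] (must be > 1).
#' @param improve minimum relative out-of-bag improvement for [tune_mtry()]
#'   to accept a move (default 0.01).
#' @return list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_models = 10000, n_trees = 1000, mtry = "auto",
                            seed = 1, step_factor = 1.5, improve = 0.01) {
  stopifnot(n_models >= 1, n_trees >= 1, step_factor > 1)
  structure(list(n_models = as.integer(n_models), n_trees = as.integer(n_trees),
                 mtry = mtry, seed = as.integer(seed),
                 step_factor = step_factor, improve = improve),
            class = "ensemble_config")
}

resolve_mtry <- function(cfg, p) {
  if (identical(cfg$mtry, "auto")) max(1L, as.integer(floor(sqrt(p))))
  else min(max(1L, as.integer(cfg$mtry)), p)
}

#' Sample a pseudo-negative set from the unlabeled pool
#'
#' Uniform sampling without replacement; deterministic for a given seed.
#'
#' @param pool character vector of candidate protein ids.
#' @param k sample size (the size of the positive set, for balance).
#' @param seed integer seed.
#' @return character vector of k protein ids.
#' @export
sample_negatives <- function(pool, k, seed) {
  if (k > length(pool)) stop("k exceeds the size of the negative pool")
  with_seed(seed, sample(pool, k, replace = FALSE))
}

#' Fit one balanced replicate of the ensemble
#'
#' Trains a random forest on the positives versus one pseudo-negative
#' sample (equal class sizes, no overlap).
#'
#' @param fm a [feature_matrix()].
#' @param positives,negatives disjoint, non-empty, equal-sized protein sets
#'   present in `fm`.
#' @param cfg an [ensemble_config()].
#' @param seed replicate seed (default: derived from `cfg$seed`).
#' @param keep_forest store trees for later [predict.rf_model()] calls?
#' @param xtest optional matrix to score during training.
#' @return an `rf_model` (importance = per-feature mean decrease in Gini).
#' @export
fit_replicate <- function(fm, positives, negatives, cfg, seed = NULL,
                          keep_forest = TRUE, xtest = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(intersect(positives, negatives)) > 0)
    stop("positives and negatives overlap")
  if (length(positives) == 0 || length(negatives) == 0)
    stop("both classes must be non-empty")
  if (length(positives) != length(negatives))
    stop("replicate training set must be balanced")
  ids <- c(positives, negatives)
  missing <- setdiff(ids, protein_ids(fm))
  if (length(missing)) stop("proteins absent from the feature matrix: ",
                            paste(head(missing, 5), collapse = ", "))
  x <- fm$values[ids, , drop = FALSE]
  y <- c(rep(1L, length(positives)), rep(0L, length(negatives)))
  rf_fit(x, y, ntree = cfg$n_trees, mtry = resolve_mtry(cfg, ncol(x)),
         seed = seed %||% derive_seed(cfg$seed, 1L), xtest = xtest,
         keep_forest = keep_forest)
}

#' Positive-unlabeled bagging: fit the full ensemble and score every protein
#'
#' For each of `cfg$n_models` replicates: draw a fresh balanced
#' pseudo-negative sample from the pool (without replacement), train a
#' random forest of `cfg$n_trees` trees on positives vs that sample, and
#' predict the class-1 probability of every protein in the feature matrix.
#' The druggability score is the mean predicted probability over all
#' replicates, and the reported importance is the mean decrease in Gini
#' averaged over replicates. Note the scores of training positives are
#' resubstitution scores, and pool proteins keep the predictions of
#' replicates in which they served as negatives.
#'
#' @param fm a [feature_matrix()] (typically log-transformed and min-max
#'   scaled).
#' @param sets a [build_study_sets()] result (uses `positives` and
#'   `negative_pool`).
#' @param cfg an [ensemble_config()].
#' @param keep_replicates keep the per-replicate probability matrix (memory
#'   heavy; for diagnostics/tests only).
#' @param replicate_order order in which replicates are executed; results
#'   are invariant to it because each replicate's seed depends only on its
#'   index and averaging is performed in index order.
#' @return a `druggability_result`: list with `scores` (named, in \[0,1\]),
#'   `importance` (named mean decrease in Gini), `replicate_seeds`, `config`.
#' @export
fit_predict_ensemble <- function(fm, sets, cfg, keep_replicates = FALSE,
                                 replicate_order = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  positives <- sets$positives
  pool <- sets$negative_pool
  if (length(positives) < 2) stop("need at least 2 positives")
  if (length(pool) < length(positives)) stop("negative pool smaller than the positive set")
  n <- cfg$n_models
  order_idx <- replicate_order %||% seq_len(n)
  stopifnot(setequal(order_idx, seq_len(n)))
  x_all <- fm$values
  seeds <- vapply(seq_len(n), function(m) derive_seed(cfg$seed, m), 1L)
  sequential <- identical(order_idx, seq_len(n))
  store <- keep_replicates || !sequential

  prob_sum <- numeric(nrow(x_all))
  imp_sum <- numeric(ncol(x_all))
  probs <- if (store) matrix(NA_real_, nrow(x_all), n, dimnames = list(protein_ids(fm), NULL))
  imps <- if (store) matrix(NA_real_, ncol(x_all), n, dimnames = list(feature_names(fm), NULL))

  for (m in order_idx) {
    s <- seeds[m]
    negatives <- sample_negatives(pool, length(positives), s)
    fit <- fit_replicate(fm, positives, negatives, cfg, seed = s,
                         keep_forest = FALSE, xtest = x_all)
    if (store) {
      probs[, m] <- fit$test_prob
      imps[, m] <- fit$importance
    } else {
      prob_sum <- prob_sum + fit$test_prob
      imp_sum <- imp_sum + fit$importance
    }
  }
  if (store) { # sum in index order so results are execution-order free
    prob_sum <- rowSums(probs)
    imp_sum <- rowSums(imps)
  }
  res <- list(scores = setNames(prob_sum / n, protein_ids(fm)),
              importance = setNames(imp_sum / n, feature_names(fm)),
              replicate_seeds = seeds,
              config = cfg)
  if (keep_replicates) res$replicate_probs <- probs
  class(res) <- "druggability_result"
  res
}

#' @export
print.druggability_result <- function(x, ...) {
  cat(sprintf("druggability_result: %d proteins, %d features, %d models x %d trees\n",
              length(x$scores), length(x$importance),
              x$config$n_models, x$config$n_trees))
  cat("  top scores:\n")
  top <- sort(x$scores, decreasing = TRUE)[1:min(5, length(x$scores))]
  for (nm in names(top)) cat(sprintf("    %s  %.3f\n", nm, top[nm]))
  invisible(x)
}

#' Tune mtry by out-of-bag error
#'
#' Starting from `floor(sqrt(p))`, walks the candidate mtry up and down by
#' the multiplicative `step_factor`, accepting a move only while the
#' relative out-of-bag error improvement is at least `improve` (the classic
#' `tuneRF` search). Falls back to the starting value when nothing
#' improves.
#'
#' @param fm a [feature_matrix()].
#' @param positives,negatives the balanced training sets.
#' @param cfg an [ensemble_config()] (`step_factor`, `improve`, `n_trees`,
#'   `seed` are used).
#' @return the selected integer mtry.
#' @export
tune_mtry <- function(fm, positives, negatives, cfg) {
  p <- ncol(fm$values)
  start <- max(1L, as.integer(floor(sqrt(p))))
  if (p == 1) return(1L)
  oob <- function(m) {
    fit <- fit_replicate(fm, positives, negatives,
                         ensemble_config(n_models = 1, n_trees = cfg$n_trees,
                                         mtry = m, seed = cfg$seed),
                         seed = derive_seed(cfg$seed, 982451L + m),
                         keep_forest = FALSE)
    fit$oob_error
  }
  best <- start
  best_err <- oob(start)
  for (dir in c(1, -1)) {
    m <- start
    err <- best_err
    repeat {
      nxt <- if (dir > 0) as.integer(ceiling(m * cfg$step_factor))
             else as.integer(floor(m / cfg$step_factor))
      nxt <- min(max(nxt, 1L), as.integer(p))
      if (nxt == m) break
      e <- oob(nxt)
      gain <- if (err > 0) (err - e) / err else 0
      if (gain < cfg$improve) break
      m <- nxt; err <- e
      if (e < best_err) { best <- m; best_err <- e }
    }
  }
  best
}
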