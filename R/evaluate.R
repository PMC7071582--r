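#' ROC curve and AUC for scored positives vs negatives
#'
#' AUC is computed with the rank (Mann-Whitney) formulation, counting ties
#' as 1/2; the curve is a threshold sweep over the observed scores.
#'
#' @param scores named numeric vector of per-protein scores.
#' @param positives,negatives disjoint, non-empty sets of protein ids
#'   present in `scores`.
#' @return list with `auc` and `roc_points` (data.frame `fpr`, `tpr`,
#'   running from (0,0) to (1,1), monotone in both coordinates).
#' @export
roc_auc <- function(scores, positives, negatives) {
  if (length(positives) == 0 || length(negatives) == 0)
    stop("both classes must be non-empty")
  if (length(intersect(positives, negatives)) > 0)
    stop("positives and negatives overlap")
  sp <- scores[positives]
  sn <- scores[negatives]
  if (anyNA(sp) || anyNA(sn)) stop("all proteins in both classes must be scored")
  np <- length(sp); nn <- length(sn)
  r <- rank(c(sp, sn))
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  auc <- u / (np * nn)

  s <- c(sp, sn)
  y <- c(rep(1L, np), rep(0L, nn))
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  # merge ties: one ROC point per distinct threshold
  last <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(y)[last] / np
  fpr <- cumsum(1 - y)[last] / nn
  list(auc = auc,
       roc_points = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Univariate feature differentiation tests
#'
#' Continuous features are compared between classes with a two-sided
#' Wilcoxon rank-sum test; categorical indicator columns with a chi-squared
#' test (no continuity correction) on the 2 x 2 value-by-class table.
#' Constant features are skipped with a warning.
#'
#' @param fm a [feature_matrix()].
#' @param positives,negatives protein-id sets present in `fm`.
#' @return data.frame with columns `feature`, `kind`, `test`, `statistic`,
#'   `p_value`.
#' @export
feature_tests <- function(fm, positives, negatives) {
  stopifnot(inherits(fm, "feature_matrix"))
  xp <- fm$values[positives, , drop = FALSE]
  xn <- fm$values[negatives, , drop = FALSE]
  out <- lapply(feature_names(fm), function(f) {
    a <- xp[, f]; b <- xn[, f]
    if (length(unique(c(a, b))) < 2) {
      warning("constant feature skipped: ", f)
      return(data.frame(feature = f, kind = fm$kinds[f], test = NA_character_,
                        statistic = NA_real_, p_value = NA_real_))
    }
    if (fm$kinds[f] == "continuous") {
      ht <- suppressWarnings(wilcox.test(a, b))
      data.frame(feature = f, kind = "continuous", test = "wilcoxon",
                 statistic = unname(ht$statistic), p_value = ht$p.value)
    } else {
      tab <- table(value = c(a, b),
                   class = rep(c("pos", "neg"), c(length(a), length(b))))
      zero <- rowSums(tab) == 0
      if (any(zero)) {
        warning("dropping empty level(s) in feature ", f)
        tab <- tab[!zero, , drop = FALSE]
      }
      ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
      data.frame(feature = f, kind = "categorical", test = "chi_squared",
                 statistic = unname(ht$statistic), p_value = ht$p.value)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Repeated leave-one-out cross-validation of the balanced classifier
#'
#' For each repeat a fresh balanced pseudo-negative sample is drawn from
#' the pool; each example (positive or sampled negative) is then held out
#' in turn, a forest is trained on the rest, and the held-out example is
#' classified at probability threshold 0.5. Sensitivity is computed over
#' positives, specificity over the sampled negatives, and AUC from the
#' held-out scores; all four metrics are averaged over repeats.
#'
#' @param fm a [feature_matrix()].
#' @param positives positive protein ids (at least 3).
#' @param negative_pool pool to draw pseudo-negatives from.
#' @param cfg an [ensemble_config()] (`n_trees`, `mtry`, `seed`).
#' @param n_repeats number of random negative sets (production default in
#'   the workflow: 100).
#' @return list with `sensitivity`, `specificity`, `accuracy`, `auc` and
#'   the per-repeat data.frame `per_repeat`.
#' @export
loocv <- function(fm, positives, negative_pool, cfg, n_repeats = 10) {
  if (length(positives) < 3) stop("need at least 3 positives")
  k <- length(positives)
  per <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rs <- derive_seed(cfg$seed, 500000L + r)
    negatives <- sample_negatives(negative_pool, k, rs)
    ids <- c(positives, negatives)
    y <- c(rep(1L, k), rep(0L, k))
    x <- fm$values[ids, , drop = FALSE]
    prob <- numeric(length(ids))
    for (i in seq_along(ids)) {
      fit <- rf_fit(x[-i, , drop = FALSE], y[-i], ntree = cfg$n_trees,
                    mtry = resolve_mtry(cfg, ncol(x)),
                    seed = derive_seed(rs, i), xtest = x[i, , drop = FALSE],
                    keep_forest = FALSE)
      prob[i] <- fit$test_prob
    }
    pred <- as.integer(prob >= 0.5)
    sens <- mean(pred[y == 1] == 1)
    spec <- mean(pred[y == 0] == 0)
    acc <- mean(pred == y)
    names(prob) <- ids
    auc <- roc_auc(prob, ids[y == 1], ids[y == 0])$auc
    per[[r]] <- data.frame(repeat_id = r, sensitivity = sens,
                           specificity = spec, accuracy = acc, auc = auc)
  }
  per <- do.call(rbind, per)
  list(sensitivity = mean(per$sensitivity), specificity = mean(per$specificity),
       accuracy = mean(per$accuracy), auc = mean(per$auc), per_repeat = per)
}

#' Spearman rank correlation between two score vectors
#'
#' Computed over the intersection of the names of the two vectors.
#'
#' @param scores_a,scores_b named numeric vectors sharing at least 3 keys.
#' @return list with `rho`, `p_value` and `n` (shared keys).
#' @export
rank_correlation <- function(scores_a, scores_b) {
  shared <- intersect(names(scores_a), names(scores_b))
  if (length(shared) < 3) stop("need at least 3 shared keys")
  ct <- suppressWarnings(cor.test(scores_a[shared], scores_b[shared],
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(shared))
}

#' Holdout evaluation report
#'
#' Scores the clinical holdout (positive class) against the full negative
#' pool (negative class) and reports AUC, the ROC points, and the
#' threshold-0.5 sensitivity / specificity / accuracy.
#'
#' @param scores named per-protein score vector.
#' @param sets a [build_study_sets()] result.
#' @param threshold classification threshold (default 0.5).
#' @return list of class `evaluation_report`.
#' @export
evaluate_holdout <- function(scores, sets, threshold = 0.5) {
  pos <- sets$clinical_holdout
  neg <- sets$negative_pool
  if (length(pos) == 0) stop("empty clinical holdout")
  roc <- roc_auc(scores, pos, neg)
  pred_p <- scores[pos] >= threshold
  pred_n <- scores[neg] >= threshold
  structure(list(
    auc = roc$auc, roc_points = roc$roc_points,
    sensitivity = mean(pred_p), specificity = mean(!pred_n),
    accuracy = (sum(pred_p) + sum(!pred_n)) / (length(pos) + length(neg)),
    n_positive = length(pos), n_negative = length(neg),
    threshold = threshold), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: AUC %.3f (holdout %d vs pool %d); sens %.3f spec %.3f acc %.3f @ %.2f\n",
              x$auc, x$n_positive, x$n_negative, x$sensitivity, x$specificity,
              x$accuracy, x$threshold))
  invisible(x)
}
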