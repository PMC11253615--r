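# Random-forest classification with leave-one-out cross validation, plus
# ROC / precision-recall evaluation computed from first principles.
#
# The forest is a compact in-package implementation (bagged CART, Gini
# splits, random feature subsets; probability = fraction of trees voting
# positive) because the pipeline's only requirement is a standard bagged
# ensemble with reproducible seeding.

rf_params <- function(p, n_trees = 500L, mtry = NULL, min_node = 1L) {
  list(n_trees = as.integer(n_trees),
       mtry = as.integer(if (is.null(mtry)) max(1, floor(sqrt(p))) else mtry),
       min_node = as.integer(min_node))
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  f <- factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly 2 classes")
  as.integer(f) - 1L   # second level is the positive class
}

#' Leave-one-out cross-validated random-forest scores
#'
#' For each sample, a forest trained on all other samples yields its
#' positive-class probability. Per-fold seeds are derived from `seed`, so
#' the whole procedure is deterministic.
#'
#' @param m [abundance_matrix()] restricted to the signature genomes
#'   (relative mode recommended).
#' @param labels binary labels (factor with 2 levels, logical, or 0/1);
#'   the second factor level / TRUE / 1 is the positive class.
#' @param n_trees,mtry,min_node forest parameters (defaults 500 trees,
#'   floor(sqrt(p)) features per split, grow to purity).
#' @param seed integer seed.
#' @return numeric vector of out-of-fold scores in [0, 1], named by sample.
#' @export
rf_loocv_scores <- function(m, labels, n_trees = 500L, mtry = NULL,
                            min_node = 1L, seed = 1L) {
  x <- unclass_mat(m)
  n <- nrow(x)
  if (n < 10) stop("need >= 10 samples for LOOCV")
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  prm <- rf_params(ncol(x), n_trees, mtry, min_node)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(as.integer(seed) + i)
    scores[i] <- rf_train_predict(x[-i, , drop = FALSE], y[-i],
                                  x[i, , drop = FALSE],
                                  prm$n_trees, prm$mtry, prm$min_node)
  }
  names(scores) <- rownames(x)
  scores
}

#' ROC curve and AUROC
#'
#' Threshold sweep over the unique scores (descending); tied scores step
#' simultaneously. AUROC by the trapezoid rule.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels as in [rf_loocv_scores()].
#' @return list of class `eval_curves` (ROC part): `roc` data.frame
#'   (threshold, fpr, tpr), `auroc`, plus the inputs.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  stopifnot(length(scores) == length(y))
  np <- sum(y == 1); nn <- sum(y == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / nn, numeric(1))
  fpr_c <- c(0, fpr, 1); tpr_c <- c(0, tpr, 1)
  auroc <- sum(diff(fpr_c) * (head(tpr_c, -1) + tpr_c[-1]) / 2)
  structure(list(scores = scores, labels = y,
                 roc = data.frame(threshold = c(Inf, thr, -Inf),
                                  fpr = fpr_c, tpr = tpr_c),
                 auroc = auroc),
            class = "eval_curves")
}

#' Precision-recall curve and AUPRC
#'
#' Precision/recall at each unique score threshold; AUPRC by the step-wise
#' average-precision estimator (no trapezoidal interpolation, which is
#' biased for PR curves). The baseline equals the positive fraction - the
#' precision of a random classifier.
#'
#' @inheritParams roc_auc
#' @return list of class `eval_curves` (PR part): `pr` data.frame
#'   (threshold, recall, precision), `auprc`, `pr_baseline`.
#' @export
pr_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  np <- sum(y == 1)
  if (np == 0) stop("need at least one positive sample")
  stopifnot(length(scores) == length(y))
  thr <- sort(unique(scores), decreasing = TRUE)
  rec <- prec <- numeric(length(thr))
  for (k in seq_along(thr)) {
    sel <- scores >= thr[k]
    rec[k] <- sum(sel & y == 1) / np
    prec[k] <- sum(sel & y == 1) / sum(sel)
  }
  # average precision: sum over thresholds of (delta recall) * precision
  auprc <- sum(diff(c(0, rec)) * prec)
  structure(list(scores = scores, labels = y,
                 pr = data.frame(threshold = thr, recall = rec,
                                 precision = prec),
                 auprc = auprc,
                 pr_baseline = np / length(y)),
            class = "eval_curves")
}

#' Full ROC + PR evaluation of scores
#' @inheritParams roc_auc
#' @return `eval_curves` with both ROC and PR components.
#' @export
evaluate_scores <- function(scores, labels) {
  r <- roc_auc(scores, labels)
  p <- pr_auc(scores, labels)
  structure(c(r[c("scores", "labels", "roc", "auroc")],
              p[c("pr", "auprc", "pr_baseline")]),
            class = "eval_curves")
}

#' @export
print.eval_curves <- function(x, ...) {
  cat("<eval_curves>",
      if (!is.null(x$auroc)) sprintf(" AUROC = %.3f", x$auroc),
      if (!is.null(x$auprc)) sprintf(" AUPRC = %.3f (baseline %.3f)",
                                     x$auprc, x$pr_baseline),
      "\n", sep = "")
  invisible(x)
}

#' Train on one cohort, evaluate on another
#'
#' A single forest is trained on the full training matrix and scored on the
#' external matrix. Signature genomes missing from the external cohort are
#' zero-filled with a warning; the external matrix is reordered to the
#' training columns.
#'
#' @param train_m,train_labels training abundance matrix and binary labels.
#' @param test_m,test_labels external cohort.
#' @param n_trees,mtry,min_node,seed forest parameters.
#' @return `eval_curves` for the external cohort (scores attached).
#' @export
transfer_classifier <- function(train_m, train_labels, test_m, test_labels,
                                n_trees = 500L, mtry = NULL, min_node = 1L,
                                seed = 1L) {
  xtr <- unclass_mat(train_m)
  ytr <- as_binary_labels(train_labels)
  if (length(unique(as_binary_labels(test_labels))) < 2)
    stop("external labels must contain both classes")
  xte <- unclass_mat(test_m)
  shared <- intersect(colnames(xtr), colnames(xte))
  if (!length(shared)) stop("no overlapping genomes between cohorts")
  missing <- setdiff(colnames(xtr), colnames(xte))
  if (length(missing)) {
    warning("zero-filling ", length(missing),
            " signature genome(s) absent from the external cohort")
    fill <- matrix(0, nrow(xte), length(missing),
                   dimnames = list(rownames(xte), missing))
    xte <- cbind(xte, fill)
  }
  xte <- xte[, colnames(xtr), drop = FALSE]
  prm <- rf_params(ncol(xtr), n_trees, mtry, min_node)
  set.seed(as.integer(seed))
  scores <- rf_train_predict(xtr, ytr, xte, prm$n_trees, prm$mtry,
                             prm$min_node)
  names(scores) <- rownames(xte)
  evaluate_scores(scores, test_labels)
}
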