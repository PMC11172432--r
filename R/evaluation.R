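# Evaluation protocols: confusion-matrix metrics, ranking AUCs, stratified
# k-fold cross-validation, the positive-only threshold-accuracy AUC,
# F1-based threshold selection and network edge reconstruction.

#' Confusion counts for binary predictions
#'
#' @param labels,predictions Equal-length vectors with values in \{0, 1\}.
#' @return Named integer vector with elements `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
    stop("labels and predictions must be 0/1")
  c(TP = sum(labels == 1 & predictions == 1),
    TN = sum(labels == 0 & predictions == 0),
    FP = sum(labels == 0 & predictions == 1),
    FN = sum(labels == 1 & predictions == 0))
}

#' Threshold metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(P+N)`, sensitivity `TP/P`, specificity `TN/N`,
#' precision `TP/(TP+FP)`, negative predictive value `TN/(TN+FN)`, F1
#' `2TP/(2TP+FP+FN)` and the Matthews correlation coefficient. A metric
#' whose denominator is zero is reported as 0 with a warning, which keeps
#' fold aggregation total.
#'
#' @param counts A [confusion()] result (or any named vector with `TP`,
#'   `TN`, `FP`, `FN`).
#' @return Named numeric vector `acc`, `sen`, `spe`, `pre`, `npv`, `f1`,
#'   `mcc`.
#' @export
metrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  p <- tp + fn; n <- tn + fp
  safe <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  mcc_den <- sqrt(p) * sqrt(n) * sqrt(tp + fp) * sqrt(tn + fn)
  c(acc = safe(tp + tn, p + n, "accuracy"),
    sen = safe(tp, p, "sensitivity"),
    spe = safe(tn, n, "specificity"),
    pre = safe(tp, tp + fp, "precision"),
    npv = safe(tn, tn + fn, "NPV"),
    f1 = safe(2 * tp, 2 * tp + fp + fn, "F1"),
    mcc = safe(tp * tn - fp * fn, mcc_den, "MCC"))
}

#' Ranking areas under curves
#'
#' AUROC by the midrank (Mann-Whitney) construction and AUPRC by step
#' integration of the precision-recall curve with tied scores grouped.
#'
#' @param labels 0/1 vector with both classes present.
#' @param probabilities Numeric scores, higher = more likely positive.
#' @return Named numeric vector `auroc`, `auprc`.
#' @export
ranking_aucs <- function(labels, probabilities) {
  if (length(labels) != length(probabilities))
    stop("labels and probabilities must have equal length")
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  if (pos == 0 || neg == 0)
    stop("both classes must be present to compute ranking AUCs")
  r <- rank(probabilities)  # midranks for ties
  auroc <- (sum(r[labels == 1]) - pos * (pos + 1) / 2) / (pos * neg)
  # precision-recall: walk thresholds from high to low, grouping ties
  ord <- order(probabilities, decreasing = TRUE)
  lab <- labels[ord]
  sc <- probabilities[ord]
  grp_end <- which(diff(sc) != 0)
  cuts <- c(grp_end, length(sc))
  ctp <- cumsum(lab)[cuts]
  cn <- cuts
  prec <- ctp / cn
  rec <- ctp / pos
  auprc <- sum(diff(c(0, rec)) * prec)
  c(auroc = auroc, auprc = auprc)
}

#' Stratified fold assignment
#'
#' @param labels 0/1 vector.
#' @param k Number of folds.
#' @param seed Integer seed; the assignment is reproducible from it.
#' @return Integer vector of fold ids in 1..k, class-balanced.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (any(table(labels) < k))
    stop("each class must have at least k members")
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Generic stratified k-fold cross-validation
#'
#' Splits the data by [stratified_folds()], calls `fit_predict` once per
#' fold and aggregates the per-fold metric reports.
#'
#' @param labels 0/1 vector for the whole dataset.
#' @param fit_predict `function(train_idx, test_idx)` returning the
#'   predicted interaction probabilities for `test_idx` (trained without
#'   seeing the test fold).
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param threshold Decision threshold for the threshold metrics.
#' @return A list of class `cv_result` with `folds` (fold assignment),
#'   `per_fold` (k x metric matrix), `mean` and `sd` per metric.
#' @export
cross_validate <- function(labels, fit_predict, k = 5L, seed = 1L,
                           threshold = 0.5) {
  folds <- stratified_folds(labels, k, seed)
  per_fold <- NULL
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    prob <- fit_predict(train_idx, test_idx)
    y <- labels[test_idx]
    m <- c(metrics(confusion(y, as.integer(prob >= threshold))),
           ranking_aucs(y, prob))
    per_fold <- rbind(per_fold, m)
  }
  rownames(per_fold) <- paste0("fold", seq_len(k))
  structure(list(folds = folds, per_fold = per_fold,
                 mean = colMeans(per_fold),
                 sd = apply(per_fold, 2L, stats::sd)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (mean +/- SD):\n", nrow(x$per_fold)))
  for (m in colnames(x$per_fold))
    cat(sprintf("  %-6s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Threshold-accuracy area under the curve for positive-only test sets
#'
#' For a test set containing only true interactions, accuracy at threshold
#' t is the fraction of predicted probabilities >= t. The curve of accuracy
#' against t over [0, 1] is integrated by the trapezoidal rule on a uniform
#' grid; a confident model keeps accuracy high up to large thresholds and
#' scores near 1.
#'
#' @param probabilities Predicted probabilities of the positive-only set.
#' @param grid Number of uniform grid points over [0, 1] (default 1001).
#' @return Scalar in [0, 1].
#' @export
threshold_accuracy_auc <- function(probabilities, grid = 1001L) {
  if (length(probabilities) == 0L) stop("empty probability set")
  ts <- seq(0, 1, length.out = grid)
  acc <- vapply(ts, function(t) mean(probabilities >= t), 0)
  sum((acc[-1] + acc[-grid]) / 2) * (ts[2] - ts[1])
}

#' Select a decision threshold by F1 on a holdout set
#'
#' Grid search over `[range[1], range[2]]` maximizing F1 on the holdout
#' labels; ties are broken toward the smallest threshold.
#'
#' @param labels Holdout 0/1 labels (both classes required).
#' @param probabilities Holdout predicted probabilities.
#' @param range Threshold range (default `c(0.5, 1)`).
#' @param step Grid step (default 0.001).
#' @return The selected threshold.
#' @export
select_threshold <- function(labels, probabilities, range = c(0.5, 1),
                             step = 0.001) {
  if (length(unique(labels)) < 2L)
    stop("holdout must contain both classes")
  if (range[2] < range[1]) stop("empty threshold range")
  ts <- seq(range[1], range[2], by = step)
  # high grid points can predict no positives at all; their F1 is 0 by the
  # zero-denominator convention and the per-point warning is not useful here
  f1s <- vapply(ts, function(t) {
    suppressWarnings(
      metrics(confusion(labels, as.integer(probabilities >= t)))[["f1"]])
  }, 0)
  ts[which.max(f1s)]  # which.max takes the first, i.e. smallest, maximizer
}

#' Reconstruct a known interaction network
#'
#' Predicts every edge of an interaction network and counts how many are
#' recovered at the given probability threshold.
#'
#' @param model A trained `dfppi_model`, or a `function(pairs, records)`
#'   returning per-edge probabilities (useful for oracle baselines).
#' @param edges data.frame with columns `id_a`, `id_b`, one row per known
#'   edge.
#' @param records Protein records covering every node; a missing node
#'   sequence is an error naming the node.
#' @param threshold Probability threshold in [0, 1].
#' @param ... Passed to [encode_pairs()] when `model` is a `dfppi_model`.
#' @return List of class `network_reconstruction` with `predicted`, `total`
#'   and the per-edge `probabilities`.
#' @export
reconstruct_network <- function(model, edges, records, threshold = 0.5, ...) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  nodes <- unique(c(edges$id_a, edges$id_b))
  missing <- setdiff(nodes, records$id)
  if (length(missing) > 0L)
    stop("no sequence for network node: ", missing[1])
  prob <- if (is.function(model)) {
    model(edges, records)
  } else {
    predict_prob(model, encode_pairs(edges, records, ...))
  }
  structure(list(predicted = sum(prob >= threshold),
                 total = nrow(edges), probabilities = prob),
            class = "network_reconstruction")
}

#' @export
print.network_reconstruction <- function(x, ...) {
  cat(sprintf("recovered edges: %d/%d\n", x$predicted, x$total))
  invisible(x)
}
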