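#' Confusion counts at a probability threshold
#'
#' @param labels Binary vector (0/1 or logical) of true classes.
#' @param scores Numeric vector of predicted activity probabilities in
#'   `[0, 1]`, same length as `labels`.
#' @param threshold Compounds with `score >= threshold` are predicted
#'   active (default 0.5, the majority-vote operating point).
#' @return A `confusion_counts` object (named list `TP`, `FP`, `TN`, `FN`).
#' @export
confusion_at_threshold <- function(labels, scores, threshold = 0.5) {
  labels <- check_binary_labels(labels)
  if (length(labels) != length(scores)) {
    stop("labels and scores differ in length", call. = FALSE)
  }
  pred <- scores >= threshold
  confusion_counts(TP = sum(pred & labels == 1),
                   FP = sum(pred & labels == 0),
                   TN = sum(!pred & labels == 0),
                   FN = sum(!pred & labels == 1))
}

#' @rdname confusion_at_threshold
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  stopifnot(all(counts >= 0))
  structure(as.list(counts), class = "confusion_counts")
}

check_binary_labels <- function(labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  labels
}

#' False positive and true positive rates
#'
#' `FPR = FP / (FP + TN)`, `TPR = TP / (TP + FN)`.
#'
#' @param counts A `confusion_counts` object.
#' @return Named numeric vector `c(FPR =, TPR =)`.
#' @export
rates <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  neg <- counts$FP + counts$TN
  pos <- counts$TP + counts$FN
  if (neg == 0 || pos == 0) {
    stop("rates undefined: one of the classes is empty", call. = FALSE)
  }
  c(FPR = counts$FP / neg, TPR = counts$TP / pos)
}

#' Precision, recall and F1 score
#'
#' `Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)`,
#' `F1 = 2TP/(2TP+FP+FN)` (the harmonic mean of the first two). Degenerate
#' folds with an empty predicted-positive or actual-positive margin return
#' 0 for the affected scores, with a warning, rather than NaN.
#'
#' @param counts A `confusion_counts` object.
#' @return Named numeric vector `c(precision =, recall =, f1 =)`.
#' @export
precision_recall_f1 <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP
  denom_p <- tp + counts$FP
  denom_r <- tp + counts$FN
  if (denom_p == 0 || denom_r == 0) {
    warning("degenerate confusion counts: precision/recall denominator is zero, returning 0")
  }
  precision <- if (denom_p == 0) 0 else tp / denom_p
  recall <- if (denom_r == 0) 0 else tp / denom_r
  f1_denom <- 2 * tp + counts$FP + counts$FN
  f1 <- if (f1_denom == 0) 0 else 2 * tp / f1_denom
  c(precision = precision, recall = recall, f1 = f1)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, ranging
#' from -1 (perfect inverse prediction) through 0 (no better than chance)
#' to 1 (perfect prediction). When any marginal is empty the denominator
#' vanishes and the score is defined as 0 (standard convention for
#' degenerate folds on heavily imbalanced screens).
#'
#' @param counts A `confusion_counts` object.
#' @return A number in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) {
    bfp_log("MCC denominator zero (empty marginal); returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / denom
}

#' Cohen's kappa
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (TP+TN)/N` and chance agreement computed from the row and column
#' marginals, `p_e = [(TP+FN)(TP+FP) + (FN+TN)(FP+TN)] / N^2`. Zero means
#' agreement no better than chance.
#'
#' @param counts A `confusion_counts` object.
#' @return A list with `kappa`, `p_o` and `p_e`. `kappa` is `NaN` (with a
#'   warning) in the degenerate case `p_e = 1`.
#' @export
cohens_kappa <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion counts", call. = FALSE)
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (fn + tn) * (fp + tn)) / n^2
  if (p_e == 1) {
    warning("Cohen's kappa undefined: chance agreement p_e = 1")
    return(list(kappa = NaN, p_o = p_o, p_e = p_e))
  }
  list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e)
}

#' Enrichment factor of a ranked selection
#'
#' `EF_x = Hitrate^x / Hitrate^100`, where `Hitrate^x` is the fraction of
#' actives within the top-scoring `x` fraction of the ranked list (selection
#' size `floor(x * N)`, minimum 1) and `Hitrate^100` is the overall active
#' rate. A value of 1.0 is what random selection achieves in expectation.
#'
#' @param labels Binary vector of true activity, aligned with the ranking.
#' @param ranking Integer rank vector (1 = best) as produced by
#'   [rank_predictions()].
#' @param fraction Top fraction to select (default 0.01).
#' @return An `enrichment_result`: list with `hitrate_top`,
#'   `hitrate_overall`, `ef`, `fraction` and `n_selected`.
#' @export
enrichment_factor <- function(labels, ranking, fraction = 0.01) {
  labels <- check_binary_labels(labels)
  stopifnot(length(labels) == length(ranking),
            fraction > 0, fraction <= 1)
  if (sum(labels) == 0) {
    stop("enrichment factor undefined: no actives in the screen", call. = FALSE)
  }
  n <- length(labels)
  n_sel <- max(1L, floor(fraction * n))
  sel <- ranking <= n_sel
  hitrate_top <- sum(labels[sel]) / n_sel
  hitrate_overall <- sum(labels) / n
  structure(
    list(hitrate_top = hitrate_top, hitrate_overall = hitrate_overall,
         ef = hitrate_top / hitrate_overall, fraction = fraction,
         n_selected = n_sel),
    class = "enrichment_result"
  )
}

#' ROC curve and area under it
#'
#' Sweeps the classification threshold over the distinct score values
#' (tied scores form a single threshold step), accumulating
#' `FPR = FP/(FP+TN)` against `TPR = TP/(TP+FN)`, and integrates the area
#' with the trapezoidal rule. Both classes must be present.
#'
#' @param labels Binary vector of true classes.
#' @param scores Numeric prediction scores (higher = more active).
#' @return A `roc_curve`: list with vectors `fpr`, `tpr` (including the
#'   (0,0) and (1,1) endpoints) and scalar `auc`.
#' @export
roc_curve_and_auc <- function(labels, scores) {
  labels <- check_binary_labels(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC undefined: both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  # cumulative counts at each distinct-score step
  step_end <- which(!duplicated(sc, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(lab)[step_end]
  fp <- cumsum(1 - lab)[step_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_curve")
}

#' Per-fold metric table for a cross-validated model
#'
#' Computes the full evaluation suite fold by fold: ROC-AUC, confusion-based
#' scores at the decision threshold, and enrichment factors at several top
#' fractions, each on that fold's held-out compounds only.
#'
#' @param cv A `cv_result` from [run_cv()].
#' @param threshold Decision threshold for confusion-based scores
#'   (default 0.5).
#' @param ef_fractions Numeric vector of EF top-fractions
#'   (default `c(0.01, 0.015, 0.02, 0.025)`).
#' @return A data.frame, one row per fold, with columns `fold`, `auc`,
#'   `mcc`, `kappa`, `f1`, `precision`, `recall` and one `ef_<pct>` column
#'   per fraction.
#' @export
fold_metric_table <- function(cv, threshold = 0.5,
                              ef_fractions = c(0.01, 0.015, 0.02, 0.025)) {
  stopifnot(inherits(cv, "cv_result"))
  preds <- cv$predictions
  rows <- lapply(sort(unique(preds$fold)), function(f) {
    p <- preds[preds$fold == f, , drop = FALSE]
    cm <- confusion_at_threshold(p$label, p$probability, threshold)
    prf <- suppressWarnings(precision_recall_f1(cm))
    kap <- cohens_kappa(cm)
    roc <- roc_curve_and_auc(p$label, p$probability)
    rank <- rank_predictions(p$probability, p$compound_id)
    efs <- vapply(ef_fractions,
                  function(x) enrichment_factor(p$label, rank, x)$ef,
                  numeric(1))
    names(efs) <- paste0("ef_", sub("0+$", "", formatC(100 * ef_fractions, format = "f", digits = 2)))
    names(efs) <- sub("\\.$", "", names(efs))
    data.frame(fold = f, auc = roc$auc, mcc = mcc(cm), kappa = kap$kappa,
               f1 = prf[["f1"]], precision = prf[["precision"]],
               recall = prf[["recall"]], t(efs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean and standard deviation across folds
#'
#' @param fold_table Output of [fold_metric_table()].
#' @return A data.frame with one row per metric and columns `metric`,
#'   `mean`, `sd`.
#' @export
metric_summary <- function(fold_table) {
  stopifnot(is.data.frame(fold_table), "fold" %in% names(fold_table))
  metrics <- setdiff(names(fold_table), "fold")
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(fold_table[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) sd(fold_table[[m]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
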