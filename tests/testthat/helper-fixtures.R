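options(bashfp.quiet = TRUE)

# small synthetic world, built once per test run and shared across files
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_world(generator_config(
        n_compounds = 600, n_assays = 15, n_chemotypes = 6,
        test_prevalence = 0.04, seed = 42
      ))
    }
    cache
  }
})

# write a toy activity table file and return its path
write_toy_activity <- function(rows, sep = ",") {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    paste(c("assay_id", "compound_id", "outcome"), collapse = sep),
    vapply(rows, paste, "", collapse = sep)
  ), path)
  path
}

# brute-force metric oracles, independent of the package implementations
oracle_confusion <- function(labels, scores, threshold) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(labels)) {
    pred <- scores[i] >= threshold
    if (pred && labels[i] == 1) tp <- tp + 1
    else if (pred && labels[i] == 0) fp <- fp + 1
    else if (!pred && labels[i] == 0) tn <- tn + 1
    else fn <- fn + 1
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# AUC as the normalized Mann-Whitney pair count (ties count 1/2)
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

oracle_mcc <- function(cm) {
  num <- cm["TP"] * cm["TN"] - cm["FP"] * cm["FN"]
  den <- sqrt(prod(c(cm["TP"] + cm["FP"], cm["TP"] + cm["FN"],
                     cm["TN"] + cm["FP"], cm["TN"] + cm["FN"])))
  if (den == 0) 0 else unname(num / den)
}

oracle_kappa <- function(cm) {
  n <- sum(cm)
  p_o <- (cm["TP"] + cm["TN"]) / n
  p_e <- ((cm["TP"] + cm["FN"]) * (cm["TP"] + cm["FP"]) +
          (cm["FN"] + cm["TN"]) * (cm["FP"] + cm["TN"])) / n^2
  unname((p_o - p_e) / (1 - p_e))
}

oracle_ef <- function(labels, scores, ids, fraction) {
  n <- length(labels)
  n_sel <- max(1, floor(fraction * n))
  ord <- order(-scores, ids)
  sel <- ord[seq_len(n_sel)]
  (sum(labels[sel]) / n_sel) / (sum(labels) / n)
}
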