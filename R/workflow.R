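#' End-to-end benchmark over one or more held-out test assays
#'
#' Orchestrates the full retrospective pipeline: resolve activity records
#' into a panel, build the HTSFP / structural / hybrid descriptors for each
#' test assay's compound universe (with the test assay excluded from the
#' bioactivity block), run stratified cross-validated random forests for
#' the three descriptor types, and assemble the evaluation suite: per-fold
#' metric tables, scaffold-overlap report on the true positives of the
#' top-scoring fraction, nearest-neighbor Tanimoto distributions of the
#' top-ranked compounds, and the cross-model ranking comparison.
#'
#' @param records Activity records data.frame (`assay_id`, `compound_id`,
#'   `outcome`) or a `resolved_panel`.
#' @param compounds A `compound_table` covering the panel's compounds.
#' @param test_assay_ids Character vector of assay ids to hold out and
#'   predict.
#' @param configs Named list of `rf_config`s for the three descriptor
#'   types (`htsfp`, `ecfp4`, `bash`); defaults to the shipped presets.
#' @param k Number of cross-validation folds (default 6).
#' @param radius,n_bits Structural fingerprint parameters.
#' @param min_assay_size Assays below this tested-compound count are
#'   dropped from the panel (default 1; set to 20000 for full-scale
#'   PubChem-like panels). Test assays below it are skipped with a warning.
#' @param top_fraction_scaffold Top fraction whose true positives feed the
#'   scaffold analysis (default 0.01).
#' @param top_n_rank Selection size for the ranking comparison and
#'   nearest-neighbor analysis (default 1000, capped at the universe).
#' @param out_dir Optional directory; when given, metric tables, reports
#'   and a run manifest are written there as delimited text / JSON.
#' @return A `benchmark_suite`: list of per-assay reports (each with
#'   `cv` per model, `fold_metrics`, `summaries`, `scaffolds`,
#'   `nn_similarity`, `rank_comparison`) plus `manifest`.
#' @export
run_benchmark_suite <- function(records, compounds, test_assay_ids,
                                configs = list(htsfp = rf_config("htsfp"),
                                               ecfp4 = rf_config("ecfp4"),
                                               bash = rf_config("bash")),
                                k = 6, radius = 2, n_bits = 1024,
                                min_assay_size = 1,
                                top_fraction_scaffold = 0.01,
                                top_n_rank = 1000,
                                out_dir = NULL) {
  t_start <- Sys.time()
  panel <- if (inherits(records, "resolved_panel")) records
           else resolve_replicates(records)
  panel <- filter_assays_by_size(panel, min_assay_size)
  stopifnot(inherits(compounds, "compound_table"))
  stopifnot(all(c("htsfp", "ecfp4", "bash") %in% names(configs)))

  structural_all <- build_structural_fp(compounds, radius = radius,
                                        n_bits = n_bits)
  reports <- list()
  for (aid in test_assay_ids) {
    if (!aid %in% panel$assay_ids) {
      warning("test assay ", aid, " not present in the panel; skipped")
      next
    }
    rep_a <- benchmark_one_assay(panel, compounds, structural_all, aid,
                                 configs, k, top_fraction_scaffold,
                                 top_n_rank)
    reports[[aid]] <- rep_a
  }
  if (length(reports) == 0) stop("no test assay could be benchmarked", call. = FALSE)

  manifest <- list(
    generated = format(t_start, "%Y-%m-%d %H:%M:%S"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    test_assays = names(reports),
    k = k, radius = radius, n_bits = n_bits,
    min_assay_size = min_assay_size,
    seeds = lapply(configs, function(cf) list(forest = cf$seed,
                                              folds = cf$fold_seed)),
    outputs = character(0)
  )
  suite <- structure(list(reports = reports, manifest = manifest),
                     class = "benchmark_suite")
  if (!is.null(out_dir)) suite <- write_suite(suite, out_dir)
  suite
}

benchmark_one_assay <- function(panel, compounds, structural_all, aid,
                                configs, k, top_fraction_scaffold,
                                top_n_rank) {
  pairs <- panel$pairs[panel$pairs$assay_id == aid, , drop = FALSE]
  universe <- sort(pairs$compound_id)
  labels <- stats::setNames(as.integer(pairs$active[match(universe, pairs$compound_id)]),
                            universe)

  htsfp_full <- build_htsfp(panel, universe)
  htsfp <- exclude_assay(htsfp_full, aid)
  structural <- unclass(structural_all)[universe, , drop = FALSE]
  structural <- structure(structural,
                          params = attr(structural_all, "params"),
                          class = c("structural_fp", "matrix", "array"))
  bash <- build_bash(htsfp, structural)

  feats <- list(htsfp = as_fingerprint_set(htsfp),
                ecfp4 = as_fingerprint_set(structural),
                bash = bash)
  cvs <- lapply(names(feats), function(m) {
    run_cv(feats[[m]], labels, configs[[m]], k = k)
  })
  names(cvs) <- names(feats)

  fold_metrics <- lapply(cvs, fold_metric_table)
  summaries <- lapply(fold_metrics, metric_summary)

  # per-fold true positives of the top-scoring fraction -> scaffold overlap
  selections <- lapply(cvs, function(cv) {
    lapply(seq_len(k), function(f) {
      p <- cv$predictions[cv$predictions$fold == f, , drop = FALSE]
      rk <- rank_predictions(p$probability, p$compound_id)
      p$compound_id[top_fraction(rk, top_fraction_scaffold) & p$label == 1]
    })
  })
  scaffolds <- scaffold_sets(selections[c("bash", "htsfp", "ecfp4")], compounds)

  top_n <- min(top_n_rank, length(universe))
  nn <- lapply(cvs, function(cv) {
    sel <- cv$predictions$compound_id[cv$predictions$rank <= top_n]
    nearest_neighbor_similarities(sel, structural)
  })
  rc <- rank_comparison(cvs$bash, cvs$ecfp4, cvs$htsfp, top_n = top_n)

  list(assay_id = aid, n_compounds = length(universe),
       n_actives = sum(labels), cv = cvs, fold_metrics = fold_metrics,
       summaries = summaries, scaffolds = scaffolds, nn_similarity = nn,
       rank_comparison = rc)
}

#' Cross-assay comparison table
#'
#' @param suite A `benchmark_suite` from [run_benchmark_suite()].
#' @return A list with `table` (per assay x model: mean and SD of AUC, MCC
#'   and EF at 1%) and `wins` (pairwise win counts per model on mean AUC).
#' @export
summarize_suite <- function(suite) {
  stopifnot(inherits(suite, "benchmark_suite"))
  rows <- list()
  for (rep_a in suite$reports) {
    for (m in names(rep_a$fold_metrics)) {
      ft <- rep_a$fold_metrics[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        assay_id = rep_a$assay_id, model = m,
        auc_mean = mean(ft$auc), auc_sd = sd(ft$auc),
        mcc_mean = mean(ft$mcc), mcc_sd = sd(ft$mcc),
        ef1_mean = mean(ft$ef_1), ef1_sd = sd(ft$ef_1),
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  models <- unique(tab$model)
  wins <- matrix(0L, length(models), length(models),
                 dimnames = list(models, models))
  for (aid in unique(tab$assay_id)) {
    sub <- tab[tab$assay_id == aid, , drop = FALSE]
    for (m1 in models) for (m2 in models) {
      if (m1 != m2 &&
          sub$auc_mean[sub$model == m1] > sub$auc_mean[sub$model == m2]) {
        wins[m1, m2] <- wins[m1, m2] + 1L
      }
    }
  }
  list(table = tab, wins = wins)
}

# write per-assay tables + manifest; returns the suite with manifest updated
write_suite <- function(suite, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  for (rep_a in suite$reports) {
    aid <- rep_a$assay_id
    for (m in names(rep_a$cv)) {
      p <- file.path(out_dir, sprintf("%s_%s_predictions.tsv", aid, m))
      write.table(rep_a$cv[[m]]$predictions, p, sep = "\t",
                  row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, p)
      p <- file.path(out_dir, sprintf("%s_%s_metrics.tsv", aid, m))
      write.table(rep_a$fold_metrics[[m]], p, sep = "\t",
                  row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, p)
    }
    p <- file.path(out_dir, sprintf("%s_scaffold_regions.tsv", aid))
    reg <- as.data.frame(rep_a$scaffolds$regions)
    reg$fold <- seq_len(nrow(reg))
    write.table(reg, p, sep = "\t", row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, p)
    p <- file.path(out_dir, sprintf("%s_rank_comparison.tsv", aid))
    write.table(rep_a$rank_comparison$table, p, sep = "\t",
                row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, p)
  }
  suite$manifest$outputs <- outputs
  jsonlite::write_json(suite$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  suite
}

#' @export
print.benchmark_suite <- function(x, ...) {
  cat(sprintf("benchmark_suite: %d test assay(s): %s\n",
              length(x$reports), paste(names(x$reports), collapse = ", ")))
  for (rep_a in x$reports) {
    aucs <- vapply(rep_a$fold_metrics, function(ft) mean(ft$auc), numeric(1))
    cat(sprintf("  %s (n=%d, actives=%d): %s\n", rep_a$assay_id,
                rep_a$n_compounds, rep_a$n_actives,
                paste(sprintf("AUC(%s)=%.3f", names(aucs), aucs),
                      collapse = ", ")))
  }
  invisible(x)
}
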