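test_that("stratified folds reproduce global class ratios up to rounding", {
  labels <- c(rep(1, 12), rep(0, 588))
  folds <- make_stratified_folds(labels, k = 6, seed = 1)
  per_fold_actives <- tapply(labels, folds, sum)
  per_fold_sizes <- tabulate(folds, 6)
  expect_equal(as.vector(per_fold_actives), rep(2, 6))
  expect_equal(unname(per_fold_sizes), rep(100, 6))

  # 13 actives over 6 folds: exactly one fold with 3
  labels13 <- c(rep(1, 13), rep(0, 60))
  folds13 <- make_stratified_folds(labels13, k = 6, seed = 1)
  counts <- unname(tapply(labels13, folds13, sum))
  expect_setequal(unique(counts), c(2, 3))
  expect_equal(sum(counts == 3), 1)
})

test_that("fold assignment is deterministic in (labels, k, seed) and seed-sensitive", {
  labels <- rbinom(300, 1, 0.1)
  if (sum(labels) < 6) labels[1:6] <- 1
  f1 <- make_stratified_folds(labels, k = 6, seed = 56)
  f2 <- make_stratified_folds(labels, k = 6, seed = 56)
  f3 <- make_stratified_folds(labels, k = 6, seed = 57)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_error(make_stratified_folds(c(1, 1, rep(0, 50)), k = 6), "fewer actives")
})

test_that("fold generation leaves the caller's RNG stream untouched", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_stratified_folds(rep(c(1, 0), 20), k = 2, seed = 9))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("rf presets carry the published hyperparameters", {
  htsfp <- rf_config("htsfp")
  expect_equal(htsfp$n_trees, 150L)
  expect_equal(htsfp$split_criterion, "entropy")
  expect_equal(htsfp$max_depth, 40)
  expect_equal(htsfp$min_samples_leaf, 5L)
  ecfp <- rf_config("ecfp4")
  expect_equal(ecfp$n_trees, 200L)
  expect_equal(ecfp$max_depth, 30)
  expect_equal(ecfp$min_samples_leaf, 8L)
  bash <- rf_config("bash")
  expect_equal(bash$n_trees, 150L)
  expect_false(is.finite(bash$max_depth))  # unlimited depth
  expect_equal(bash$seed, 56L)
  expect_equal(bash$class_weighting, "balanced")
  expect_equal(bash$max_features_rule, "sqrt")
})

make_toy_features <- function(n = 240, p = 30, seed = 5) {
  set.seed(seed)
  x <- matrix(rbinom(n * p, 1, 0.3), n, p,
              dimnames = list(sprintf("c%03d", 1:n), paste0("f", 1:p)))
  x
}

test_that("cross-validation holds out every compound exactly once with sane scores", {
  x <- make_toy_features()
  labels <- rbinom(nrow(x), 1, 0.25)
  labels[1:12] <- 1
  cv <- run_cv(x, labels, rf_config("custom", n_trees = 50), k = 6)
  expect_equal(sort(cv$predictions$compound_id), sort(rownames(x)))
  expect_equal(anyDuplicated(cv$predictions$compound_id), 0L)
  expect_true(all(cv$predictions$probability >= 0 & cv$predictions$probability <= 1))
  expect_setequal(cv$predictions$rank, seq_len(nrow(x)))
})

test_that("perfectly separable features give held-out AUC of 1", {
  x <- make_toy_features()
  labels <- rbinom(nrow(x), 1, 0.3)
  labels[1:10] <- 1
  x[, 1] <- labels  # label leaked into a column
  cv <- run_cv(x, labels, rf_config("custom", n_trees = 50), k = 6)
  ft <- fold_metric_table(cv)
  expect_gte(mean(ft$auc), 0.999)
})

test_that("label-independent features give chance-level AUC across seeds", {
  aucs <- vapply(1:8, function(s) {
    x <- make_toy_features(n = 200, p = 20, seed = 100 + s)
    set.seed(1000 + s)
    labels <- c(rep(1, 40), rep(0, 160))[sample(200)]
    cv <- run_cv(x, labels, rf_config("custom", n_trees = 60, seed = s,
                                      fold_seed = s), k = 4)
    roc_curve_and_auc(cv$predictions$label, cv$predictions$probability)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("identical configuration and seed reproduce bit-identical probabilities", {
  x <- make_toy_features()
  labels <- rbinom(nrow(x), 1, 0.2); labels[1:10] <- 1
  cfg <- rf_config("custom", n_trees = 40)
  cv1 <- run_cv(x, labels, cfg, k = 4)
  cv2 <- run_cv(x, labels, cfg, k = 4)
  expect_identical(cv1$predictions$probability, cv2$predictions$probability)
  expect_identical(cv1$importances, cv2$importances)
})

test_that("single-class training partitions are rejected", {
  x <- make_toy_features(n = 40, p = 5)
  labels <- c(rep(1, 2), rep(0, 38))
  expect_error(run_cv(x, labels, rf_config("custom", n_trees = 10), k = 2),
               NA)  # 1 active per training half is still two classes
  expect_error(make_stratified_folds(c(1, rep(0, 39)), k = 2), "fewer actives")
})

test_that("prediction ranking is deterministic with id-ordered ties", {
  expect_equal(rank_predictions(c(0.2, 0.9, 0.5)), c(3L, 1L, 2L))
  rk <- rank_predictions(c(0.5, 0.5, 0.1), ids = c("b", "a", "c"))
  expect_equal(rk, c(2L, 1L, 3L))
  set.seed(3)
  sc <- sample(round(runif(50), 1))
  expect_setequal(rank_predictions(sc), 1:50)
})

test_that("top-fraction selection follows floor with a minimum of one", {
  expect_equal(sum(top_fraction(1:24074, 0.01)), 240)
  expect_equal(sum(top_fraction(1:100, 0.001)), 1)
  expect_equal(sum(top_fraction(1:400339, 0.01)), 4003)
})

test_that("block importance totals pass normalization through and flag mismatches", {
  x <- make_toy_features(n = 120, p = 10)
  labels <- rbinom(120, 1, 0.3); labels[1:8] <- 1
  prov <- data.frame(block = rep(c("bioactivity", "structural"), c(4, 6)),
                     ref = c(paste0("A", 1:4), paste0("bit", 1:6)),
                     stringsAsFactors = FALSE)
  cv <- run_cv(fingerprint_set(x, prov), labels,
               rf_config("custom", n_trees = 30), k = 4)
  fib <- feature_importance_blocks(cv)
  # per-fold importances are normalized to 1, so block totals sum to 1
  expect_equal(sum(fib$block_totals), 1, tolerance = 1e-8)
  expect_equal(nrow(fib$per_feature), 10)
  expect_true(all(fib$per_feature$max >= fib$per_feature$mean))
  expect_lte(nrow(fib$top_bioactivity), 5)
  expect_true(all(fib$top_bioactivity$block == "bioactivity"))
  bad_prov <- prov[1:9, ]
  expect_error(feature_importance_blocks(cv, bad_prov), "length")
})

test_that("constant all-zero structural columns carry no importance", {
  x <- make_toy_features(n = 150, p = 8)
  x <- cbind(x, matrix(0L, 150, 4,
                       dimnames = list(NULL, paste0("z", 1:4))))
  labels <- rbinom(150, 1, 0.3); labels[1:8] <- 1
  prov <- data.frame(block = rep(c("bioactivity", "structural"), c(8, 4)),
                     ref = colnames(x), stringsAsFactors = FALSE)
  cv <- run_cv(fingerprint_set(x, prov), labels,
               rf_config("custom", n_trees = 30), k = 3)
  fib <- feature_importance_blocks(cv)
  expect_equal(unname(fib$block_totals["structural"]), 0)
})

test_that("feature importance tracks the signal regime of the generating world", {
  cfg_base <- function(...) generator_config(n_compounds = 2000, n_assays = 40,
                                             test_prevalence = 0.03, seed = 3, ...)
  cfgs <- list(htsfp = rf_config("htsfp", n_trees = 100),
               ecfp4 = rf_config("ecfp4", n_trees = 100),
               bash = rf_config("bash", n_trees = 100))
  run_world <- function(w) {
    panel <- resolve_replicates(w$records)
    universe <- w$compounds$entries$compound_id
    labels <- w$test$labels[universe]
    ht <- exclude_assay(build_htsfp(panel, universe), "AIDTEST")
    st <- build_structural_fp(w$compounds)
    bash <- build_bash(ht, st)
    list(
      auc = vapply(list(htsfp = as_fingerprint_set(ht),
                        ecfp4 = as_fingerprint_set(st), bash = bash),
                   function(f) {
                     cv <- run_cv(f, labels, cfgs[[1]], k = 6)
                     roc_curve_and_auc(cv$predictions$label,
                                       cv$predictions$probability)$auc
                   }, numeric(1)),
      fib = feature_importance_blocks(run_cv(bash, labels, cfgs$bash, k = 6)),
      sisters = w$panel_meta$assay_id[w$panel_meta$target == w$test$target_index]
    )
  }

  # activity generated from panel assays only (no structural channel at all):
  # bioactivity columns dominate -> pronounced assay features on top
  bio_only <- run_world(generate_world(cfg_base(structure_weight = 0),
                                       affinity = matrix(0, 8, 5)))
  expect_gt(bio_only$auc["htsfp"], bio_only$auc["ecfp4"] + 0.05)
  top_feats <- head(bio_only$fib$per_feature[
    order(-bio_only$fib$per_feature$mean), ], 3)
  expect_true(all(top_feats$block == "bioactivity"))
  expect_true(all(top_feats$ref %in% bio_only$sisters))

  # activity generated from structure only: structural block dominates
  str_only <- run_world(generate_world(cfg_base(bioactivity_weight = 0)))
  expect_gt(str_only$auc["ecfp4"], str_only$auc["htsfp"] + 0.05)
  expect_gt(str_only$fib$block_totals["structural"], 0.9)
  expect_gt(bio_only$fib$block_totals["bioactivity"],
            5 * str_only$fib$block_totals["bioactivity"])
})
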