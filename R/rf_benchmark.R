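#' Random-forest configuration presets
#'
#' Named hyperparameter presets for the three descriptor types, matching
#' the settings used for full-scale benchmarking: 150-200 trees, balanced
#' class weighting (vital on screens with <1% actives), `sqrt(p)` candidate
#' features per split, and per-preset depth/leaf-size settings. The split
#' criterion is recorded in the config; forests are grown with the Gini
#' impurity (the `entropy` annotation of the HTSFP preset is honoured as
#' Gini, which selects near-identical splits on binary features).
#'
#' @param preset One of `"bash"`, `"htsfp"`, `"ecfp4"`, or `"custom"`.
#' @param n_trees,class_weighting,max_features_rule,split_criterion,max_depth,min_samples_split,min_samples_leaf,seed,threshold
#'   Individual overrides; defaults come from the preset. `max_depth = Inf`
#'   means unlimited. `threshold` is the decision threshold used for
#'   confusion-based metrics.
#' @param fold_seed Seed for the stratified fold assignment.
#' @return An `rf_config` object (named list).
#' @export
rf_config <- function(preset = c("bash", "htsfp", "ecfp4", "custom"),
                      n_trees = NULL, class_weighting = c("balanced", "none"),
                      max_features_rule = c("sqrt", "all"),
                      split_criterion = c("gini", "entropy"),
                      max_depth = NULL, min_samples_split = NULL,
                      min_samples_leaf = NULL, seed = 56L,
                      fold_seed = 56L, threshold = 0.5) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    htsfp = list(n_trees = 150L, split_criterion = "entropy", max_depth = 40,
                 min_samples_split = 2L, min_samples_leaf = 5L),
    ecfp4 = list(n_trees = 200L, split_criterion = "gini", max_depth = 30,
                 min_samples_split = 2L, min_samples_leaf = 8L),
    bash = list(n_trees = 150L, split_criterion = "gini", max_depth = Inf,
                min_samples_split = 2L, min_samples_leaf = 8L),
    custom = list(n_trees = 150L, split_criterion = "gini", max_depth = Inf,
                  min_samples_split = 2L, min_samples_leaf = 1L)
  )
  cfg <- list(
    preset = preset,
    n_trees = if (is.null(n_trees)) defaults$n_trees else as.integer(n_trees),
    class_weighting = match.arg(class_weighting),
    max_features_rule = match.arg(max_features_rule),
    split_criterion = if (missing(split_criterion)) defaults$split_criterion
                      else match.arg(split_criterion),
    max_depth = if (is.null(max_depth)) defaults$max_depth else max_depth,
    min_samples_split = if (is.null(min_samples_split)) defaults$min_samples_split
                        else as.integer(min_samples_split),
    min_samples_leaf = if (is.null(min_samples_leaf)) defaults$min_samples_leaf
                       else as.integer(min_samples_leaf),
    seed = as.integer(seed),
    fold_seed = as.integer(fold_seed),
    threshold = threshold
  )
  stopifnot(cfg$n_trees >= 1, cfg$min_samples_split >= 1,
            cfg$min_samples_leaf >= 1, cfg$max_depth >= 1)
  structure(cfg, class = "rf_config")
}

#' @export
print.rf_config <- function(x, ...) {
  cat(sprintf(
    "rf_config '%s': %d trees, class_weighting=%s, max_features=%s, criterion=%s, max_depth=%s, min_leaf=%d, seed=%d\n",
    x$preset, x$n_trees, x$class_weighting, x$max_features_rule,
    x$split_criterion, ifelse(is.finite(x$max_depth), x$max_depth, "unlimited"),
    x$min_samples_leaf, x$seed))
  invisible(x)
}

#' Deterministic stratified fold assignment
#'
#' Actives and inactives are shuffled separately under the given seed and
#' dealt round-robin into `k` folds, so every fold carries the global
#' active:inactive ratio up to integer rounding (per-class fold counts
#' differ by at most one).
#'
#' @param labels Binary vector (0/1 or logical).
#' @param k Number of folds (default 6).
#' @param seed Integer seed; the assignment is a deterministic function of
#'   `(labels, k, seed)`.
#' @return Integer vector of fold ids in `1..k`, aligned with `labels`.
#' @export
make_stratified_folds <- function(labels, k = 6, seed = 56) {
  labels <- check_binary_labels(labels)
  stopifnot(k >= 2)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos < k) stop("fewer actives (", n_pos, ") than folds (", k, ")", call. = FALSE)
  if (n_neg < k) stop("fewer inactives (", n_neg, ") than folds (", k, ")", call. = FALSE)
  folds <- integer(length(labels))
  rng <- local_rng(seed)
  for (cls in c(1, 0)) {
    idx <- which(labels == cls)
    idx <- idx[rng$shuffle(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# seed-scoped RNG so package functions never disturb the caller's RNG state
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  restore <- function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
  with_state <- function(f) {
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      restore()
    })
    f()
  }
  list(
    shuffle = function(n) with_state(function() sample.int(n)),
    runif = function(n, ...) with_state(function() runif(n, ...)),
    rnorm = function(n, ...) with_state(function() rnorm(n, ...)),
    rbinom = function(n, ...) with_state(function() rbinom(n, ...)),
    rlogis = function(n, ...) with_state(function() rlogis(n, ...)),
    sample = function(x, ...) with_state(function() sample(x, ...))
  )
}

#' Cross-validated random-forest benchmark for one assay
#'
#' Trains a probability random forest on `k - 1` folds and scores the
#' held-out fold, for every fold, under the supplied hyperparameter
#' configuration. The held-out probability is the forest's consensus vote
#' for the active class, and is produced exactly once per compound.
#' Per-fold Gini feature importances (normalized to sum to one) and
#' confusion counts at the decision threshold are retained.
#'
#' @param features A `fingerprint_set`, or a numeric matrix with compound-id
#'   rownames.
#' @param labels Binary vector aligned with the feature rows.
#' @param config An `rf_config`.
#' @param k Number of cross-validation folds (default 6).
#' @return A `cv_result`: list with `predictions` (data.frame
#'   `compound_id`, `fold`, `label`, `probability`, `rank` where rank is the
#'   pooled ranking across all held-out scores), `importances` (k x p
#'   matrix), `fold_confusion` (list of `confusion_counts`), `folds`,
#'   `config` and `provenance` (if the input carried one).
#' @export
run_cv <- function(features, labels, config = rf_config("bash"), k = 6) {
  provenance <- NULL
  if (inherits(features, "fingerprint_set")) {
    provenance <- features$provenance
    features <- features$features
  }
  stopifnot(is.matrix(features), inherits(config, "rf_config"))
  labels <- check_binary_labels(labels)
  if (nrow(features) != length(labels)) {
    stop("features and labels are not aligned", call. = FALSE)
  }
  compound_ids <- rownames(features)
  if (is.null(compound_ids)) compound_ids <- as.character(seq_len(nrow(features)))

  folds <- make_stratified_folds(labels, k = k, seed = config$fold_seed)
  probs <- numeric(length(labels))
  importances <- matrix(0, nrow = k, ncol = ncol(features),
                        dimnames = list(NULL, colnames(features)))
  fold_confusion <- vector("list", k)

  mtry <- switch(config$max_features_rule,
                 sqrt = max(1L, floor(sqrt(ncol(features)))),
                 all = ncol(features))
  max_depth <- if (is.finite(config$max_depth)) as.integer(config$max_depth) else 0L

  for (f in seq_len(k)) {
    tr <- folds != f
    y_tr <- labels[tr]
    if (length(unique(y_tr)) < 2) {
      stop("training partition for fold ", f, " contains a single class",
           call. = FALSE)
    }
    w <- if (config$class_weighting == "balanced") {
      # weight w_c = n / (2 * n_c), the standard inverse-frequency balance
      nc <- c(`0` = sum(y_tr == 0), `1` = sum(y_tr == 1))
      (length(y_tr) / (2 * nc))[as.character(y_tr)]
    } else rep(1, length(y_tr))
    fit <- ranger::ranger(
      x = features[tr, , drop = FALSE],
      y = factor(y_tr, levels = c(0, 1)),
      num.trees = config$n_trees,
      mtry = mtry,
      probability = TRUE,
      importance = "impurity",
      case.weights = w,
      min.node.size = config$min_samples_split,
      min.bucket = config$min_samples_leaf,
      max.depth = max_depth,
      splitrule = "gini",
      seed = config$seed,
      num.threads = 1,
      verbose = FALSE
    )
    imp <- fit$variable.importance
    if (sum(imp) > 0) imp <- imp / sum(imp)
    importances[f, ] <- imp
    te <- which(folds == f)
    pr <- stats::predict(fit, data = features[te, , drop = FALSE],
                         num.threads = 1)$predictions
    probs[te] <- pr[, "1"]
    fold_confusion[[f]] <- confusion_at_threshold(labels[te], probs[te],
                                                  config$threshold)
  }

  predictions <- data.frame(
    compound_id = compound_ids, fold = folds, label = labels,
    probability = probs,
    rank = rank_predictions(probs, compound_ids),
    stringsAsFactors = FALSE
  )
  structure(
    list(predictions = predictions, importances = importances,
         fold_confusion = fold_confusion, folds = folds, k = k,
         config = config, provenance = provenance),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d compounds, %d folds, preset '%s'\n",
              nrow(x$predictions), x$k, x$config$preset))
  invisible(x)
}

#' Rank prediction scores (1 = highest)
#'
#' @param scores Numeric score vector.
#' @param ids Optional ids used to break ties deterministically (ascending
#'   id order); defaults to input position.
#' @return Integer rank vector: a permutation of `1..length(scores)`.
#' @export
rank_predictions <- function(scores, ids = NULL) {
  stopifnot(length(scores) >= 1)
  if (is.null(ids)) ids <- seq_along(scores)
  stopifnot(length(ids) == length(scores))
  ord <- order(-scores, ids)
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  ranks
}

#' Select the top-ranked fraction of compounds
#'
#' @param ranking Integer ranks from [rank_predictions()].
#' @param fraction Top fraction to keep (default 0.01); the selection size
#'   is `floor(fraction * N)`, minimum 1.
#' @return Logical vector marking the selected positions.
#' @export
top_fraction <- function(ranking, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  n_sel <- max(1L, floor(fraction * length(ranking)))
  ranking <= n_sel
}

#' Feature-importance summaries per provenance block
#'
#' Aggregates per-fold feature importances into per-feature mean and max
#' across folds, and sums the per-feature means within each provenance
#' block. With per-fold importances normalized to one, the block totals are
#' the fraction of total forest importance attributable to the bioactivity
#' and structural portions of the fingerprint.
#'
#' @param cv A `cv_result` from [run_cv()].
#' @param provenance Optional provenance data.frame (`block`, `ref`);
#'   defaults to the one stored in `cv`.
#' @param top Number of top bioactivity features to report (default 5).
#' @return A list with `per_feature` (data.frame `ref`, `block`, `mean`,
#'   `max`), `block_totals` (named numeric), and `top_bioactivity`
#'   (data.frame of the `top` highest-mean-importance bioactivity features
#'   with their assay ids).
#' @export
feature_importance_blocks <- function(cv, provenance = NULL, top = 5) {
  stopifnot(inherits(cv, "cv_result"))
  if (is.null(provenance)) provenance <- cv$provenance
  if (is.null(provenance)) {
    stop("no provenance available for this cv_result", call. = FALSE)
  }
  if (nrow(provenance) != ncol(cv$importances)) {
    stop("provenance length does not match feature count", call. = FALSE)
  }
  per_feature <- data.frame(
    ref = provenance$ref, block = provenance$block,
    mean = colMeans(cv$importances),
    max = apply(cv$importances, 2, max),
    row.names = NULL, stringsAsFactors = FALSE
  )
  block_totals <- tapply(per_feature$mean, per_feature$block, sum)
  block_totals <- stats::setNames(as.numeric(block_totals), names(block_totals))
  bio <- per_feature[per_feature$block == "bioactivity", , drop = FALSE]
  bio <- bio[order(-bio$mean), , drop = FALSE]
  list(per_feature = per_feature, block_totals = block_totals,
       top_bioactivity = head(bio, top))
}
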