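# Synthetic compound libraries and HTS panels with controllable
# structure-activity and panel-activity signal.  The generator emulates the
# statistics of large public HTS collections: hundreds of sparse assays,
# per-assay hit rates spanning roughly 0.05%-4%, most compound-assay cells
# untested, and a held-out test assay whose activity depends jointly on a
# structural chemotype and a latent-target bioactivity profile.

# ring-system templates; {A} is always substituted, {B} is optional.
# all template x substituent combinations are valid by construction
# (exercised in the test suite).
.chemotype_cores <- c(
  "c1cc({A})cc({B})c1",           # benzene, 1,3-disubstituted
  "c1cc({A})nc({B})c1",           # pyridine
  "c1ccc2cc({A})c({B})cc2c1",     # naphthalene
  "C1CCN(CC1){A}",                # N-substituted piperidine
  "c1cc({A})cs1",                 # thiophene
  "c1cc({A})co1",                 # furan
  "c1ncc({A})cn1",                # pyrimidine
  "c1ccc2c(c1)cc({A})[nH]2",      # indole
  "c1ccc2nc({A})ccc2c1",          # quinoline
  "c1ccc2c(c1)CCC({A})C2"         # tetralin
)

# substituent grammar: fragments valid when attached through their first atom
.substituents <- c(
  "C", "CC", "CCC", "CCCC", "C(C)C", "C(C)(C)C",
  "F", "Cl", "Br", "I",
  "O", "OC", "OCC", "N", "NC", "N(C)C",
  "C#N", "C(=O)C", "C(=O)OC", "C(=O)N",
  "CO", "CCO", "S", "SC", "C(F)(F)F"
)

#' Configuration for the synthetic HTS world generator
#'
#' Defaults emulate a desk-scale version of a public HTS panel: per-assay
#' hit rates drawn log-uniformly from 0.05%-4% (the span observed across
#' real screening panels), 30% of compound-assay cells tested, and a test
#' assay at 2% prevalence whose labels mix a structural chemotype effect
#' with a latent-target bioactivity effect in equal weights.
#'
#' @param n_compounds Library size.
#' @param n_assays Number of panel assays.
#' @param hit_rate_range Two-element range of per-assay active rates;
#'   assay rates are drawn uniformly within it.
#' @param coverage Probability that a compound is tested in an assay.
#' @param n_chemotypes Number of ring-scaffold chemotypes (max 10).
#' @param n_latent_targets Number of latent biological targets behind the
#'   panel; with the default 50 assays over 5 targets, each target is read
#'   out by about ten assays, mirroring the confirmatory/related-assay
#'   redundancy of real screening collections.
#' @param link_slope Slope of the logistic link between a compound's
#'   latent-target score and its activity probability in an assay. Large
#'   values make each assay a sharp readout of its target (actives are
#'   essentially the top scorers), small values a noisy one.
#' @param structure_weight,bioactivity_weight Relative weights of the
#'   chemotype and latent-profile signals in the test-assay label model
#'   (both non-negative, not both zero).
#' @param label_noise Scale of the logistic noise added to the test-assay
#'   latent utility; at the default 0.5 the systematic effects dominate
#'   the noise.
#' @param test_prevalence Active fraction of the test assay.
#' @param seed Integer seed; the whole world is a deterministic function of
#'   the configuration.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_compounds = 5000, n_assays = 50,
                             hit_rate_range = c(0.0005, 0.04),
                             coverage = 0.35, n_chemotypes = 8,
                             n_latent_targets = 5, link_slope = 6,
                             structure_weight = 1, bioactivity_weight = 1,
                             label_noise = 0.5,
                             test_prevalence = 0.02, seed = 1) {
  stopifnot(n_compounds >= n_chemotypes, n_chemotypes >= 1,
            n_chemotypes <= length(.chemotype_cores),
            length(hit_rate_range) == 2,
            all(hit_rate_range > 0), all(hit_rate_range < 1),
            coverage > 0, coverage <= 1,
            structure_weight >= 0, bioactivity_weight >= 0,
            link_slope > 0, label_noise >= 0,
            test_prevalence > 0, test_prevalence < 1)
  structure(
    list(n_compounds = as.integer(n_compounds), n_assays = as.integer(n_assays),
         hit_rate_range = hit_rate_range, coverage = coverage,
         n_chemotypes = as.integer(n_chemotypes),
         n_latent_targets = as.integer(n_latent_targets),
         link_slope = link_slope,
         structure_weight = structure_weight,
         bioactivity_weight = bioactivity_weight,
         label_noise = label_noise,
         test_prevalence = test_prevalence, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic compound library
#'
#' Each compound is one of `n_chemotypes` ring-scaffold templates decorated
#' with 1-2 random substituents from a fixed grammar, so compounds of the
#' same chemotype share a generic scaffold and are structurally closer to
#' each other than to other chemotypes.
#'
#' @param n Number of compounds.
#' @param n_chemotypes Number of scaffold templates to use (max 10).
#' @param seed Integer seed.
#' @return A list with `compounds` (a `compound_table`) and `chemotype`
#'   (integer vector aligned with the table rows).
#' @export
generate_compound_library <- function(n, n_chemotypes = 8, seed = 1) {
  stopifnot(n >= n_chemotypes, n_chemotypes >= 1,
            n_chemotypes <= length(.chemotype_cores))
  rng <- local_rng(seed)
  chemotype <- rng$sample(n_chemotypes, n, replace = TRUE)
  sub_a <- .substituents[rng$sample(length(.substituents), n, replace = TRUE)]
  sub_b <- .substituents[rng$sample(length(.substituents), n, replace = TRUE)]
  has_b <- rng$runif(n) < 0.6
  smiles <- vapply(seq_len(n), function(i) {
    tpl <- .chemotype_cores[chemotype[i]]
    tpl <- sub("{A}", sub_a[i], tpl, fixed = TRUE)
    if (grepl("{B}", tpl, fixed = TRUE)) {
      tpl <- if (has_b[i]) sub("{B}", sub_b[i], tpl, fixed = TRUE)
             else sub("({B})", "", tpl, fixed = TRUE)
    }
    tpl
  }, character(1))
  ids <- sprintf("CPD%05d", seq_len(n))
  compounds <- compound_table(ids, smiles)
  if (length(compounds$rejected) > 0) {
    stop("internal error: generated invalid SMILES: ",
         paste(head(compounds$rejected, 5), collapse = ", "), call. = FALSE)
  }
  list(compounds = compounds, chemotype = chemotype)
}

# latent chemotype-target affinities plus compound-level idiosyncrasy:
# score[i, t] = affinity[chemotype(i), t] + eps[i, t]
generate_bioprofile <- function(chemotype, n_targets, seed, affinity = NULL) {
  n <- length(chemotype)
  n_chemo <- max(chemotype)
  rng <- local_rng(seed)
  if (is.null(affinity)) {
    affinity <- matrix(rng$rnorm(n_chemo * n_targets), n_chemo, n_targets)
    affinity <- affinity * (matrix(rng$runif(n_chemo * n_targets), n_chemo,
                                   n_targets) < 0.5)
    # guarantee every target at least one strongly coupled chemotype
    for (t in seq_len(n_targets)) {
      affinity[rng$sample(n_chemo, 1), t] <- affinity[rng$sample(n_chemo, 1), t] + 1.5
    }
  }
  eps <- matrix(rng$rnorm(n * n_targets), n, n_targets)
  list(affinity = affinity, score = affinity[chemotype, , drop = FALSE] + eps)
}

#' Generate sparse panel activity records
#'
#' Links each assay to one latent target, draws its marginal hit rate
#' uniformly from the configured range, tests each compound with
#' probability `coverage`, and makes tested compounds active with a
#' logistic probability in their latent-target score, with the intercept
#' calibrated numerically so the expected hit rate among tested compounds
#' matches the drawn rate.
#'
#' @param library Output of [generate_compound_library()].
#' @param config A `generator_config`.
#' @param bioprofile Optional precomputed latent profile (internal use).
#' @return A list with `records` (data.frame in the activity-table dialect:
#'   `assay_id`, `compound_id`, `outcome`), `assay_target`, `assay_rate`
#'   (drawn target rates) and `bioprofile`.
#' @export
generate_panel <- function(library, config, bioprofile = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n <- nrow(library$compounds$entries)
  ids <- library$compounds$entries$compound_id
  if (is.null(bioprofile)) {
    bioprofile <- generate_bioprofile(library$chemotype,
                                      config$n_latent_targets,
                                      seed = config$seed + 1L)
  }
  rng <- local_rng(config$seed + 2L)
  n_assays <- config$n_assays
  assay_target <- rng$sample(config$n_latent_targets, n_assays, replace = TRUE)
  assay_rate <- rng$runif(n_assays, config$hit_rate_range[1],
                          config$hit_rate_range[2])
  beta <- config$link_slope

  rec_list <- vector("list", n_assays)
  for (j in seq_len(n_assays)) {
    tested <- which(rng$runif(n) < config$coverage)
    if (length(tested) == 0) next
    z <- bioprofile$score[tested, assay_target[j]]
    z <- (z - mean(z)) / max(sd(z), 1e-8)
    a <- uniroot(function(a) mean(plogis(a + beta * z)) - assay_rate[j],
                 interval = c(-100, 20))$root
    active <- rng$runif(length(tested)) < plogis(a + beta * z)
    rec_list[[j]] <- data.frame(
      assay_id = sprintf("AID%03d", j),
      compound_id = ids[tested],
      outcome = ifelse(active, "active", "inactive"),
      stringsAsFactors = FALSE
    )
  }
  list(records = do.call(rbind, rec_list), assay_target = assay_target,
       assay_rate = assay_rate, bioprofile = bioprofile)
}

#' Generate test-assay labels with mixed structural and bioactivity signal
#'
#' Labels follow a latent-utility model: a standardized chemotype effect
#' (a subset of chemotypes is intrinsically active) weighted by
#' `structure_weight`, plus a standardized latent-target profile score
#' weighted by `bioactivity_weight`, plus logistic noise; the top
#' `prevalence` fraction of utilities is labelled active, so the realized
#' prevalence is exact.
#'
#' @param library Output of [generate_compound_library()].
#' @param bioprofile Latent profile list from [generate_panel()].
#' @param target_index Latent target the test assay reads out.
#' @param structure_weight,bioactivity_weight Non-negative signal weights,
#'   not both zero.
#' @param prevalence Active fraction.
#' @param label_noise Scale of the logistic noise term.
#' @param seed Integer seed.
#' @return A list with `labels` (named 0/1 integer vector by compound id),
#'   `active_chemotypes`, `chem_score` and `bio_score`.
#' @export
generate_test_assay <- function(library, bioprofile, target_index = 1,
                                structure_weight = 1, bioactivity_weight = 1,
                                prevalence = 0.02, label_noise = 0.5,
                                seed = 1) {
  if (structure_weight == 0 && bioactivity_weight == 0) {
    stop("structure_weight and bioactivity_weight cannot both be zero",
         call. = FALSE)
  }
  n <- nrow(library$compounds$entries)
  ids <- library$compounds$entries$compound_id
  rng <- local_rng(seed)
  n_chemo <- max(library$chemotype)
  n_active_chemo <- max(1L, round(n_chemo / 3))
  active_chemotypes <- rng$sample(n_chemo, n_active_chemo)
  chem_score <- as.numeric(library$chemotype %in% active_chemotypes)
  bio_score <- bioprofile$score[, target_index]
  zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  det <- structure_weight * zs(chem_score) + bioactivity_weight * zs(bio_score)
  if (sd(det) == 0) {
    stop("test-assay scores have no variance; prevalence unreachable",
         call. = FALSE)
  }
  utility <- det + label_noise * rng$rlogis(n)
  n_active <- max(1L, floor(prevalence * n))
  labels <- integer(n)
  labels[order(-utility)[seq_len(n_active)]] <- 1L
  list(labels = stats::setNames(labels, ids),
       active_chemotypes = active_chemotypes,
       chem_score = chem_score, bio_score = bio_score,
       target_index = target_index)
}

#' Generate a complete synthetic HTS world
#'
#' Convenience wrapper chaining library, latent-profile, panel and
#' test-assay generation. The test assay is appended to the activity
#' records as assay `AIDTEST` with full coverage, so the emitted records
#' round-trip through the regular loading path and the leave-assay-out
#' machinery applies to it like to any other assay.
#'
#' @param config A `generator_config`.
#' @param affinity Optional chemotype-by-target affinity matrix override
#'   (e.g. all-zero for null-signal worlds).
#' @return A `synthetic_world`: list with `compounds`, `chemotype`,
#'   `records` (including `AIDTEST`), `test` (ground truth from
#'   [generate_test_assay()]), `panel_meta` (assay targets and rates),
#'   `bioprofile` and `config`.
#' @export
generate_world <- function(config = generator_config(), affinity = NULL) {
  stopifnot(inherits(config, "generator_config"))
  library <- generate_compound_library(config$n_compounds,
                                       config$n_chemotypes,
                                       seed = config$seed)
  bioprofile <- generate_bioprofile(library$chemotype,
                                    config$n_latent_targets,
                                    seed = config$seed + 1L,
                                    affinity = affinity)
  panel <- generate_panel(library, config, bioprofile = bioprofile)
  test <- generate_test_assay(
    library, bioprofile,
    target_index = panel$assay_target[1],
    structure_weight = config$structure_weight,
    bioactivity_weight = config$bioactivity_weight,
    prevalence = config$test_prevalence,
    label_noise = config$label_noise,
    seed = config$seed + 3L
  )
  test_records <- data.frame(
    assay_id = "AIDTEST",
    compound_id = names(test$labels),
    outcome = ifelse(test$labels == 1, "active", "inactive"),
    stringsAsFactors = FALSE
  )
  structure(
    list(compounds = library$compounds, chemotype = library$chemotype,
         records = rbind(panel$records, test_records),
         test = test,
         panel_meta = data.frame(
           assay_id = sprintf("AID%03d", seq_len(config$n_assays)),
           target = panel$assay_target, rate = panel$assay_rate,
           stringsAsFactors = FALSE),
         bioprofile = bioprofile, config = config),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world: %d compounds, %d panel assays + test assay, seed %d\n",
              x$config$n_compounds, x$config$n_assays, x$config$seed))
  invisible(x)
}
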