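#' Generic (topological) Bemis-Murcko scaffold
#'
#' Reduces each molecule to its ring systems plus the linkers connecting
#' them: side chains are removed by iteratively deleting terminal
#' (degree-1) atoms, every remaining atom is converted to carbon and every
#' bond order set to 1 (all-sp3 carbon skeleton), and the skeleton is
#' canonicalized so equal frameworks compare equal as strings. Acyclic
#' molecules have no framework and yield `NA`.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Character vector of canonical skeleton SMILES, `NA` for acyclic
#'   molecules. The transformation is idempotent.
#' @export
generic_scaffold <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  canon <- ob_canonical(smiles)
  if (anyNA(canon)) {
    stop("invalid SMILES: ",
         paste(head(smiles[is.na(canon)], 5), collapse = ", "), call. = FALSE)
  }
  uniq <- unique(smiles)
  sdfset <- ob_smiles_to_sdf(uniq)
  got <- as.integer(ChemmineR::sdfid(sdfset))
  skeletons <- vector("list", length(uniq))
  keep_ids <- integer(0)
  for (i in seq_along(sdfset)) {
    sk <- skeleton_sdf(sdfset[[i]])
    if (!is.null(sk)) {
      skeletons[[got[i]]] <- sk
      keep_ids <- c(keep_ids, got[i])
    }
  }
  res_uniq <- rep(NA_character_, length(uniq))
  if (length(keep_ids)) {
    sks <- methods::new("SDFset", SDF = skeletons[keep_ids],
                        ID = as.character(keep_ids))
    res_uniq[keep_ids] <- ob_sdf_to_canonical(sks, length(uniq))[keep_ids]
  }
  res_uniq[match(smiles, uniq)]
}

# prune side chains and saturate one molecule; NULL if acyclic.
# the SDF title is rewritten to the molecule's index so canonical SMILES
# can be mapped back after the OpenBabel round trip.
skeleton_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  if (is.null(bb) || nrow(bb) == 0 || n < 3) return(NULL)
  edges <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  keep <- rep(TRUE, n)
  repeat {
    live <- keep[edges[, 1]] & keep[edges[, 2]]
    deg <- tabulate(c(edges[live, ]), nbins = n)
    drop <- keep & deg <= 1
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  if (!any(keep)) return(NULL)
  idx <- which(keep)
  remap <- match(seq_len(n), idx)
  live <- keep[edges[, 1]] & keep[edges[, 2]]
  e2 <- edges[live, , drop = FALSE]
  ab2 <- ab[idx, , drop = FALSE]
  ab2[] <- 0
  rownames(ab2) <- paste0("C_", seq_along(idx))
  bb2 <- cbind(remap[e2[, 1]], remap[e2[, 2]], 1L)
  colnames(bb2) <- c("C1", "C2", "C3")
  h <- ChemmineR::header(sdf)
  h["Counts_Line"] <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                              length(idx), nrow(bb2))
  methods::new("SDF", header = h, atomblock = ab2, bondblock = bb2,
               datablock = character(0))
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`: 1 for identical non-empty fingerprints, 0 for
#' disjoint bit sets.
#'
#' @param fp_a,fp_b Binary vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  stopifnot(length(fp_a) == length(fp_b))
  a <- as.logical(fp_a); b <- as.logical(fp_b)
  uni <- sum(a | b)
  if (uni == 0) {
    stop("Tanimoto undefined: both fingerprints are empty", call. = FALSE)
  }
  sum(a & b) / uni
}

# all-pairs Tanimoto for the rows of a binary matrix
tanimoto_matrix <- function(bits) {
  stopifnot(is.matrix(bits))
  m <- matrix(as.numeric(bits != 0), nrow = nrow(bits))
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  uni <- outer(ones, ones, "+") - inter
  sim <- inter / uni
  sim[uni == 0] <- NA_real_
  dimnames(sim) <- list(rownames(bits), rownames(bits))
  sim
}

#' Nearest-neighbor Tanimoto similarity within a compound selection
#'
#' For each compound in the selection, the maximum Tanimoto similarity to
#' any other selected compound, computed on the structural fingerprint
#' regardless of which model produced the selection. The distribution of
#' these values summarizes the structural diversity of a predicted hit
#' list: a tight chemical series piles up near 1, a diverse set sits low.
#'
#' @param selection Character vector of compound ids (length >= 2).
#' @param structural_fps A `structural_fp` matrix covering the selection.
#' @return Named numeric vector of nearest-neighbor similarities in
#'   `[0, 1]`, one per selected compound.
#' @export
nearest_neighbor_similarities <- function(selection, structural_fps) {
  stopifnot(is.character(selection))
  if (length(selection) < 2) {
    stop("nearest-neighbor similarity needs at least two compounds", call. = FALSE)
  }
  idx <- match(selection, rownames(structural_fps))
  if (anyNA(idx)) {
    stop("selection contains compounds without structural fingerprints: ",
         paste(head(selection[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  }
  sim <- tanimoto_matrix(unclass(structural_fps)[idx, , drop = FALSE])
  diag(sim) <- NA_real_
  nn <- apply(sim, 1, max, na.rm = TRUE)
  stats::setNames(nn, selection)
}

# region counts of a three-set Venn diagram
venn_regions <- function(a, b, c) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(a, union(b, c))
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  c(
    a_only = sum(in_a & !in_b & !in_c),
    b_only = sum(!in_a & in_b & !in_c),
    c_only = sum(!in_a & !in_b & in_c),
    ab = sum(in_a & in_b & !in_c),
    ac = sum(in_a & !in_b & in_c),
    bc = sum(!in_a & in_b & in_c),
    abc = sum(in_a & in_b & in_c)
  )
}

#' Scaffold-overlap report across prediction models
#'
#' Computes, per cross-validation fold, the set of unique generic scaffolds
#' among each model's true-positive top-fraction selections, the seven
#' region counts of the three-set Venn diagram, and their means across
#' folds. Acyclic compounds (no ring framework) are excluded from scaffold
#' counting.
#'
#' @param selections Named list (one element per model, e.g. `bash`,
#'   `htsfp`, `ecfp4`); each element is a list of per-fold character
#'   vectors of selected compound ids.
#' @param compounds A `compound_table` with SMILES for every selected
#'   compound.
#' @return A `scaffold_report`: list with `models`, `per_fold_sets`
#'   (model -> fold -> scaffold character vector), `set_sizes` (folds x
#'   models), `regions` (folds x 7 regions, models in the order given),
#'   `region_means`, `set_size_means` and `pooled_sets` (per-model union
#'   over folds).
#' @export
scaffold_sets <- function(selections, compounds) {
  stopifnot(is.list(selections), length(selections) == 3,
            !is.null(names(selections)))
  models <- names(selections)
  n_folds <- unique(lengths(selections))
  stopifnot(length(n_folds) == 1)

  all_ids <- unique(unlist(selections, use.names = FALSE))
  scafs <- if (length(all_ids)) {
    stats::setNames(generic_scaffold(compound_smiles(compounds, all_ids)), all_ids)
  } else stats::setNames(character(0), character(0))

  sets <- lapply(selections, function(per_fold) {
    lapply(per_fold, function(ids) {
      s <- scafs[ids]
      sort(unique(s[!is.na(s)]))
    })
  })
  set_sizes <- sapply(sets, function(per_fold) vapply(per_fold, length, integer(1)))
  set_sizes <- matrix(set_sizes, nrow = n_folds,
                      dimnames = list(NULL, models))
  regions <- t(vapply(seq_len(n_folds), function(f) {
    venn_regions(sets[[1]][[f]], sets[[2]][[f]], sets[[3]][[f]])
  }, numeric(7)))
  structure(
    list(models = models, per_fold_sets = sets, set_sizes = set_sizes,
         regions = regions,
         region_means = colMeans(regions),
         set_size_means = colMeans(set_sizes),
         pooled_sets = lapply(sets, function(s) sort(unique(unlist(s))))),
    class = "scaffold_report"
  )
}

#' @export
print.scaffold_report <- function(x, ...) {
  cat("scaffold_report over models:", paste(x$models, collapse = ", "), "\n")
  cat("  mean unique scaffolds per fold:",
      paste(sprintf("%s=%.1f", x$models, x$set_size_means), collapse = ", "), "\n")
  cat("  mean Venn regions (display rounded):\n")
  print(round(x$region_means))
  invisible(x)
}

#' Cross-model ranking comparison of the top hybrid-model compounds
#'
#' Takes the `top_n` compounds ranked best by the hybrid (BaSH) model and
#' looks up where each of them ranks in the structural-only and
#' bioactivity-only models (pooled held-out rankings). Compounds outside
#' `top_n` in both single models fall in the upper-right quadrant of the
#' rank-rank scatter: hits neither parent descriptor would have surfaced.
#'
#' @param bash_cv,ecfp_cv,htsfp_cv `cv_result` objects over the same
#'   compound universe.
#' @param top_n Selection size (default 1000, capped at the universe size).
#' @return A `rank_comparison`: list with `table` (data.frame
#'   `compound_id`, `bash_rank`, `ecfp_rank`, `htsfp_rank`, `label`),
#'   `quadrants` (named counts `both_top`, `ecfp_only`, `htsfp_only`,
#'   `neither`) and `top_n`.
#' @export
rank_comparison <- function(bash_cv, ecfp_cv, htsfp_cv, top_n = 1000) {
  stopifnot(inherits(bash_cv, "cv_result"), inherits(ecfp_cv, "cv_result"),
            inherits(htsfp_cv, "cv_result"))
  ids <- sort(bash_cv$predictions$compound_id)
  if (!identical(ids, sort(ecfp_cv$predictions$compound_id)) ||
      !identical(ids, sort(htsfp_cv$predictions$compound_id))) {
    stop("cv results cover different compound universes", call. = FALSE)
  }
  top_n <- min(top_n, length(ids))
  b <- bash_cv$predictions
  sel <- b[b$rank <= top_n, , drop = FALSE]
  e <- ecfp_cv$predictions
  h <- htsfp_cv$predictions
  tab <- data.frame(
    compound_id = sel$compound_id,
    bash_rank = sel$rank,
    ecfp_rank = e$rank[match(sel$compound_id, e$compound_id)],
    htsfp_rank = h$rank[match(sel$compound_id, h$compound_id)],
    label = sel$label,
    stringsAsFactors = FALSE
  )
  quadrants <- c(
    both_top = sum(tab$ecfp_rank <= top_n & tab$htsfp_rank <= top_n),
    ecfp_only = sum(tab$ecfp_rank <= top_n & tab$htsfp_rank > top_n),
    htsfp_only = sum(tab$ecfp_rank > top_n & tab$htsfp_rank <= top_n),
    neither = sum(tab$ecfp_rank > top_n & tab$htsfp_rank > top_n)
  )
  structure(list(table = tab, quadrants = quadrants, top_n = top_n),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("rank_comparison: top %d hybrid-model compounds\n", x$top_n))
  print(x$quadrants)
  invisible(x)
}
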