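#' Build an HTS fingerprint matrix from a resolved panel
#'
#' The HTS fingerprint (HTSFP) encodes each compound as a binary vector over
#' a panel of historical screening assays: bit = 1 where the compound's
#' resolved flag in that assay is active, and 0 both for resolved-inactive
#' and for never-tested cells. Collapsing missing data onto the inactive
#' state reflects the extreme class imbalance of HTS panels: an untested
#' compound is far more likely to be inactive than active, so a
#' tested-inactive compound and a never-tested compound receive identical
#' rows.
#'
#' @param panel A `resolved_panel` from [resolve_replicates()].
#' @param compound_universe Ordered character vector of compound ids to use
#'   as rows. Compounds never tested in any panel assay get all-zero rows.
#' @return An `htsfp_matrix`: integer 0/1 matrix with `compound_universe`
#'   rownames and the panel's `assay_ids` as colnames.
#' @export
build_htsfp <- function(panel, compound_universe) {
  stopifnot(inherits(panel, "resolved_panel"),
            is.character(compound_universe), length(compound_universe) >= 1)
  if (anyDuplicated(compound_universe)) {
    stop("compound_universe contains duplicates", call. = FALSE)
  }
  bits <- matrix(0L, nrow = length(compound_universe),
                 ncol = length(panel$assay_ids),
                 dimnames = list(compound_universe, panel$assay_ids))
  act <- panel$pairs[panel$pairs$active, , drop = FALSE]
  ri <- match(act$compound_id, compound_universe)
  ci <- match(act$assay_id, panel$assay_ids)
  ok <- !is.na(ri)
  bits[cbind(ri[ok], ci[ok])] <- 1L
  structure(bits, class = c("htsfp_matrix", "matrix", "array"))
}

#' Build folded circular (Morgan/ECFP) structural fingerprints
#'
#' Hashes circular atom environments up to `radius` bonds (ECFP uses the
#' diameter, so radius 2 corresponds to ECFP4) and folds them onto a fixed
#' binary vector of `n_bits` hash buckets. Fingerprints are computed from
#' SMILES via OpenBabel's extended-connectivity implementation and are
#' invariant to the textual rendering of the molecule.
#'
#' @param compounds A `compound_table`, or a named character vector of
#'   SMILES (names = compound ids).
#' @param radius Circular environment radius in bonds (default 2 = ECFP4).
#' @param n_bits Folded fingerprint width (default 1024).
#' @return A `structural_fp`: integer 0/1 matrix (compounds x bits) with
#'   compound-id rownames and attribute `params = list(radius, n_bits)`.
#' @export
build_structural_fp <- function(compounds, radius = 2, n_bits = 1024) {
  if (inherits(compounds, "compound_table")) {
    smiles <- stats::setNames(compounds$entries$smiles,
                              compounds$entries$compound_id)
  } else {
    smiles <- compounds
  }
  stopifnot(is.character(smiles), length(smiles) >= 1, !is.null(names(smiles)))
  stopifnot(radius >= 1, n_bits >= 8)
  # fingerprint unique SMILES once; duplicated structures share rows
  uniq <- unique(unname(smiles))
  raw <- ob_ecfp(uniq, radius = radius)
  canon <- ob_canonical(uniq)
  if (anyNA(canon)) {
    bad <- names(smiles)[match(uniq[is.na(canon)], smiles)]
    stop("invalid SMILES reached build_structural_fp for compound(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  folded <- fold_bits(raw, n_bits)
  bits <- folded[match(unname(smiles), uniq), , drop = FALSE]
  dimnames(bits) <- list(names(smiles), paste0("bit", seq_len(n_bits) - 1L))
  structure(bits, params = list(radius = radius, n_bits = n_bits),
            class = c("structural_fp", "matrix", "array"))
}

#' Concatenate bioactivity and structural fingerprints into a BaSH set
#'
#' The bioactivity-structure hybrid (BaSH) fingerprint is the column-wise
#' concatenation of the HTSFP block (first) and the structural block
#' (second); for the full-scale panel of 561 assays and a 1024-bit ECFP4
#' this gives a width of 1585. Per-column provenance is recorded so either
#' parent can be recovered by projection and so downstream feature-importance
#' analysis can attribute signal to a block.
#'
#' @param htsfp An `htsfp_matrix` from [build_htsfp()].
#' @param structural A `structural_fp` from [build_structural_fp()].
#' @return A `fingerprint_set`: list with `features` (binary matrix),
#'   `compound_ids`, and `provenance` (data.frame with `block` in
#'   `{"bioactivity","structural"}` and `ref` naming the assay id or bit).
#' @export
build_bash <- function(htsfp, structural) {
  stopifnot(inherits(htsfp, "htsfp_matrix"), inherits(structural, "structural_fp"))
  if (!identical(rownames(htsfp), rownames(structural))) {
    stop("compound ordering mismatch between HTSFP and structural fingerprints",
         call. = FALSE)
  }
  features <- cbind(unclass(htsfp), unclass(structural))
  attr(features, "params") <- NULL
  provenance <- data.frame(
    block = c(rep("bioactivity", ncol(htsfp)), rep("structural", ncol(structural))),
    ref = c(colnames(htsfp), colnames(structural)),
    stringsAsFactors = FALSE
  )
  fingerprint_set(features, provenance)
}

#' Construct a fingerprint set from a feature matrix and provenance
#'
#' @param features Binary feature matrix with compound-id rownames.
#' @param provenance Data.frame with columns `block` and `ref`, one row per
#'   feature column.
#' @return A `fingerprint_set` object.
#' @export
fingerprint_set <- function(features, provenance) {
  stopifnot(is.matrix(features), !is.null(rownames(features)),
            is.data.frame(provenance),
            all(c("block", "ref") %in% names(provenance)),
            nrow(provenance) == ncol(features))
  stopifnot(all(provenance$block %in% c("bioactivity", "structural")))
  structure(
    list(features = features, compound_ids = rownames(features),
         provenance = provenance),
    class = "fingerprint_set"
  )
}

#' Coerce single-block fingerprints to a fingerprint set
#'
#' @param x An `htsfp_matrix`, `structural_fp` or `fingerprint_set`.
#' @return A `fingerprint_set` with homogeneous block provenance.
#' @export
as_fingerprint_set <- function(x) {
  if (inherits(x, "fingerprint_set")) return(x)
  if (inherits(x, "htsfp_matrix")) {
    return(fingerprint_set(unclass(x),
                           data.frame(block = "bioactivity", ref = colnames(x),
                                      stringsAsFactors = FALSE)))
  }
  if (inherits(x, "structural_fp")) {
    m <- unclass(x)
    attr(m, "params") <- NULL
    return(fingerprint_set(m,
                           data.frame(block = "structural", ref = colnames(m),
                                      stringsAsFactors = FALSE)))
  }
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to fingerprint_set", call. = FALSE)
}

#' @export
print.fingerprint_set <- function(x, ...) {
  tab <- table(x$provenance$block)
  cat(sprintf("fingerprint_set: %d compounds x %d features (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Remove one assay column from a bioactivity fingerprint
#'
#' Leave-assay-out guard: before benchmarking a test assay, its own column
#' must be removed from the HTSFP (and hence BaSH) features, otherwise the
#' model would see the labels it is asked to predict.
#'
#' @param fps An `htsfp_matrix` or `fingerprint_set`.
#' @param assay_id The assay column to remove; must be present among the
#'   bioactivity columns.
#' @return Object of the same class with exactly that column removed.
#' @export
exclude_assay <- function(fps, assay_id) UseMethod("exclude_assay")

#' @export
exclude_assay.htsfp_matrix <- function(fps, assay_id) {
  stopifnot(length(assay_id) == 1)
  j <- match(assay_id, colnames(fps))
  if (is.na(j)) stop("assay ", assay_id, " not present in HTSFP", call. = FALSE)
  out <- unclass(fps)[, -j, drop = FALSE]
  structure(out, class = c("htsfp_matrix", "matrix", "array"))
}

#' @export
exclude_assay.fingerprint_set <- function(fps, assay_id) {
  stopifnot(length(assay_id) == 1)
  hit <- fps$provenance$block == "bioactivity" & fps$provenance$ref == assay_id
  if (!any(hit)) {
    stop("assay ", assay_id, " not present among bioactivity columns",
         call. = FALSE)
  }
  fingerprint_set(fps$features[, !hit, drop = FALSE],
                  fps$provenance[!hit, , drop = FALSE])
}

#' Project a fingerprint set onto one provenance block
#'
#' @param fps A `fingerprint_set`.
#' @param block `"bioactivity"` or `"structural"`.
#' @return The feature sub-matrix of that block (columns in original order).
#' @export
project_block <- function(fps, block = c("bioactivity", "structural")) {
  stopifnot(inherits(fps, "fingerprint_set"))
  block <- match.arg(block)
  sel <- fps$provenance$block == block
  m <- fps$features[, sel, drop = FALSE]
  colnames(m) <- fps$provenance$ref[sel]
  m
}

#' Serialize / read a binary fingerprint matrix as sparse triplets
#'
#' HTSFP matrices are typically >99% zeros, so matrices are stored as a
#' plain-text triplet table (`row_id`, `column_id`, value 1) together with a
#' sidecar listing the full row and column index (needed to preserve
#' all-zero rows and columns).
#'
#' @param m A binary matrix with row and column names (`htsfp_matrix`,
#'   `structural_fp` or plain matrix).
#' @param path Output path for the triplet table; the index sidecar is
#'   written to `<path>.idx`.
#' @return `path`, invisibly.
#' @export
write_fingerprint_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  idx <- which(m != 0, arr.ind = TRUE)
  trip <- data.frame(row_id = rownames(m)[idx[, 1]],
                     column_id = colnames(m)[idx[, 2]],
                     value = 1L, stringsAsFactors = FALSE)
  write.table(trip, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- c(paste0("row\t", rownames(m)), paste0("column\t", colnames(m)))
  writeLines(side, paste0(path, ".idx"))
  invisible(path)
}

#' @rdname write_fingerprint_matrix
#' @export
read_fingerprint_matrix <- function(path) {
  trip <- read.table(path, header = TRUE, sep = "\t",
                     colClasses = c("character", "character", "integer"))
  side <- strsplit(readLines(paste0(path, ".idx")), "\t", fixed = TRUE)
  kind <- vapply(side, `[[`, "", 1L)
  ids <- vapply(side, `[[`, "", 2L)
  rows <- ids[kind == "row"]; cols <- ids[kind == "column"]
  m <- matrix(0L, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  if (nrow(trip)) {
    m[cbind(match(trip$row_id, rows), match(trip$column_id, cols))] <- 1L
  }
  m
}
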