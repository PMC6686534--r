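#' Read an HTS activity table
#'
#' Parses a delimited text export of screening outcomes into a long table of
#' activity records. The file must carry a header row naming the columns
#' `assay_id`, `compound_id` and `outcome`; the delimiter is auto-detected
#' between tab and comma. Outcome strings `Active` and `Inactive`
#' (case-insensitive) map to `"active"`/`"inactive"`; anything else
#' (`Inconclusive`, `Unspecified`, `Probe`, ...) maps to `"other"` and is
#' ignored later when replicate outcomes are voted on. Duplicated
#' (assay, compound) rows are preserved here; see [resolve_replicates()].
#'
#' @param path Path to a delimited text file with header
#'   `assay_id,compound_id,outcome`.
#' @return A `data.frame` with character columns `assay_id`, `compound_id`
#'   and factor-free character column `outcome` (one of `active`,
#'   `inactive`, `other`), one row per data row of the file.
#' @seealso [resolve_replicates()], [filter_assays_by_size()]
#' @export
parse_activity_records <- function(path) {
  if (!file.exists(path)) stop("activity table not found: ", path, call. = FALSE)
  sep <- detect_delim(path)
  df <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                   quote = "\"", comment.char = "", stringsAsFactors = FALSE)
  required <- c("assay_id", "compound_id", "outcome")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("activity table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("activity table ", path, " has a header but no data rows")
    return(data.frame(assay_id = character(0), compound_id = character(0),
                      outcome = character(0), stringsAsFactors = FALSE))
  }
  records <- df[required]
  if (any(!nzchar(records$assay_id)) || any(!nzchar(records$compound_id))) {
    stop("activity table contains empty assay_id or compound_id values",
         call. = FALSE)
  }
  records$outcome <- normalize_outcome(records$outcome)
  bfp_log("read %d activity records from %s (%d 'other' outcomes)",
          nrow(records), path, sum(records$outcome == "other"))
  records
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) return(",")
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_com <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (n_tab >= n_com) "\t" else ","
}

normalize_outcome <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep("other", length(x))
  out[lx == "active"] <- "active"
  out[lx == "inactive"] <- "inactive"
  out
}

#' Resolve replicate activity outcomes into one flag per compound-assay pair
#'
#' Compounds screened several times in the same assay can carry mixed
#' outcomes. Non-binary (`other`) outcomes are discarded first; among the
#' remaining flags the most common one wins, and an exact active/inactive
#' tie resolves to `active`. Pairs observed only with `other` outcomes are
#' dropped from the panel (counted in the log line).
#'
#' @param records A data.frame of activity records as returned by
#'   [parse_activity_records()] (columns `assay_id`, `compound_id`,
#'   `outcome`), or any data.frame with those columns.
#' @return A `resolved_panel` object: list with `assay_ids` (ordered as first
#'   encountered), `pairs` (data.frame `assay_id`, `compound_id`, `active`
#'   logical, one row per resolved pair) and `tested` (named integer vector
#'   of per-assay tested-compound counts).
#' @export
resolve_replicates <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("no activity records to resolve", call. = FALSE)
  required <- c("assay_id", "compound_id", "outcome")
  stopifnot(all(required %in% names(records)))
  assay_order <- unique(records$assay_id)

  keep <- records$outcome %in% c("active", "inactive")
  n_other_pairs <- 0L
  if (!all(keep)) {
    all_pairs <- unique(paste0(records$assay_id, "\r", records$compound_id))
    records <- records[keep, , drop = FALSE]
    kept_pairs <- unique(paste0(records$assay_id, "\r", records$compound_id))
    n_other_pairs <- length(all_pairs) - length(kept_pairs)
  }
  if (nrow(records) == 0) stop("all records have non-binary outcomes", call. = FALSE)

  key <- paste0(records$assay_id, "\r", records$compound_id)
  is_active <- records$outcome == "active"
  n_act <- tapply(is_active, key, sum)
  n_tot <- tapply(is_active, key, length)
  # majority vote, exact tie -> active
  resolved_active <- as.vector(n_act) >= as.vector(n_tot) / 2
  parts <- strsplit(names(n_act), "\r", fixed = TRUE)
  pairs <- data.frame(
    assay_id = vapply(parts, `[[`, "", 1L),
    compound_id = vapply(parts, `[[`, "", 2L),
    active = resolved_active,
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(match(pairs$assay_id, assay_order), pairs$compound_id), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  assay_ids <- assay_order[assay_order %in% pairs$assay_id]
  tested <- vapply(assay_ids, function(a) sum(pairs$assay_id == a), integer(1))
  bfp_log("resolved %d records into %d compound-assay pairs across %d assays (%d all-'other' pairs dropped)",
          length(key), nrow(pairs), length(assay_ids), n_other_pairs)
  structure(
    list(assay_ids = assay_ids, pairs = pairs, tested = tested),
    class = "resolved_panel"
  )
}

#' @export
print.resolved_panel <- function(x, ...) {
  cat(sprintf("resolved_panel: %d assays, %d compound-assay pairs\n",
              length(x$assay_ids), nrow(x$pairs)))
  cat(sprintf("  tested counts: min %d / median %.0f / max %d\n",
              min(x$tested), stats::median(x$tested), max(x$tested)))
  invisible(x)
}

#' Drop assays below a minimum screened-compound count
#'
#' Small assays contribute little to a screening fingerprint while adding
#' sparsity; panels are routinely restricted to assays above a size cutoff
#' (20,000 compounds for full-scale PubChem panels).
#'
#' @param panel A `resolved_panel` from [resolve_replicates()].
#' @param min_compounds Minimum number of tested compounds an assay must
#'   have to be retained (`>= 1`).
#' @return A `resolved_panel` containing exactly the assays with tested
#'   count `>= min_compounds`, in their original order, with their compound
#'   mappings untouched.
#' @export
filter_assays_by_size <- function(panel, min_compounds) {
  stopifnot(inherits(panel, "resolved_panel"), min_compounds >= 1)
  keep <- panel$assay_ids[panel$tested[panel$assay_ids] >= min_compounds]
  if (length(keep) == 0) {
    stop("no assays with at least ", min_compounds, " tested compounds",
         call. = FALSE)
  }
  dropped <- length(panel$assay_ids) - length(keep)
  if (dropped > 0) {
    bfp_log("dropped %d assays below %d compounds (%d retained)",
            dropped, min_compounds, length(keep))
  }
  pairs <- panel$pairs[panel$pairs$assay_id %in% keep, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(assay_ids = keep, pairs = pairs, tested = panel$tested[keep]),
    class = "resolved_panel"
  )
}

#' Load a compound structure table and validate its SMILES
#'
#' Reads a two-column delimited file mapping compound ids to SMILES and
#' validates every structure with OpenBabel. Unparsable SMILES are routed to
#' the `rejected` slot rather than kept; duplicated compound ids keep their
#' first SMILES.
#'
#' @param path Path to a delimited text file with header `compound_id,smiles`
#'   (tab or comma separated).
#' @return A `compound_table` object: list with `entries` (data.frame
#'   `compound_id`, `smiles` of valid structures) and `rejected` (character
#'   vector of compound ids whose SMILES failed to parse).
#' @export
load_compound_table <- function(path) {
  if (!file.exists(path)) stop("compound table not found: ", path, call. = FALSE)
  sep <- detect_delim(path)
  df <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                   quote = "\"", comment.char = "", stringsAsFactors = FALSE)
  required <- c("compound_id", "smiles")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("compound table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  compound_table(df$compound_id, df$smiles)
}

#' Build a validated compound table from vectors
#'
#' In-memory companion of [load_compound_table()]; used directly by the
#' synthetic generator and tests.
#'
#' @param compound_id Character vector of compound identifiers.
#' @param smiles Character vector of SMILES, same length.
#' @return A `compound_table` object (see [load_compound_table()]).
#' @export
compound_table <- function(compound_id, smiles) {
  stopifnot(length(compound_id) == length(smiles))
  dup <- duplicated(compound_id)
  if (any(dup)) {
    bfp_log("compound table: %d duplicated compound ids, keeping first SMILES",
            sum(dup))
    smiles <- smiles[!dup]
    compound_id <- compound_id[!dup]
  }
  canon <- ob_canonical(smiles)
  bad <- is.na(canon)
  if (all(bad)) stop("no valid SMILES in compound table", call. = FALSE)
  entries <- data.frame(compound_id = compound_id[!bad],
                        smiles = smiles[!bad],
                        stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  bfp_log("compound table: %d valid compounds, %d rejected SMILES",
          nrow(entries), sum(bad))
  structure(
    list(entries = entries, rejected = compound_id[bad]),
    class = "compound_table"
  )
}

#' @export
print.compound_table <- function(x, ...) {
  cat(sprintf("compound_table: %d compounds (%d rejected SMILES)\n",
              nrow(x$entries), length(x$rejected)))
  invisible(x)
}

# named SMILES lookup helper
compound_smiles <- function(compounds, compound_ids) {
  stopifnot(inherits(compounds, "compound_table"))
  idx <- match(compound_ids, compounds$entries$compound_id)
  if (anyNA(idx)) {
    stop("unknown compound id(s): ",
         paste(head(compound_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(compounds$entries$smiles[idx], compound_ids)
}

#' Write activity records / compound tables in the package's dialect
#'
#' Convenience writers producing files that round-trip through
#' [parse_activity_records()] and [load_compound_table()].
#'
#' @param records Data.frame with `assay_id`, `compound_id`, `outcome`.
#' @param path Output file path.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_activity_records <- function(records, path, sep = ",") {
  stopifnot(all(c("assay_id", "compound_id", "outcome") %in% names(records)))
  write.table(records[c("assay_id", "compound_id", "outcome")], path,
              sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_activity_records
#' @param compounds A `compound_table` or data.frame with `compound_id`,
#'   `smiles`.
#' @export
write_compound_table <- function(compounds, path, sep = ",") {
  df <- if (inherits(compounds, "compound_table")) compounds$entries else compounds
  stopifnot(all(c("compound_id", "smiles") %in% names(df)))
  write.table(df[c("compound_id", "smiles")], path,
              sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
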