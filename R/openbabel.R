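# Thin wrappers around the OpenBabel command line (obabel) for batch
# SMILES handling: canonicalization/validation, ECFP bit generation, and
# SDF round-trips.  All functions map results back to the caller's order
# through numeric record titles, so molecules that OpenBabel rejects are
# reported as NA rather than silently shifting positions.

ob_available <- function() nzchar(Sys.which("obabel"))

ob_check <- function() {
  if (!ob_available()) {
    stop("OpenBabel executable 'obabel' not found on the PATH", call. = FALSE)
  }
}

# run obabel on a temporary input file; returns stdout lines
ob_run <- function(input_lines, in_ext, args) {
  ob_check()
  infile <- tempfile(fileext = in_ext)
  on.exit(unlink(infile), add = TRUE)
  writeLines(input_lines, infile)
  out <- suppressWarnings(
    system2("obabel", c(infile, args), stdout = TRUE, stderr = FALSE)
  )
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0) {
    stop("obabel exited with status ", attr(out, "status"), call. = FALSE)
  }
  out
}

# smiles -> named map of canonical SMILES; NA for strings OpenBabel rejects
ob_canonical <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  lines <- paste(smiles, seq_along(smiles))
  out <- ob_run(lines, ".smi", c("-ocan", "-e"))
  res <- rep(NA_character_, length(smiles))
  if (length(out)) {
    parts <- strsplit(out, "\t", fixed = TRUE)
    ok <- lengths(parts) >= 2
    idx <- as.integer(vapply(parts[ok], function(p) trimws(p[[2]]), ""))
    res[idx] <- vapply(parts[ok], `[[`, "", 1L)
  }
  res
}

# lookup table: hex character -> 4 bits (low bit first within the nibble);
# the exact within-byte order is irrelevant as long as it is fixed, since
# folded fingerprint bits are anonymous hash buckets
.hex_bits <- local({
  tab <- matrix(0L, nrow = 256, ncol = 4)
  chars <- c(as.character(0:9), letters[1:6], LETTERS[1:6])
  vals <- c(0:9, 10:15, 10:15)
  for (i in seq_along(chars)) {
    v <- vals[i]
    tab[utf8ToInt(chars[i]), ] <- as.integer(intToBits(v)[1:4])
  }
  tab
})

# parse FPS hex lines into a binary matrix (rows follow the order of `titles`)
ob_parse_fps <- function(out, n, n_bits_native) {
  keep <- out[!startsWith(out, "#") & nzchar(out)]
  bits <- matrix(0L, nrow = n, ncol = n_bits_native)
  for (line in keep) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    idx <- as.integer(trimws(parts[[2]]))
    codes <- utf8ToInt(parts[[1]])
    row <- as.vector(t(.hex_bits[codes, , drop = FALSE]))
    bits[idx, seq_along(row)] <- row
  }
  bits
}

# Extended-connectivity fingerprints via OpenBabel; radius r maps onto the
# ECFP_{2r} type (diameter naming).  Native width is 4096 bits.
ob_ecfp <- function(smiles, radius = 2) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (!radius %in% 1:5) {
    stop("radius must be between 1 and 5 (ECFP2..ECFP10)", call. = FALSE)
  }
  type <- paste0("ECFP", 2L * radius)
  lines <- paste(smiles, seq_along(smiles))
  out <- ob_run(lines, ".smi", c("-ofps", paste0("-xf", type), "-e"))
  ob_parse_fps(out, length(smiles), 4096L)
}

# OR-fold a wide binary fingerprint down to n_bits hash buckets (modulo rule)
fold_bits <- function(bits, n_bits) {
  stopifnot(is.matrix(bits), n_bits >= 8, n_bits <= ncol(bits))
  folded <- matrix(0L, nrow = nrow(bits), ncol = n_bits)
  for (start in seq(1L, ncol(bits), by = n_bits)) {
    end <- min(start + n_bits - 1L, ncol(bits))
    blk <- bits[, start:end, drop = FALSE]
    folded[, seq_len(ncol(blk))] <- pmax(folded[, seq_len(ncol(blk)), drop = FALSE], blk)
  }
  folded
}

# SMILES -> SDFset (batch, via an SDF temp file)
ob_smiles_to_sdf <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  lines <- paste(smiles, seq_along(smiles))
  out <- ob_run(lines, ".smi", c("-osdf", "-e"))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(out, tf)
  ChemmineR::read.SDFset(tf)
}

# SDFset -> canonical SMILES (titles must be numeric indices 1..n)
ob_sdf_to_canonical <- function(sdfset, n) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  ChemmineR::write.SDF(sdfset, tf)
  out <- suppressWarnings(
    system2("obabel", c(tf, "-ocan", "-e"), stdout = TRUE, stderr = FALSE)
  )
  res <- rep(NA_character_, n)
  if (length(out)) {
    parts <- strsplit(out, "\t", fixed = TRUE)
    ok <- lengths(parts) >= 2
    idx <- as.integer(vapply(parts[ok], function(p) trimws(p[[2]]), ""))
    res[idx] <- vapply(parts[ok], `[[`, "", 1L)
  }
  res
}
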