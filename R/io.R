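#' Read a FASTA file into a tibble
#'
#' Thin, validating wrapper around [Biostrings::readBStringSet()]. Record
#' order is preserved and multi-line sequences are concatenated. Record ids
#' are the first whitespace-delimited token of each header and must be
#' unique.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param alphabet `"rna"` converts T to U, `"dna"` converts U to T,
#'   `"as-is"` leaves sequences untouched (uppercased in all cases).
#' @return A tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path, alphabet = c("rna", "dna", "as-is")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(sprintf("malformed FASTA '%s': %s", path,
                                                    conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(set))
  if (anyNA(ids) || any(ids == "")) abort(sprintf("malformed FASTA header in '%s'", path))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate FASTA ids in '%s': %s", path, paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0) {
    abort(sprintf("empty sequence for record '%s' in '%s'", ids[empty[1]], path))
  }
  seqs <- switch(alphabet, rna = as_rna(seqs), dna = as_dna(seqs), `as-is` = seqs)
  tibble(id = ids, seq = unname(seqs))
}

#' Write a tibble of sequences to FASTA
#'
#' @param x Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[i]), con)
    s <- x$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' Reads 4-line FASTQ records (plain or gzip) into a tibble. Sequence and
#' quality strings must have equal length per record; truncated files are
#' rejected.
#'
#' @param path Path to a FASTQ file.
#' @param stage Optional stage label attached to every read.
#' @return A tibble with columns `read_id`, `seq`, `qual` and, if `stage`
#'   is given, `stage`.
#' @export
read_fastq <- function(path, stage = NULL) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  lines <- readLines(path)  # readLines transparently handles gzip
  if (length(lines) %% 4 != 0) {
    abort(sprintf("truncated FASTQ '%s': %d lines is not a multiple of 4",
                  path, length(lines)))
  }
  n <- length(lines) %/% 4
  if (n == 0) {
    out <- tibble(read_id = character(), seq = character(), qual = character())
    if (!is.null(stage)) out$stage <- character()
    return(out)
  }
  idx <- seq_len(n)
  hdr <- lines[4 * idx - 3]
  seqs <- lines[4 * idx - 2]
  plus <- lines[4 * idx - 1]
  qual <- lines[4 * idx]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr) > 0) {
    abort(sprintf("malformed FASTQ '%s': record %d header does not start with '@'",
                  path, bad_hdr[1]))
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus) > 0) {
    abort(sprintf("malformed FASTQ '%s': record %d separator line is not '+'",
                  path, bad_plus[1]))
  }
  mism <- which(nchar(seqs) != nchar(qual))
  if (length(mism) > 0) {
    abort(sprintf("FASTQ '%s': sequence/quality length mismatch at record %d",
                  path, mism[1]))
  }
  out <- tibble(read_id = sub("\\s.*$", "", sub("^@", "", hdr)),
                seq = toupper(seqs), qual = qual)
  if (!is.null(stage)) out$stage <- stage
  out
}

#' Write a read table to FASTQ
#'
#' @param reads Tibble with columns `read_id`, `seq`, `qual`.
#' @param path Output path (".gz" suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", reads$qual)), con)
  }
  invisible(path)
}

#' Write / read a mature-by-stage counts table as TSV
#'
#' The long expression table (one row per mature miRNA and stage) is
#' pivoted to a wide TSV with mature ids as the first column and one column
#' per stage. `read_counts_table()` inverts the operation, so a
#' write-then-read round trip is the identity on (`mature_id`, `stage`,
#' `count`).
#'
#' @param expr Long expression tibble with columns `mature_id`, `stage`,
#'   and `count` (see [count_matrix()]).
#' @param path Output TSV path.
#' @param value Which column to write, `"count"` or `"rpm"`.
#' @return `path` invisibly for the writer; a long tibble for the reader.
#' @export
write_counts_table <- function(expr, path, value = "count") {
  stopifnot(all(c("mature_id", "stage", value) %in% names(expr)))
  wide <- tidyr::pivot_wider(expr[, c("mature_id", "stage", value)],
                             names_from = "stage", values_from = all_of(value))
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_counts_table
#' @export
read_counts_table <- function(path, value = "count") {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(wide)[1] != "mature_id") abort(sprintf("counts table '%s' lacks a mature_id column", path))
  tidyr::pivot_longer(wide, -"mature_id", names_to = "stage", values_to = value)
}

#' Read a mature-annotation table
#'
#' Tab-separated with header `precursor_id`, `arm`, `start`, `end`.
#' Coordinates are 0-based half-open on the precursor.
#'
#' @param path TSV path.
#' @return Tibble with the four columns, validated.
#' @export
read_mature_annotations <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("precursor_id", "arm", "start", "end")
  if (!all(need %in% names(x))) {
    abort(sprintf("annotation table '%s' must have columns %s", path,
                  paste(need, collapse = ", ")))
  }
  bad <- which(!x$arm %in% c("5p", "3p"))
  if (length(bad) > 0) abort(sprintf("invalid arm '%s' at row %d of '%s'", x$arm[bad[1]], bad[1], path))
  if (any(x$end <= x$start)) abort(sprintf("empty mature interval in '%s'", path))
  as_tibble(x[need])
}

#' Read a gene annotation table (stop-codon positions)
#'
#' Tab-separated with header `gene_id`, `seq_id`, `stop_codon_pos`,
#' `strand`. `stop_codon_pos` is the 0-based position of the first base of
#' the stop codon on the forward strand of `seq_id`.
#'
#' @param path TSV path.
#' @return Validated tibble.
#' @export
read_annotation_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "seq_id", "stop_codon_pos", "strand")
  if (!all(need %in% names(x))) {
    abort(sprintf("annotation table '%s' must have columns %s", path,
                  paste(need, collapse = ", ")))
  }
  dup <- unique(x$gene_id[duplicated(x$gene_id)])
  if (length(dup) > 0) abort(sprintf("duplicate gene ids in '%s': %s", path, paste(dup, collapse = ", ")))
  if (!all(x$strand %in% c("+", "-"))) abort(sprintf("invalid strand value in '%s'", path))
  as_tibble(x[need])
}

#' Read an ortholog-pair table
#'
#' Two tab-separated columns `gene_a`, `gene_b`; duplicate pairs are
#' rejected.
#'
#' @param path TSV path.
#' @return Tibble of unique ortholog pairs.
#' @export
read_ortholog_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(x) < 2) abort(sprintf("ortholog map '%s' needs two columns", path))
  names(x)[1:2] <- c("gene_a", "gene_b")
  key <- paste(x$gene_a, x$gene_b)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate ortholog pairs in '%s': %s", path,
                  paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  as_tibble(x[, 1:2])
}

#' Validate a precursor table
#'
#' Checks the invariants of the precursor container: RNA alphabet,
#' non-empty sequences, and (when present) a balanced dot-bracket structure
#' of matching length. DNA input is converted to RNA once, with a message.
#'
#' @param precursors Tibble with columns `id`, `seq`, optional `structure`.
#' @param matures Optional mature-annotation tibble checked against
#'   precursor bounds.
#' @return The validated (possibly T->U converted) precursor tibble.
#' @export
validate_precursors <- function(precursors, matures = NULL) {
  stopifnot(all(c("id", "seq") %in% names(precursors)))
  dup <- unique(precursors$id[duplicated(precursors$id)])
  if (length(dup) > 0) abort(sprintf("duplicate precursor ids: %s", paste(dup, collapse = ", ")))
  if (any(nchar(precursors$seq) == 0)) abort("empty precursor sequence")
  had_t <- grepl("[Tt]", precursors$seq)
  if (any(had_t)) {
    inform(sprintf("converted %d precursor sequence(s) from DNA (T) to RNA (U)", sum(had_t)))
  }
  precursors$seq <- as_rna(precursors$seq)
  assert_rna(precursors$seq, "precursor sequence")
  if ("structure" %in% names(precursors)) {
    has <- !is.na(precursors$structure)
    if (any(nchar(precursors$structure[has]) != nchar(precursors$seq[has]))) {
      abort("structure length differs from sequence length")
    }
    if (any(!db_balanced(precursors$structure[has]))) {
      abort("unbalanced dot-bracket structure")
    }
  }
  if (!is.null(matures)) {
    m <- left_join(matures, precursors[, c("id", "seq")],
                   by = c(precursor_id = "id"))
    if (anyNA(m$seq)) abort("mature annotation references unknown precursor")
    if (any(m$start < 0 | m$end > nchar(m$seq))) {
      abort("mature interval outside precursor bounds")
    }
  }
  precursors
}
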