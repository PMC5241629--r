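#' Trim a 3' sequencing adapter from reads
#'
#' Finds, per read, the leftmost position at which a prefix of the adapter
#' matches with at most `floor(max_mismatch_rate * overlap)` mismatches and
#' removes the read suffix from there. Overlaps shorter than `min_overlap`
#' are considered only where the adapter prefix reaches the read's 3'
#' terminus. Reads with no hit are returned unchanged, so the operation is
#' idempotent on adapter-free sequences.
#'
#' @param reads Read tibble with columns `read_id`, `seq`, and optionally
#'   `qual` (trimmed alongside).
#' @param adapter Adapter sequence (same alphabet as the reads; DNA for
#'   FASTQ input).
#' @param min_overlap Minimum adapter-prefix length away from the terminus.
#' @param max_mismatch_rate Mismatch tolerance as a fraction of the
#'   overlap.
#' @return The read tibble with trimmed `seq`/`qual` and a logical column
#'   `trimmed`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 8,
                         max_mismatch_rate = 0.1) {
  if (nchar(adapter) < min_overlap) abort("adapter must be at least min_overlap long")
  if (nrow(reads) == 0) return(mutate(reads, trimmed = logical(0)))
  pos <- cpp_trim_positions(toupper(reads$seq), toupper(adapter),
                            as.integer(min_overlap), max_mismatch_rate)
  hit <- pos >= 0
  out <- reads
  out$seq[hit] <- substr(out$seq[hit], 1, pos[hit])
  if ("qual" %in% names(out)) out$qual[hit] <- substr(out$qual[hit], 1, pos[hit])
  out$trimmed <- hit
  out
}

#' Keep reads within a length window
#'
#' Mature miRNA reads are 19-24 nt; everything outside that window is
#' discarded after adapter trimming. Input order is preserved and a
#' histogram of discarded lengths is attached as the `"discarded"`
#' attribute.
#'
#' @param reads Read tibble with a `seq` column.
#' @param min_len,max_len Inclusive length bounds.
#' @return Filtered read tibble.
#' @export
length_filter <- function(reads, min_len = 19, max_len = 24) {
  if (min_len > max_len) abort("min_len must be <= max_len")
  len <- nchar(reads$seq)
  keep <- len >= min_len & len <= max_len
  dropped <- table(len[!keep])
  out <- reads[keep, , drop = FALSE]
  attr(out, "discarded") <- tibble(length = as.integer(names(dropped)),
                                   n = as.integer(dropped))
  out
}

#' Per-stage preprocessing summary
#'
#' @param raw,trimmed,filtered Read tibbles before trimming, after
#'   trimming, and after length filtering.
#' @return One-row tibble with read counts and the surviving-length
#'   histogram columns `len_<k>`.
#' @export
preprocess_summary <- function(raw, trimmed, filtered) {
  hist <- table(factor(nchar(filtered$seq), levels = 19:24))
  out <- tibble(input_reads = nrow(raw),
                trimmed_reads = sum(trimmed$trimmed),
                surviving_reads = nrow(filtered))
  for (k in names(hist)) out[[paste0("len_", k)]] <- as.integer(hist[[k]])
  out
}
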