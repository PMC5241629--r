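#' Map small-RNA reads to precursor hairpins
#'
#' Forward-strand, ungapped mapping: every (precursor, offset) with
#' Hamming distance at most `max_mismatch` is found, only minimum-distance
#' hits are retained per read, and multi-mapping reads are split with
#' equal fractional weights (weight = 1 / number of retained hits), so
#' downstream counts are deterministic and order-independent. Reads are
#' compared in the RNA alphabet regardless of input alphabet.
#'
#' @param reads Read tibble with `read_id`, `seq`, and optionally `stage`
#'   (carried through to the alignments).
#' @param precursors Precursor tibble with `id`, `seq`.
#' @param max_mismatch Maximum Hamming distance.
#' @return Alignment tibble with columns `read_id`, (`stage`,)
#'   `precursor_id`, `start` (0-based), `length`, `mismatches`, `weight`.
#'   Unmapped read ids are attached as the `"unmapped"` attribute.
#' @export
map_reads <- function(reads, precursors, max_mismatch = 1) {
  if (nrow(precursors) == 0) abort("precursor set is empty")
  if (nrow(reads) == 0) {
    out <- tibble(read_id = character(), precursor_id = character(),
                  start = integer(), length = integer(),
                  mismatches = integer(), weight = double())
    attr(out, "unmapped") <- character()
    return(out)
  }
  seq_rna <- as_rna(reads$seq)
  uniq <- unique(seq_rna)
  hits <- as_tibble(cpp_map_reads(uniq, as_rna(precursors$seq),
                                  as.integer(max_mismatch)))
  hits <- hits %>%
    group_by(.data$read) %>%
    filter(.data$mismatches == min(.data$mismatches)) %>%
    mutate(weight = 1 / n()) %>%
    ungroup()
  key <- tibble(read = match(seq_rna, uniq), read_id = reads$read_id,
                length = nchar(seq_rna))
  if ("stage" %in% names(reads)) key$stage <- reads$stage
  out <- left_join(key, hits, by = "read", relationship = "many-to-many") %>%
    filter(!is.na(.data$precursor)) %>%
    mutate(precursor_id = precursors$id[.data$precursor]) %>%
    select(any_of(c("read_id", "stage")), "precursor_id", "start", "length",
           "mismatches", "weight")
  attr(out, "unmapped") <- setdiff(reads$read_id, out$read_id)
  out
}
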