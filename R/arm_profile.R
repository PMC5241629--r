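#' Build a weighted coverage/start profile for one precursor
#'
#' Accumulates, per precursor position, the weighted number of read starts
#' and the weighted coverage depth from an alignment table.
#'
#' @param alignments Alignment tibble (see [map_reads()]); rows for other
#'   precursors are ignored.
#' @param precursor One-row precursor tibble (or list) with `id` and `seq`.
#' @return A `coverage_profile` object: list with `precursor_id`,
#'   `profile` (tibble pos, start_count, coverage; pos 0-based) and
#'   `starts` (tibble start, length, weight) used for peak calling.
#' @export
build_profile <- function(alignments, precursor) {
  plen <- nchar(precursor$seq)
  aln <- alignments[alignments$precursor_id == precursor$id, , drop = FALSE]
  start_count <- numeric(plen)
  coverage <- numeric(plen)
  if (nrow(aln) > 0) {
    sc <- tapply(aln$weight, factor(aln$start, levels = 0:(plen - 1)), sum)
    start_count <- as.numeric(ifelse(is.na(sc), 0, sc))
    # coverage via weighted difference array
    d <- numeric(plen + 1)
    for (i in seq_len(nrow(aln))) {
      s <- aln$start[i] + 1
      e <- min(plen, aln$start[i] + aln$length[i])
      d[s] <- d[s] + aln$weight[i]
      d[e + 1] <- d[e + 1] - aln$weight[i]
    }
    coverage <- cumsum(d)[seq_len(plen)]
  }
  structure(list(precursor_id = precursor$id,
                 profile = tibble(pos = 0:(plen - 1),
                                  start_count = start_count,
                                  coverage = coverage),
                 starts = tibble(start = aln$start, length = aln$length,
                                 weight = aln$weight)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: %d nt, %.1f weighted reads\n",
              x$precursor_id, nrow(x$profile), sum(x$starts$weight)))
  invisible(x)
}

#' Fold an RNA sequence by base-pair maximisation
#'
#' Nussinov-style dynamic program maximising the number of base pairs
#' (Watson-Crick plus G:U wobble) with a minimum hairpin loop of
#' `min_loop` unpaired nucleotides. The traceback is deterministic: each
#' position is paired with the smallest admissible partner achieving the
#' optimum. This is a topological stand-in for thermodynamic folding,
#' sufficient to localise the stem and loop of miRNA hairpins.
#'
#' @param sequence RNA string (T converted to U), length <= 500.
#' @param min_loop Minimum unpaired loop length.
#' @return Dot-bracket string of the same length.
#' @examples
#' fold_hairpin("GGGAAACCC")
#' @export
fold_hairpin <- function(sequence, min_loop = 3) {
  sequence <- as_rna(sequence)
  assert_rna(sequence, "sequence")
  if (nchar(sequence) > 500) abort("sequence longer than 500 nt")
  cpp_nussinov(sequence, as.integer(min_loop))
}

#' Split a precursor into 5' arm, loop, and 3' arm regions
#'
#' The loop is the region between the last opening and the first closing
#' bracket of the structure; the 5' region precedes it and the 3' region
#' follows it. A structure with no pair at all falls back to a midpoint
#' split, flagged in the result.
#'
#' @param precursor One-row precursor tibble with `seq` and optionally
#'   `structure`; a missing structure is computed with [fold_hairpin()].
#' @return List with 0-based half-open intervals `five`, `loop`, `three`
#'   and a logical `fallback`.
#' @export
split_arms <- function(precursor) {
  struct <- precursor$structure
  if (is.null(struct) || is.na(struct)) struct <- fold_hairpin(precursor$seq)
  n <- nchar(struct)
  ch <- strsplit(struct, "")[[1]]
  opens <- which(ch == "(")
  closes <- which(ch == ")")
  if (length(opens) == 0) {
    mid <- n %/% 2
    return(list(five = c(0L, mid), loop = c(mid, mid), three = c(mid, n),
                fallback = TRUE))
  }
  loop_start <- max(opens)           # 0-based index after last '(' = max(opens)
  loop_end <- min(closes) - 1L       # 0-based index of first ')'
  list(five = c(0L, loop_start), loop = c(loop_start, loop_end),
       three = c(loop_end, as.integer(n)), fallback = FALSE)
}

#' Call mature 5p/3p miRNAs from read-start peaks
#'
#' Per arm, the peak is the position with the maximum weighted read-start
#' count (ties break to the smallest position). The mature interval runs
#' from the peak over the modal read length among reads starting exactly
#' at the peak (modal ties break toward 22 nt, then shorter). A call is
#' emitted only when its support -- the total weight of reads starting
#' within one nucleotide of the peak -- reaches `min_support`; at most one
#' call per arm.
#'
#' @param profile A `coverage_profile` from [build_profile()].
#' @param precursor One-row precursor tibble (needs `seq`, optional
#'   `structure`).
#' @param min_support Minimum weighted read support (summed over all
#'   stages present in the alignments used to build the profile).
#' @return Tibble of mature calls: `precursor_id`, `arm`, `start`, `end`,
#'   `support` (possibly zero rows).
#' @export
call_matures <- function(profile, precursor, min_support = 10) {
  regions <- split_arms(precursor)
  sc <- profile$profile$start_count
  one_arm <- function(arm, region) {
    lo <- region[1]; hi <- region[2]           # 0-based half-open
    if (hi <= lo) return(NULL)
    idx <- (lo + 1):hi                         # 1-based into sc
    if (all(sc[idx] == 0)) return(NULL)
    peak <- lo + which.max(sc[idx]) - 1L       # 0-based; which.max ties -> first
    at_peak <- profile$starts[profile$starts$start == peak, ]
    if (nrow(at_peak) == 0) return(NULL)
    wl <- tapply(at_peak$weight, at_peak$length, sum)
    cand <- as.integer(names(wl)[wl == max(wl)])
    modal_len <- cand[order(abs(cand - 22L), cand)][1]
    win <- profile$starts$start >= peak - 1 & profile$starts$start <= peak + 1
    support <- sum(profile$starts$weight[win])
    if (support < min_support) return(NULL)
    tibble(precursor_id = profile$precursor_id, arm = arm,
           start = as.integer(peak), end = as.integer(peak + modal_len),
           support = support)
  }
  out <- bind_rows(one_arm("5p", regions$five), one_arm("3p", regions$three))
  if (nrow(out) == 0) {
    out <- tibble(precursor_id = character(), arm = character(),
                  start = integer(), end = integer(), support = double())
  }
  out
}

#' Check that a mature call lies in the hairpin stem
#'
#' @param call One-row mature-call tibble with `start`, `end`.
#' @param structure Dot-bracket string of the precursor.
#' @param min_paired_fraction Minimum fraction of mature positions that
#'   must be paired.
#' @return `TRUE` if the paired fraction over the mature interval reaches
#'   the threshold.
#' @export
stem_check <- function(call, structure, min_paired_fraction = 0.6) {
  ch <- strsplit(structure, "")[[1]]
  idx <- (call$start + 1):call$end
  mean(ch[idx] %in% c("(", ")")) >= min_paired_fraction
}

#' Flag novel mature calls against known annotations
#'
#' A call is novel unless a known mature on the same precursor overlaps it
#' reciprocally by at least 50% (overlap / call length and
#' overlap / annotation length both >= 0.5). A peak on a known precursor's
#' unannotated arm is therefore novel.
#'
#' @param calls Mature-call tibble.
#' @param known Known-annotation tibble (`precursor_id`, `arm`, `start`,
#'   `end`); may have zero rows.
#' @return `calls` with an added logical `novel` column.
#' @export
flag_novel <- function(calls, known) {
  novel <- vapply(seq_len(nrow(calls)), function(i) {
    k <- known[known$precursor_id == calls$precursor_id[i], , drop = FALSE]
    if (nrow(k) == 0) return(TRUE)
    ov <- pmax(0, pmin(calls$end[i], k$end) - pmax(calls$start[i], k$start))
    rec <- ov / (calls$end[i] - calls$start[i]) >= 0.5 & ov / (k$end - k$start) >= 0.5
    !any(rec)
  }, logical(1))
  mutate(calls, novel = novel)
}

#' Profile and call matures for a whole precursor cohort
#'
#' Convenience driver: builds per-precursor profiles (summed over all
#' stages in `alignments`), folds structures where missing, calls matures,
#' runs the stem check, and flags novelty against `known`.
#'
#' @param alignments Alignment tibble over all stages.
#' @param precursors Precursor tibble.
#' @param known Optional known-mature annotation tibble.
#' @param min_support Passed to [call_matures()].
#' @param min_paired_fraction Passed to [stem_check()].
#' @return Mature-call tibble with `support`, `novel`, `in_stem` columns.
#' @export
profile_cohort <- function(alignments, precursors, known = NULL,
                           min_support = 10, min_paired_fraction = 0.6) {
  calls <- purrr::map(seq_len(nrow(precursors)), function(i) {
    pre <- precursors[i, ]
    struct <- if ("structure" %in% names(pre) && !is.na(pre$structure)) {
      pre$structure
    } else {
      fold_hairpin(pre$seq)
    }
    pre$structure <- struct
    prof <- build_profile(alignments, pre)
    cl <- call_matures(prof, pre, min_support = min_support)
    if (nrow(cl) == 0) return(NULL)
    cl$in_stem <- vapply(seq_len(nrow(cl)), function(j) {
      stem_check(cl[j, ], struct, min_paired_fraction)
    }, logical(1))
    cl
  })
  calls <- bind_rows(calls)
  if (nrow(calls) == 0) {
    return(tibble(precursor_id = character(), arm = character(),
                  start = integer(), end = integer(), support = double(),
                  in_stem = logical(), novel = logical()))
  }
  if (is.null(known)) {
    known <- tibble(precursor_id = character(), arm = character(),
                    start = integer(), end = integer())
  }
  flag_novel(calls, known)
}
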