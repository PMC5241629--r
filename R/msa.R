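#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment under linear match/mismatch/gap scoring with a
#' deterministic traceback: on score ties, diagonal (align) is preferred
#' over up (gap in `b`) over left (gap in `a`).
#'
#' @param a,b Sequences (non-empty, length <= 100).
#' @param match,mismatch,gap Scoring parameters.
#' @return List with `aligned_a`, `aligned_b` (gap = `-`) and `score`.
#' @examples
#' global_align("ACGU", "AGU")
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (nchar(a) == 0 || nchar(b) == 0) abort("sequences must be non-empty")
  if (nchar(a) > 100 || nchar(b) > 100) abort("sequences longer than 100 nt")
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in 1:n) {
    sub <- ifelse(A[i] == B, match, mismatch)
    for (j in 1:m) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j], S[i, j + 1] + gap, S[i + 1, j] + gap)
    }
  }
  # traceback, diagonal > up > left on ties
  ra <- character(); rb <- character()
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(A[i] == B[j], match, mismatch)) {
      ra <- c(A[i], ra); rb <- c(B[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ra <- c(A[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(B[j], rb); j <- j - 1
    }
  }
  list(aligned_a = paste(ra, collapse = ""), aligned_b = paste(rb, collapse = ""),
       score = S[n + 1, m + 1])
}

#' Center-star multiple sequence alignment
#'
#' The center sequence maximises the summed pairwise alignment scores
#' against all others (ties break to input order). Every other sequence is
#' aligned to the center and merged under "once a gap, always a gap".
#' Mature miRNAs are short and near-identical, where this heuristic is
#' effectively exact and fully deterministic.
#'
#' @param seqs Character vector (optionally named) or tibble `id`, `seq`.
#' @param match,mismatch,gap Passed to [global_align()].
#' @return A `mir_msa` object: tibble `id`, `aligned`, with the center id
#'   in attribute `"center"`.
#' @export
center_star_msa <- function(seqs, match = 1, mismatch = -1, gap = -2) {
  if (is_tibble(seqs) || is.data.frame(seqs)) {
    ids <- seqs$id; ss <- seqs$seq
  } else {
    ss <- unname(seqs)
    ids <- if (!is.null(names(seqs))) names(seqs) else paste0("seq", seq_along(seqs))
  }
  k <- length(ss)
  if (k < 2) abort("need at least two sequences")
  score <- matrix(0, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    sc <- global_align(ss[i], ss[j], match, mismatch, gap)$score
    score[i, j] <- sc; score[j, i] <- sc
  }
  center <- which.max(rowSums(score))    # ties -> first by input order
  master <- strsplit(ss[center], "")[[1]]
  rows <- list()
  rows[[center]] <- master
  for (j in setdiff(seq_len(k), center)) {
    al <- global_align(ss[center], ss[j], match, mismatch, gap)
    ac <- strsplit(al$aligned_a, "")[[1]]
    as_ <- strsplit(al$aligned_b, "")[[1]]
    # merge ac (center with new gaps) into master (center with old gaps)
    mi <- 1; ai <- 1
    new_master <- character(); new_row <- character()
    grow_old <- function(x, ch) c(x, ch)
    while (mi <= length(master) || ai <= length(ac)) {
      m_gap <- mi <= length(master) && master[mi] == "-"
      a_gap <- ai <= length(ac) && ac[ai] == "-"
      if (mi <= length(master) && ai <= length(ac) && !m_gap && !a_gap) {
        new_master <- c(new_master, master[mi]); new_row <- c(new_row, as_[ai])
        mi <- mi + 1; ai <- ai + 1
      } else if (a_gap) {
        # new gap in the center: insert gap column into all previous rows
        new_master <- c(new_master, "-"); new_row <- c(new_row, as_[ai])
        pos <- length(new_master)
        rows <- lapply(rows, function(r) if (is.null(r)) r else append(r, "-", after = pos - 1))
        ai <- ai + 1
      } else { # m_gap (old gap column the new alignment doesn't have)
        new_master <- c(new_master, "-"); new_row <- c(new_row, "-")
        mi <- mi + 1
      }
    }
    master <- new_master
    rows <- lapply(rows, function(r) if (is.null(r)) r else r)
    rows[[j]] <- new_row
    # pad any earlier row that is shorter (safety; should not trigger)
    rows <- lapply(rows, function(r) {
      if (is.null(r) || length(r) == length(master)) r else c(r, rep("-", length(master) - length(r)))
    })
  }
  rows[[center]] <- master
  out <- tibble(id = ids,
                aligned = vapply(rows, paste, character(1), collapse = ""))
  structure(out, class = c("mir_msa", class(out)), center = ids[center])
}

#' Per-column conservation profile and consensus of an MSA
#'
#' Per column, the conserved fraction is the count of the modal non-gap
#' base divided by the number of sequences. The consensus letter is
#' uppercase when the fraction is exactly 1 (conserved in all sequences),
#' lowercase when >= 0.5, and `.` otherwise; modal ties break
#' alphabetically.
#'
#' @param msa A `mir_msa` (or tibble with an `aligned` column).
#' @return Tibble `position` (1-based column), `fraction`, `consensus`;
#'   the consensus string is in attribute `"consensus"`.
#' @export
conservation_profile <- function(msa) {
  mat <- do.call(rbind, strsplit(msa$aligned, ""))
  n <- nrow(mat)
  frac <- numeric(ncol(mat))
  cons <- character(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j][mat[, j] != "-"]
    if (length(col) == 0) { frac[j] <- 0; cons[j] <- "."; next }
    tab <- table(col)
    modal <- sort(names(tab)[tab == max(tab)])[1]
    frac[j] <- max(tab) / n
    cons[j] <- if (frac[j] == 1) toupper(modal) else if (frac[j] >= 0.5) tolower(modal) else "."
  }
  out <- tibble(position = seq_len(ncol(mat)), fraction = frac, consensus = cons)
  attr(out, "consensus") <- paste(cons, collapse = "")
  out
}

#' Remove gaps from an aligned row
#'
#' @param aligned Aligned sequence string(s).
#' @return Ungapped sequence(s); for any valid MSA this recovers the input
#'   sequences exactly.
#' @export
ungap <- function(aligned) {
  gsub("-", "", aligned, fixed = TRUE)
}
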