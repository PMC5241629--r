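# Independent brute-force oracles used to pin the dynamic programs.
# These deliberately share no code with the package internals.

oracle_pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")

oracle_can_pair <- function(a, b) paste0(a, b) %in% oracle_pairs

# Maximum number of non-crossing base pairs (min hairpin loop `min_loop`)
# by exhaustive recursion, no memoisation.
brute_max_pairs <- function(seq, min_loop = 3) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in seq(i + min_loop + 1, j)) {
      if (oracle_can_pair(s[i], s[k])) {
        inner <- if (k - 1 >= i + 1) rec(i + 1, k - 1) else 0
        outer <- if (k + 1 <= j) rec(k + 1, j) else 0
        best <- max(best, 1 + inner + outer)
      }
    }
    best
  }
  if (n < min_loop + 2) 0 else rec(1, n)
}

# Pair count and structural validity of a dot-bracket string.
db_pair_count <- function(db) sum(strsplit(db, "")[[1]] == "(")

db_min_loop_ok <- function(db, min_loop = 3) {
  ch <- strsplit(db, "")[[1]]
  stack <- integer()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (i - j <= min_loop) return(FALSE)
    }
  }
  length(stack) == 0
}

# Minimum duplex free energy by exhaustive enumeration of all increasing
# pair chains between the miRNA and the reversed target, mirroring the
# declared energy model (stack terms for contiguous columns, affine loop
# penalty otherwise, free ends).
brute_duplex_dg <- function(m, u, stack = nn_stack_table(),
                            loop_open = 3.5, loop_ext = 0.5, max_loop = 10) {
  mm <- strsplit(m, "")[[1]]
  ww <- rev(strsplit(u, "")[[1]])
  M <- length(mm); N <- length(ww)
  pt <- function(a, b) match(paste0(a, b), c("CG", "GC", "GU", "UG", "AU", "UA"))
  best <- 0
  extend <- function(i, r, e) {
    if (e < best) best <<- e
    if (i >= M || r >= N) return(invisible())
    for (ni in seq(i + 1, M)) {
      for (nr in seq(r + 1, N)) {
        if (is.na(pt(mm[ni], ww[nr]))) next
        gi <- ni - i - 1; gr <- nr - r - 1
        if (gi > max_loop || gr > max_loop) next
        cost <- if (gi == 0 && gr == 0) {
          stack[pt(mm[i], ww[r]), pt(ww[nr], mm[ni])]
        } else {
          loop_open + loop_ext * (gi + gr)
        }
        extend(ni, nr, e + cost)
      }
    }
  }
  for (i in seq_len(M)) for (r in seq_len(N)) {
    if (!is.na(pt(mm[i], ww[r]))) extend(i, r, 0)
  }
  best
}

# All-offsets Hamming hits of one read against a precursor table.
brute_map_one <- function(read, precursors, max_mm) {
  out <- list()
  for (p in seq_len(nrow(precursors))) {
    ps <- precursors$seq[p]
    L <- nchar(read)
    for (s in 0:(nchar(ps) - L)) {
      sub <- substr(ps, s + 1, s + L)
      mm <- sum(strsplit(read, "")[[1]] != strsplit(sub, "")[[1]])
      if (mm <= max_mm) {
        out[[length(out) + 1]] <- data.frame(precursor_id = precursors$id[p],
                                             start = s, mismatches = mm)
      }
    }
  }
  do.call(rbind, out)
}

# Dinucleotide count vector of a sequence.
dinuc_counts <- function(x) {
  n <- nchar(x)
  table(substring(x, 1:(n - 1), 2:n))
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# One standard simulated cohort shared by several expression-level tests.
small_cohort <- function(n = 6, depth = 3000, seed = 42, error_rate = 0.001,
                         stages = c("blastoderm", "gastrulation", "germ_band", "larval_body"),
                         arm_fractions = NULL, default_fraction_5p = 0.8) {
  hp <- gen_hairpins(n, seed = seed)
  st <- tibble::tibble(stage = stages, depth = depth)
  lib <- simulate_library(hp$precursors, hp$matures, st,
                          arm_fractions = arm_fractions,
                          default_fraction_5p = default_fraction_5p,
                          error_rate = error_rate, seed = seed + 1)
  trimmed <- trim_adapter(lib$reads, "TGGAATTCTCGGGTGCCAAGG")
  filtered <- length_filter(trimmed)
  aln <- map_reads(filtered, hp$precursors)
  list(hp = hp, lib = lib, aln = aln)
}
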