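#' Generate a synthetic miRNA hairpin precursor
#'
#' Builds a hairpin as 5' stem arm + loop + 3' stem arm, where the 3' arm
#' is the reverse complement of the 5' arm except at bulged positions
#' (substituted with a non-pairing base at rate `bulge_rate`). The returned
#' dot-bracket structure is the structure of the construction itself, and
#' the truth table records a 22-nt mature window inside each arm, placed a
#' couple of nucleotides in from the hairpin ends so that simulated 5'-end
#' jitter stays on the precursor.
#'
#' @param id Precursor id.
#' @param stem_len Stem length in nt (>= 22).
#' @param loop_len Loop length in nt (>= 3).
#' @param bulge_rate Per-stem-position probability of a bulged (unpaired)
#'   position.
#' @param seed Optional integer seed; the generator is a pure function of it.
#' @return A list with `precursor` (tibble: id, seq, structure, n_pairs)
#'   and `matures` (tibble: precursor_id, arm, start, end; 0-based
#'   half-open).
#' @examples
#' hp <- gen_hairpin("hp1", seed = 1)
#' hp$matures
#' @export
gen_hairpin <- function(id = "hp1", stem_len = 30, loop_len = 6,
                        bulge_rate = 0.05, seed = NULL) {
  if (stem_len < 22) abort("stem_len must be >= 22")
  if (loop_len < 3) abort("loop_len must be >= 3")
  if (bulge_rate < 0 || bulge_rate > 1) abort("bulge_rate must be in [0,1]")
  with_seed_if(seed, {
    bases <- c("A", "C", "G", "U")
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    arm5 <- sample(bases, stem_len, replace = TRUE)
    loop <- sample(bases, loop_len, replace = TRUE)
    # 3' arm: reverse complement of 5' arm; bulged positions get a base
    # that pairs with nothing (neither Watson-Crick nor G:U) opposite its
    # 5' partner.
    bulged <- runif(stem_len) < bulge_rate
    arm3 <- comp[rev(arm5)]                      # arm3[k] partners arm5[stem_len + 1 - k]
    for (k in which(rev(bulged))) {
      partner <- arm5[stem_len + 1 - k]
      ok <- bases[!vapply(bases, function(b) pairs_rna(partner, b), logical(1))]
      arm3[k] <- sample(ok, 1)
    }
    seq <- paste(c(arm5, loop, arm3), collapse = "")
    db5 <- ifelse(bulged, ".", "(")
    db3 <- rev(ifelse(bulged, ".", ")"))
    structure <- paste(c(db5, rep(".", loop_len), db3), collapse = "")
    total <- 2 * stem_len + loop_len
    off5 <- min(2L, stem_len - 22L)
    off3 <- min(4L, stem_len - 22L)
    matures <- tibble(
      precursor_id = id,
      arm = c("5p", "3p"),
      start = c(off5, total - 22L - off3),
      end = c(off5 + 22L, total - off3)
    )
    list(precursor = tibble(id = id, seq = seq, structure = structure,
                            n_pairs = sum(!bulged)),
         matures = matures)
  })
}

# Watson-Crick or G:U wobble pairing between two RNA bases.
pairs_rna <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

#' Generate a cohort of synthetic hairpins
#'
#' @param n Number of precursors.
#' @param seed Integer seed; precursor `i` uses `seed + i`.
#' @inheritParams gen_hairpin
#' @return List with `precursors` and `matures` tibbles covering the cohort.
#' @export
gen_hairpins <- function(n, stem_len = 30, loop_len = 6, bulge_rate = 0.05,
                         seed = 1) {
  ids <- sprintf("hp%03d", seq_len(n))
  out <- purrr::map2(ids, seed + seq_len(n), function(id, s) {
    gen_hairpin(id, stem_len = stem_len, loop_len = loop_len,
                bulge_rate = bulge_rate, seed = s)
  })
  list(precursors = bind_rows(purrr::map(out, "precursor")),
       matures = bind_rows(purrr::map(out, "matures")))
}

#' Default read-length weights for the simulator
#'
#' Mature miRNA reads are 19-24 nt with a strong mode at the canonical
#' 22 nt; the weights below emulate that length jitter.
#' @return Named numeric vector over lengths 19..24 summing to 1.
#' @export
default_length_weights <- function() {
  c(`19` = 0.02, `20` = 0.05, `21` = 0.15, `22` = 0.55, `23` = 0.15, `24` = 0.08)
}

#' Simulate stage-wise small-RNA read libraries from hairpin precursors
#'
#' Emulates Dicer/Drosha processing read pileups: each read is a mature-arm
#' subsequence with 5'-start jitter, length drawn from 19-24 nt, optional
#' substitution errors, and a 3' sequencing adapter appended before the
#' read is truncated to the sequencer read length. Reads are emitted in the
#' DNA alphabet with flat qualities. A truth row records every read's
#' origin.
#'
#' @param precursors,matures Output of [gen_hairpins()] (or equivalent
#'   tables).
#' @param stages Tibble with columns `stage` and `depth` (total reads per
#'   stage, split evenly across precursors up to rounding).
#' @param arm_fractions Optional tibble `precursor_id`, `stage`,
#'   `fraction_5p`; missing combinations use `default_fraction_5p`.
#' @param default_fraction_5p 5p arm fraction used where `arm_fractions`
#'   has no entry.
#' @param error_rate Per-base substitution error probability.
#' @param adapter 3' adapter, DNA alphabet.
#' @param read_cycles Sequencer read length in nt.
#' @param jitter_weights Named weights over 5'-start offsets -1, 0, +1.
#' @param length_weights Named weights over insert lengths 19..24.
#' @param seed Optional integer seed.
#' @return List with `reads` (read_id, stage, seq, qual) and `truth`
#'   (read_id, stage, precursor_id, arm, start, insert_len, n_errors).
#' @export
simulate_library <- function(precursors, matures, stages,
                             arm_fractions = NULL, default_fraction_5p = 0.8,
                             error_rate = 0.001,
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             read_cycles = 36,
                             jitter_weights = c(`-1` = 0.15, `0` = 0.7, `1` = 0.15),
                             length_weights = default_length_weights(),
                             seed = NULL) {
  if (grepl("[^ACGTacgt]", adapter)) abort("adapter must be a DNA string (ACGT)")
  if (any(stages$depth <= 0)) abort("stage depth must be > 0")
  grid <- tidyr::expand_grid(stage = stages$stage, precursor_id = precursors$id)
  if (!is.null(arm_fractions)) {
    bad <- setdiff(arm_fractions$precursor_id, precursors$id)
    if (length(bad) > 0) abort(sprintf("arm_fractions references unknown precursor: %s", bad[1]))
    bad_st <- setdiff(arm_fractions$stage, stages$stage)
    if (length(bad_st) > 0) abort(sprintf("arm_fractions references unknown stage: %s", bad_st[1]))
    grid <- left_join(grid, arm_fractions, by = c("precursor_id", "stage"))
  } else {
    grid$fraction_5p <- NA_real_
  }
  grid$fraction_5p[is.na(grid$fraction_5p)] <- default_fraction_5p
  if (any(grid$fraction_5p < 0 | grid$fraction_5p > 1)) abort("fraction_5p must be in [0,1]")
  grid <- left_join(grid, stages, by = "stage")
  npre <- nrow(precursors)
  pre_seq <- setNames(precursors$seq, precursors$id)
  m5 <- matures[matures$arm == "5p", ]
  m3 <- matures[matures$arm == "3p", ]
  start5 <- setNames(m5$start, m5$precursor_id)
  start3 <- setNames(m3$start, m3$precursor_id)
  adapter_rna <- as_rna(adapter)
  lens <- as.integer(names(length_weights))
  jits <- as.integer(names(jitter_weights))

  with_seed_if(seed, {
    out <- purrr::pmap(grid, function(stage, precursor_id, fraction_5p, depth) {
      n <- depth %/% npre + as.integer(match(precursor_id, precursors$id) <=
                                         depth %% npre)
      if (n == 0) return(NULL)
      pseq <- pre_seq[[precursor_id]]
      plen <- nchar(pseq)
      arm <- ifelse(runif(n) < fraction_5p, "5p", "3p")
      base_start <- ifelse(arm == "5p", start5[[precursor_id]], start3[[precursor_id]])
      jit <- sample(jits, n, replace = TRUE, prob = jitter_weights)
      len <- sample(lens, n, replace = TRUE, prob = length_weights)
      start <- pmax(0L, pmin(base_start + jit, plen - len))
      insert <- as_rna(substring(pseq, start + 1, start + len))
      full <- substr(paste0(insert, adapter_rna), 1, read_cycles)
      # substitution errors across the sequenced read
      n_err <- rbinom(n, nchar(full), error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(nchar(full[i]), n_err[i])
        ch <- strsplit(full[i], "")[[1]]
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1)
        full[i] <- paste(ch, collapse = "")
      }
      tibble(stage = stage, precursor_id = precursor_id, arm = arm,
             start = start, insert_len = len, n_errors = n_err, seq = full)
    })
    res <- bind_rows(out)
    res$read_id <- sprintf("%s_r%06d", res$stage, stats::ave(seq_len(nrow(res)),
                                                             res$stage, FUN = seq_along))
    reads <- tibble(read_id = res$read_id, stage = res$stage,
                    seq = as_dna(res$seq),
                    qual = strrep("I", nchar(res$seq)))
    truth <- res[, c("read_id", "stage", "precursor_id", "arm", "start",
                     "insert_len", "n_errors")]
    list(reads = reads, truth = as_tibble(truth))
  })
}

#' Plant an arm-switching event in an arm-fraction table
#'
#' Sets the 5p fraction of one precursor high (> 0.5) in one disjoint set
#' of stages and low (< 0.5) in another, so the simulated dominance
#' alternates between arms across development.
#'
#' @param arm_fractions Tibble `precursor_id`, `stage`, `fraction_5p` (may
#'   be empty; rows are added or replaced).
#' @param precursor_id Precursor to modify.
#' @param stages_5p_dominant,stages_3p_dominant Disjoint stage sets.
#' @param high,low 5p fractions used in the two sets.
#' @return Updated `arm_fractions` tibble.
#' @export
plant_arm_switch <- function(arm_fractions, precursor_id,
                             stages_5p_dominant, stages_3p_dominant,
                             high = 0.9, low = 0.1) {
  if (length(intersect(stages_5p_dominant, stages_3p_dominant)) > 0) {
    abort("dominant stage sets must be disjoint")
  }
  if (high <= 0.5 || low >= 0.5) abort("high must be > 0.5 and low < 0.5")
  add <- tibble(
    precursor_id = precursor_id,
    stage = c(stages_5p_dominant, stages_3p_dominant),
    fraction_5p = rep(c(high, low), c(length(stages_5p_dominant), length(stages_3p_dominant)))
  )
  keep <- !(arm_fractions$precursor_id == precursor_id &
              arm_fractions$stage %in% add$stage)
  bind_rows(arm_fractions[keep, ], add)
}

#' True arm-switching flags implied by an arm-fraction table
#'
#' A precursor truly switches when its planted 5p fraction is above 0.5 in
#' at least one stage and below 0.5 in at least one other; stages at
#' exactly 0.5 (a tie) are excluded from dominance, mirroring the
#' detection rules of [arm_dominance()].
#'
#' @param arm_fractions Tibble `precursor_id`, `stage`, `fraction_5p`
#'   covering every simulated stage (use the expanded grid with defaults
#'   filled in).
#' @return Tibble `precursor_id`, `switching`.
#' @export
truth_switch_flags <- function(arm_fractions) {
  arm_fractions %>%
    group_by(.data$precursor_id) %>%
    summarise(switching = any(.data$fraction_5p > 0.5) & any(.data$fraction_5p < 0.5),
              .groups = "drop")
}

#' Generate a 3'UTR with planted miRNA regulatory elements
#'
#' Plants non-overlapping target sites of the requested pairing classes in
#' a uniform-random RNA background. Every planted site starts from the
#' full reverse complement of the miRNA -- an idealised site whose planted
#' register is the thermodynamic optimum -- and the seed (positions 2-8)
#' and 3' (positions 13-19) regions are then edited per class:
#'
#' * `canonical`: seed region perfectly Watson-Crick complementary.
#' * `gu_seed`: seed fully paired with at least one G:U wobble.
#' * `compensatory`: >= 1 seed mismatch, 3' region (13-19) perfect.
#' * `seedless`: neither seed nor 3' region complementary.
#'
#' @param mirna miRNA sequence, RNA alphabet, 19-24 nt.
#' @param n_sites Number of sites to plant.
#' @param classes Character vector of classes (recycled over sites).
#' @param utr_len UTR length in nt (>= 30 * n_sites).
#' @param gene_id Id for the generated UTR.
#' @param seed Optional integer seed.
#' @return List with `utr` (tibble id, seq) and `truth` (tibble gene_id,
#'   class, start, end; 0-based half-open site intervals).
#' @export
gen_utr_with_mres <- function(mirna, n_sites = 1, classes = "canonical",
                              utr_len = 1000, gene_id = "gene1", seed = NULL) {
  mirna <- as_rna(mirna)
  assert_rna(mirna, "miRNA")
  if (length(classes) == 0) abort("classes must be non-empty")
  bad <- setdiff(classes, c("canonical", "gu_seed", "compensatory", "seedless"))
  if (length(bad) > 0) abort(sprintf("unknown MRE class: %s", bad[1]))
  if (n_sites > 0 && utr_len < 30 * n_sites) abort("utr_len must be >= 30 * n_sites")
  L <- nchar(mirna)
  with_seed_if(seed, {
    bases <- c("A", "C", "G", "U")
    utr <- sample(bases, utr_len, replace = TRUE)
    truth <- tibble(gene_id = character(), class = character(),
                    start = integer(), end = integer())
    if (n_sites > 0) {
      cls <- rep_len(classes, n_sites)
      site_seqs <- vapply(cls, function(cl) mre_site_seq(mirna, cl), character(1))
      slen <- nchar(site_seqs[1])
      # non-overlapping placement on a regular grid with random offsets
      pitch <- utr_len %/% n_sites
      starts <- (seq_len(n_sites) - 1L) * pitch +
        sample.int(max(1L, pitch - slen), n_sites, replace = TRUE) - 1L
      for (i in seq_len(n_sites)) {
        s <- starts[i]
        utr[(s + 1):(s + slen)] <- strsplit(site_seqs[i], "")[[1]]
      }
      truth <- tibble(gene_id = gene_id, class = cls, start = starts,
                      end = starts + slen)
    }
    list(utr = tibble(id = gene_id, seq = paste(utr, collapse = "")),
         truth = truth)
  })
}

# Construct one planted target-site sequence (UTR sense, 5'->3') for a
# miRNA and pairing class. Base template: reverse complement of the whole
# miRNA (an idealised, fully pairing site whose planted register is the
# duplex MFE); class-specific edits follow.
mre_site_seq <- function(mirna, class) {
  L <- nchar(mirna)
  m <- strsplit(mirna, "")[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  partner <- comp[m]                 # partner[i] pairs miRNA position i
  nonpair <- function(b) sample(setdiff(c("A", "C", "G", "U"),
                                        c(comp[b], if (b == "G") "U", if (b == "U") "G")), 1)
  if (class == "gu_seed") {
    # one seed position becomes a G:U wobble partner; G:U exists for
    # miRNA G (partner U) and miRNA U (partner G)
    cand <- which(m[2:8] %in% c("G", "U")) + 1
    if (length(cand) == 0) abort("gu_seed class needs a G or U in the miRNA seed")
    i <- cand[sample.int(length(cand), 1)]
    partner[i] <- if (m[i] == "G") "U" else "G"
  } else if (class == "compensatory") {
    i <- sample(2:8, 1)
    partner[i] <- nonpair(m[i])
  } else if (class == "seedless") {
    for (i in 2:8) partner[i] <- nonpair(m[i])
    for (i in sample(13:19, 3)) partner[i] <- nonpair(m[i])
  }
  # UTR site read 5'->3' pairs the miRNA antiparallel
  paste(rev(partner), collapse = "")
}
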