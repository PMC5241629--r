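#' Nearest-neighbor RNA/RNA stacking free-energy table (37 C)
#'
#' The published Watson-Crick and G:U wobble stacking free energies
#' (kcal/mol at 37 C; Turner-style parameter set) over the six pair types
#' CG, GC, GU, UG, AU, UA. Entry `[p1, p2]` is the free-energy increment
#' of the stack 5'-ac-3' / 3'-bd-5' with `p1 = type(a, b)` and
#' `p2 = type(d, c)`. This table is the versioned parameter set of the
#' duplex model; [duplex_energy()] sums its terms over contiguous paired
#' columns.
#'
#' @return A 6x6 numeric matrix with dimnames over the pair types.
#' @export
nn_stack_table <- function() {
  pt <- c("CG", "GC", "GU", "UG", "AU", "UA")
  matrix(c(
    -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,  # CG
    -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,  # GC
    -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,  # GU
    -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,  # UG
    -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,  # AU
    -2.10, -2.40, -1.30, -1.00, -0.90, -1.30   # UA
  ), nrow = 6, byrow = TRUE, dimnames = list(pt, pt))
}

#' Extract 3'UTR sequences downstream of stop codons
#'
#' For a + strand gene the UTR is the `utr_len` window starting 3 nt after
#' the stop codon's first base, `[stop + 3, stop + 3 + utr_len)`, clipped
#' at the sequence end. For a - strand gene the corresponding window is
#' upstream on the forward strand, `[stop - utr_len, stop)`, returned as
#' its reverse complement. UTRs are emitted as RNA. Genes whose stop
#' position falls outside the sequence are skipped with a warning.
#'
#' @param sequences Tibble `id`, `seq` of genomic/transcript sequences.
#' @param annotation Tibble `gene_id`, `seq_id`, `stop_codon_pos`
#'   (0-based, first base of the stop codon on the forward strand),
#'   `strand`.
#' @param utr_len UTR length in nt.
#' @return Tibble `gene_id`, `seq` (RNA), `clipped` (logical: shorter than
#'   `utr_len`).
#' @export
extract_utr <- function(sequences, annotation, utr_len = 1000) {
  seqs <- setNames(as_rna(sequences$seq), sequences$id)
  out <- purrr::pmap(annotation, function(gene_id, seq_id, stop_codon_pos, strand, ...) {
    s <- seqs[[seq_id]]
    if (is.null(s)) {
      warn(sprintf("gene %s: unknown sequence %s; skipped", gene_id, seq_id))
      return(NULL)
    }
    n <- nchar(s)
    if (stop_codon_pos < 0 || stop_codon_pos >= n) {
      warn(sprintf("gene %s: stop codon position %d outside sequence; skipped",
                   gene_id, stop_codon_pos))
      return(NULL)
    }
    if (strand == "+") {
      from <- stop_codon_pos + 3
      to <- min(n, from + utr_len)
      if (from >= to) {
        warn(sprintf("gene %s: empty UTR window; skipped", gene_id))
        return(NULL)
      }
      utr <- substr(s, from + 1, to)
    } else {
      to <- stop_codon_pos
      from <- max(0, to - utr_len)
      if (from >= to) {
        warn(sprintf("gene %s: empty UTR window; skipped", gene_id))
        return(NULL)
      }
      utr <- revcomp_rna(substr(s, from + 1, to))
    }
    tibble(gene_id = gene_id, seq = utr, clipped = nchar(utr) < utr_len)
  })
  bind_rows(out)
}

# Allowed UTR partner characters for one miRNA base (Watson-Crick, plus
# G:U wobble when gu = TRUE).
utr_partner_class <- function(base, gu = FALSE) {
  wc <- c(A = "U", C = "G", G = "C", U = "A")[[base]]
  if (gu && base == "G") return("[CU]")
  if (gu && base == "U") return("[AG]")
  wc
}

#' Scan a UTR for candidate miRNA binding-site anchors
#'
#' Anchors are UTR positions matching the reverse complement of the miRNA
#' seed region (positions 2-8 from the 5' end; Watson-Crick, optionally
#' with G:U wobble) or of its 3'-compensatory region (positions 13-19,
#' Watson-Crick). Overlapping matches are all reported.
#'
#' @param mirna miRNA sequence, 19-24 nt RNA.
#' @param utr UTR sequence (RNA string).
#' @param allow_gu_seed Allow G:U wobble in seed anchors.
#' @param seed_span,comp_span 1-based inclusive miRNA position spans.
#' @return Tibble `anchor_start` (0-based UTR position of the 7-mer
#'   match), `anchor_type` (`"seed"` or `"compensatory"`).
#' @export
scan_sites <- function(mirna, utr, allow_gu_seed = TRUE,
                       seed_span = c(2, 8), comp_span = c(13, 19)) {
  mirna <- as_rna(mirna)
  if (nchar(mirna) < 19) abort("miRNA shorter than 19 nt")
  if (nchar(mirna) > 24) abort("miRNA longer than 24 nt")
  utr <- as_rna(utr)
  anchor_scan <- function(span, gu) {
    m <- strsplit(substr(mirna, span[1], span[2]), "")[[1]]
    # UTR site 5'->3' pairs the miRNA antiparallel: reverse the span
    pat <- paste(vapply(rev(m), utr_partner_class, character(1), gu = gu),
                 collapse = "")
    hits <- gregexpr(paste0("(?=", pat, ")"), utr, perl = TRUE)[[1]]
    if (hits[1] == -1) integer() else as.integer(hits) - 1L
  }
  seed_hits <- anchor_scan(seed_span, allow_gu_seed)
  comp_hits <- anchor_scan(comp_span, FALSE)
  bind_rows(
    tibble(anchor_start = seed_hits, anchor_type = "seed"),
    tibble(anchor_start = comp_hits, anchor_type = "compensatory")
  )
}

#' Minimum free energy of an intermolecular miRNA:target duplex
#'
#' Dynamic program over nearest-neighbor stacking free energies
#' ([nn_stack_table()]) for the hybridisation of a miRNA with a short
#' target window, with no intramolecular structure. Contiguous paired
#' columns contribute stack terms; interruptions (bulges/internal loops)
#' pay an affine penalty of `loop_open + loop_ext` per unpaired
#' nucleotide; dangling ends are free. The traceback is deterministic
#' (stacked continuations preferred, then smaller loops).
#'
#' @param mirna miRNA sequence 5'->3' (RNA).
#' @param utr_window Target window 5'->3' (RNA), length <= 40.
#' @param loop_open,loop_ext Affine internal loop/bulge penalty
#'   (kcal/mol; per-loop and per-unpaired-nt).
#' @param max_loop Maximum unpaired stretch per strand inside the duplex.
#' @return List with `delta_g` (kcal/mol, <= 0), `pairing` (string over
#'   `|` Watson-Crick, `:` G:U, space = unpaired, aligned to the miRNA
#'   5'->3'), and `site_start`/`site_end` (0-based half-open paired span
#'   on the window).
#' @export
duplex_energy <- function(mirna, utr_window, loop_open = 3.5, loop_ext = 0.5,
                          max_loop = 10) {
  mirna <- as_rna(mirna); utr_window <- as_rna(utr_window)
  assert_rna(mirna, "miRNA"); assert_rna(utr_window, "target window")
  if (nchar(utr_window) > 40) abort("target window longer than 40 nt")
  cpp_duplex(mirna, utr_window, nn_stack_table(), loop_open, loop_ext,
             as.integer(max_loop))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: the sequence is viewed as an Eulerian walk
#' on the graph of dinucleotide transitions and a uniformly random new
#' walk with identical edge multiset is drawn, so all dinucleotide (and
#' hence mononucleotide) counts are preserved exactly.
#'
#' @param seq Sequence string.
#' @param seed Optional integer seed.
#' @return Shuffled string with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  n <- nchar(seq)
  if (n <= 2) return(seq)
  with_seed_if(seed, {
    ch <- strsplit(seq, "")[[1]]
    verts <- unique(ch)
    from <- ch[-n]; to <- ch[-1]
    last <- ch[n]; first <- ch[1]
    edges <- split(to, factor(from, levels = verts))
    repeat {
      # pick a random terminal edge for every vertex except the walk's end
      last_edge <- vapply(verts, function(v) {
        if (v == last || length(edges[[v]]) == 0) NA_character_
        else edges[[v]][sample.int(length(edges[[v]]), 1)]
      }, character(1))
      # the chosen terminal edges must form paths leading to `last`
      ok <- TRUE
      for (v in verts) {
        if (v == last || length(edges[[v]]) == 0) next
        cur <- v; steps <- 0
        while (cur != last && steps <= length(verts)) {
          cur <- last_edge[[cur]]
          steps <- steps + 1
          if (is.na(cur) || length(edges[[cur]]) == 0 && cur != last) break
        }
        if (is.na(cur) || cur != last) { ok <- FALSE; break }
      }
      if (ok) break
    }
    # random order for the remaining edges, terminal edge last
    ordered <- lapply(verts, function(v) {
      e <- edges[[v]]
      if (length(e) == 0) return(e)
      if (v != last) {
        drop <- match(last_edge[[v]], e)
        rest <- e[-drop]
        c(if (length(rest) > 0) rest[sample.int(length(rest))], e[drop])
      } else {
        e[sample.int(length(e))]
      }
    })
    names(ordered) <- verts
    used <- setNames(integer(length(verts)), verts)
    out <- character(n)
    out[1] <- first
    cur <- first
    for (i in 2:n) {
      used[[cur]] <- used[[cur]] + 1L
      nxt <- ordered[[cur]][used[[cur]]]
      out[i] <- nxt
      cur <- nxt
    }
    paste(out, collapse = "")
  })
}

#' Empirical p-value of a duplex hit by dinucleotide shuffling
#'
#' The UTR is shuffled `n_shuffles` times preserving dinucleotide counts;
#' for each shuffle the best (lowest) duplex energy of the same miRNA over
#' all candidate anchors is recorded (0 when the shuffle has no anchor).
#' p = (1 + #{shuffle best <= hit energy}) / (n_shuffles + 1).
#'
#' @param hit_delta_g Free energy of the observed hit (kcal/mol).
#' @param mirna miRNA sequence.
#' @param utr Full UTR sequence the hit came from.
#' @param n_shuffles Number of shuffles (>= 19, so that p < 0.05 is
#'   resolvable).
#' @param seed Optional integer seed.
#' @param null_energies Optional precomputed vector of shuffle best
#'   energies (used by [predict_targets()] to share shuffles across hits
#'   on one UTR); when given, shuffling is skipped.
#' @inheritParams scan_sites
#' @return p-value in (0, 1].
#' @export
site_pvalue <- function(hit_delta_g, mirna, utr, n_shuffles = 100,
                        seed = NULL, allow_gu_seed = TRUE,
                        null_energies = NULL) {
  if (is.null(null_energies)) {
    if (n_shuffles < 19) abort("n_shuffles must be >= 19 to resolve p < 0.05")
    null_energies <- shuffle_null_energies(mirna, utr, n_shuffles, seed,
                                           allow_gu_seed = allow_gu_seed)
  }
  (1 + sum(null_energies <= hit_delta_g)) / (length(null_energies) + 1)
}

# Best duplex energy per dinucleotide shuffle of `utr`.
shuffle_null_energies <- function(mirna, utr, n_shuffles, seed = NULL,
                                  allow_gu_seed = TRUE) {
  seeds <- if (is.null(seed)) rep(list(NULL), n_shuffles) else as.list(seed + seq_len(n_shuffles))
  vapply(seeds, function(s) {
    sh <- dinucleotide_shuffle(utr, seed = s)
    anchors <- scan_sites(mirna, sh, allow_gu_seed = allow_gu_seed)
    if (nrow(anchors) == 0) return(0)
    min(vapply(seq_len(nrow(anchors)), function(i) {
      w <- anchor_window(anchors$anchor_start[i], anchors$anchor_type[i],
                         nchar(mirna), nchar(sh))
      duplex_energy(mirna, substr(sh, w[1] + 1, w[2]))$delta_g
    }, numeric(1)))
  }, numeric(1))
}

# Energy window (0-based half-open) around an anchor. The window spans the
# region the rest of the miRNA can reach given which miRNA span the anchor
# matches, plus `pad` nt on each side for bulges; total width is about
# miRNA length + 2 * pad.
anchor_window <- function(anchor_start, anchor_type, mirna_len, utr_len,
                          pad = 4, seed_span = c(2, 8), comp_span = c(13, 19)) {
  span <- if (anchor_type == "seed") seed_span else comp_span
  # UTR positions increase toward the miRNA 5' end: the anchor's last base
  # pairs miRNA position span[1]; downstream of it sit positions < span[1],
  # upstream of the anchor sit positions > span[2].
  lo <- anchor_start - (mirna_len - span[2]) - pad
  hi <- anchor_start + 7 + (span[1] - 1) + pad
  c(max(0L, as.integer(lo)), min(as.integer(utr_len), as.integer(hi)))
}

#' Classify the seed-pairing class of a duplex hit
#'
#' From the pairing string (aligned to the miRNA 5'->3'): `canonical` if
#' seed positions 2-8 are all Watson-Crick; `gu_seed` if all seven are
#' paired with at least one G:U; `compensatory` if the seed has >= 1
#' unpaired/mismatched position while positions 13-19 are all paired;
#' otherwise `seedless`.
#'
#' @param pairing Pairing string from [duplex_energy()].
#' @param seed_span,comp_span 1-based inclusive miRNA spans.
#' @return One of `"canonical"`, `"gu_seed"`, `"compensatory"`,
#'   `"seedless"`.
#' @export
classify_seed <- function(pairing, seed_span = c(2, 8), comp_span = c(13, 19)) {
  ch <- strsplit(pairing, "")[[1]]
  seed <- ch[seed_span[1]:seed_span[2]]
  comp <- ch[comp_span[1]:comp_span[2]]
  if (all(seed == "|")) return("canonical")
  if (all(seed %in% c("|", ":")) && any(seed == ":")) return("gu_seed")
  if (any(!seed %in% c("|", ":")) && all(comp %in% c("|", ":"))) return("compensatory")
  "seedless"
}

#' Filter duplex hits on free energy and p-value
#'
#' Both thresholds are strict: a hit survives iff `delta_g < dg_max` and
#' `p_value < p_max`, so a hit at exactly -20 kcal/mol or exactly p = 0.05
#' is removed.
#'
#' @param hits Hit tibble with `delta_g` and `p_value` columns.
#' @param dg_max Free-energy cutoff (kcal/mol).
#' @param p_max p-value cutoff.
#' @return Filtered hit tibble.
#' @export
filter_hits <- function(hits, dg_max = -20.0, p_max = 0.05) {
  hits[hits$delta_g < dg_max & hits$p_value < p_max, , drop = FALSE]
}

#' Predict miRNA regulatory elements across miRNAs and UTRs
#'
#' Full target scan: candidate anchors ([scan_sites()]) are expanded to
#' energy windows, scored with [duplex_energy()], collapsed so that
#' overlapping windows on one UTR keep only their best-energy hit,
#' seed-classified, and assigned empirical dinucleotide-shuffle p-values
#' (shuffle nulls are shared across hits of one miRNA/UTR pair). With
#' `filter = TRUE` the strict dG/p filters of [filter_hits()] are applied.
#'
#' @param mirnas Tibble `id`, `seq` of mature miRNAs.
#' @param utrs Tibble `gene_id` (or `id`), `seq` of UTRs.
#' @param dg_max,p_max Strict filter thresholds.
#' @param n_shuffles Shuffles per UTR for the empirical null.
#' @param seed Integer seed for the shuffles.
#' @param allow_gu_seed Allow G:U wobble in seed anchors.
#' @param compute_pvalues Set `FALSE` to skip the shuffle null (p_value =
#'   NA) for speed.
#' @param filter Apply [filter_hits()] to the result.
#' @return Hit tibble: `mirna_id`, `gene_id`, `start`, `end` (0-based
#'   half-open paired span on the UTR), `delta_g`, `pairing`,
#'   `seed_class`, `p_value`.
#' @export
predict_targets <- function(mirnas, utrs, dg_max = -20.0, p_max = 0.05,
                            n_shuffles = 100, seed = NULL,
                            allow_gu_seed = TRUE, compute_pvalues = TRUE,
                            filter = TRUE) {
  if (!"gene_id" %in% names(utrs) && "id" %in% names(utrs)) {
    utrs <- rename(utrs, gene_id = "id")
  }
  combos <- tidyr::expand_grid(mi = seq_len(nrow(mirnas)), ui = seq_len(nrow(utrs)))
  hits <- purrr::pmap(combos, function(mi, ui) {
    m <- as_rna(mirnas$seq[mi]); u <- as_rna(utrs$seq[ui])
    anchors <- scan_sites(m, u, allow_gu_seed = allow_gu_seed)
    if (nrow(anchors) == 0) return(NULL)
    cand <- purrr::map(seq_len(nrow(anchors)), function(i) {
      w <- anchor_window(anchors$anchor_start[i], anchors$anchor_type[i],
                         nchar(m), nchar(u))
      dx <- duplex_energy(m, substr(u, w[1] + 1, w[2]))
      if (dx$n_pairs == 0) return(NULL)
      tibble(mirna_id = mirnas$id[mi], gene_id = utrs$gene_id[ui],
             start = w[1] + dx$site_start, end = w[1] + dx$site_end,
             delta_g = dx$delta_g, pairing = dx$pairing)
    })
    cand <- bind_rows(cand)
    if (nrow(cand) == 0) return(NULL)
    # collapse hits whose paired spans overlap: keep the best energy
    cand <- arrange(cand, .data$start, .data$delta_g)
    grp <- integer(nrow(cand)); g <- 0L; right <- -1L
    for (i in seq_len(nrow(cand))) {
      if (cand$start[i] >= right) g <- g + 1L
      right <- max(right, cand$end[i])
      grp[i] <- g
    }
    cand$grp <- grp
    cand <- cand %>% group_by(.data$grp) %>%
      slice(which.min(.data$delta_g)) %>% ungroup() %>% select(-"grp")
    cand$seed_class <- vapply(cand$pairing, classify_seed, character(1),
                              USE.NAMES = FALSE)
    if (compute_pvalues) {
      null_e <- shuffle_null_energies(m, u, n_shuffles,
                                      seed = if (is.null(seed)) NULL else seed + 1000L * mi + ui,
                                      allow_gu_seed = allow_gu_seed)
      cand$p_value <- vapply(cand$delta_g, site_pvalue, numeric(1),
                             mirna = m, utr = u, null_energies = null_e)
    } else {
      cand$p_value <- NA_real_
    }
    cand
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0) {
    hits <- tibble(mirna_id = character(), gene_id = character(),
                   start = integer(), end = integer(), delta_g = double(),
                   pairing = character(), seed_class = character(),
                   p_value = double())
  }
  if (filter && nrow(hits) > 0) hits <- filter_hits(hits, dg_max, p_max)
  hits
}

#' Build a cross-species conserved miRNA-target network
#'
#' Edges come from the species-A hit set (one edge per miRNA/gene pair,
#' keeping the best-energy hit). An edge (m, gA) is conserved iff `m` is a
#' shared miRNA and some ortholog gB of gA is also hit by `m` in species
#' B. Non-conserved edges are retained but flagged.
#'
#' @param hits_a,hits_b Filtered hit tibbles for the two species.
#' @param ortholog_map Tibble `gene_a`, `gene_b`.
#' @param shared_mirnas miRNA ids present in both species; defaults to the
#'   ids occurring in both hit sets.
#' @param genes_a,genes_b Optional known gene universes; ortholog pairs
#'   referencing unknown genes are dropped with a warning.
#' @return A `target_network` object: list with `edges` tibble
#'   (`mirna_id`, `gene_id`, `conserved`, `delta_g`, `p_value`,
#'   `seed_class`).
#' @export
conserved_network <- function(hits_a, hits_b, ortholog_map,
                              shared_mirnas = NULL,
                              genes_a = NULL, genes_b = NULL) {
  if (is.null(shared_mirnas)) {
    shared_mirnas <- intersect(unique(hits_a$mirna_id), unique(hits_b$mirna_id))
  }
  if (!is.null(genes_a) || !is.null(genes_b)) {
    bad <- rep(FALSE, nrow(ortholog_map))
    if (!is.null(genes_a)) bad <- bad | !ortholog_map$gene_a %in% genes_a
    if (!is.null(genes_b)) bad <- bad | !ortholog_map$gene_b %in% genes_b
    if (any(bad)) {
      warn(sprintf("%d ortholog pair(s) reference unknown genes; ignored", sum(bad)))
      ortholog_map <- ortholog_map[!bad, , drop = FALSE]
    }
  }
  edges <- hits_a %>%
    group_by(.data$mirna_id, .data$gene_id) %>%
    slice(which.min(.data$delta_g)) %>%
    ungroup()
  b_key <- paste(hits_b$mirna_id, hits_b$gene_id)
  conserved <- vapply(seq_len(nrow(edges)), function(i) {
    m <- edges$mirna_id[i]
    if (!m %in% shared_mirnas) return(FALSE)
    gb <- ortholog_map$gene_b[ortholog_map$gene_a == edges$gene_id[i]]
    any(paste(m, gb) %in% b_key)
  }, logical(1))
  edges$conserved <- conserved
  edges <- select(edges, "mirna_id", "gene_id", "conserved",
                  any_of(c("delta_g", "p_value", "seed_class", "start", "end")))
  structure(list(edges = edges), class = "target_network")
}

#' @export
print.target_network <- function(x, ...) {
  cat(sprintf("<target_network> %d edges (%d conserved) over %d miRNA(s), %d gene(s)\n",
              nrow(x$edges), sum(x$edges$conserved),
              length(unique(x$edges$mirna_id)), length(unique(x$edges$gene_id))))
  invisible(x)
}

#' Per-miRNA degree statistics of a conserved target network
#'
#' Counts conserved targets per miRNA and summarises them: mean, sample SD
#' (n - 1 denominator; 0 with `sd_defined = FALSE` for a single miRNA),
#' min/max and the miRNAs attaining them.
#'
#' @param network A `target_network`.
#' @return List with `degrees` (tibble `mirna_id`, `n_targets`) and
#'   `summary` (one-row tibble `mean`, `sd`, `min`, `max`, `argmax`,
#'   `argmin`, `sd_defined`).
#' @export
degree_stats <- function(network) {
  edges <- network$edges[network$edges$conserved, , drop = FALSE]
  if (nrow(edges) == 0) {
    return(list(degrees = tibble(mirna_id = character(), n_targets = integer()),
                summary = tibble(mean = 0, sd = 0, min = 0, max = 0,
                                 argmax = NA_character_, argmin = NA_character_,
                                 sd_defined = FALSE)))
  }
  deg <- edges %>% count(.data$mirna_id, name = "n_targets") %>%
    arrange(.data$mirna_id)
  s <- if (nrow(deg) > 1) sd(deg$n_targets) else 0
  list(degrees = deg,
       summary = tibble(mean = mean(deg$n_targets), sd = s,
                        min = min(deg$n_targets), max = max(deg$n_targets),
                        argmax = deg$mirna_id[which.max(deg$n_targets)],
                        argmin = deg$mirna_id[which.min(deg$n_targets)],
                        sd_defined = nrow(deg) > 1))
}
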