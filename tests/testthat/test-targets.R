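mir34 <- "UGGCAGUGUGGUUAGCUGGUUG"  # miR-34-5p-like mature, 22 nt

test_that("UTR extraction handles strands, clipping and bad annotations", {
  withr::with_seed(10, {
    genome <- tibble::tibble(id = "chr1", seq = random_rna(1, 2000))
  })
  ann <- tibble::tibble(gene_id = c("gplus", "gend", "gminus", "gbad"),
                        seq_id = "chr1",
                        stop_codon_pos = c(0L, 1950L, 1500L, 5000L),
                        strand = c("+", "+", "-", "+"))
  expect_warning(utrs <- extract_utr(genome, ann, utr_len = 1000), "outside")
  expect_equal(nrow(utrs), 3)
  gp <- utrs[utrs$gene_id == "gplus", ]
  expect_equal(nchar(gp$seq), 1000)
  expect_equal(gp$seq, substr(genome$seq, 4, 1003))
  expect_false(gp$clipped)
  ge <- utrs[utrs$gene_id == "gend", ]
  expect_equal(nchar(ge$seq), 47)
  expect_true(ge$clipped)
  # minus strand equals an independently computed reverse complement
  gm <- utrs[utrs$gene_id == "gminus", ]
  manual <- substr(genome$seq, 501, 1500)
  manual <- paste(rev(strsplit(chartr("ACGU", "UGCA", manual), "")[[1]]),
                  collapse = "")
  expect_equal(gm$seq, manual)
})

test_that("site scanning finds planted seed and compensatory anchors only", {
  withr::with_seed(5, bg <- random_rna(1, 80))
  seed_rc <- revcomp_rna(substr(mir34, 2, 8))
  utr1 <- paste0(substr(bg, 1, 40), seed_rc, substr(bg, 48, 80))
  hits <- scan_sites(mir34, utr1)
  expect_true(any(hits$anchor_start == 40 & hits$anchor_type == "seed"))
  # a pure poly-A UTR has no complementarity to this miRNA's anchors
  expect_equal(nrow(scan_sites(mir34, strrep("A", 100))), 0)
  comp_rc <- revcomp_rna(substr(mir34, 13, 19))
  utr2 <- paste0(strrep("A", 30), comp_rc, strrep("A", 30))
  h2 <- scan_sites(mir34, utr2)
  expect_true(all(h2$anchor_type == "compensatory"))
  expect_true(any(h2$anchor_start == 30))
  expect_error(scan_sites("ACGUACGUACGU", "ACGU"), "19")
})

test_that("duplex energy of a perfect 8-mer equals the hand-summed stack terms", {
  m <- "ACGUGCCA"
  tgt <- revcomp_rna(m)
  tab <- nn_stack_table()
  pt <- function(a, b) paste0(a, b)
  mm <- strsplit(m, "")[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  hand <- 0
  for (i in 1:7) {
    hand <- hand + tab[pt(mm[i], comp[mm[i]]), pt(comp[mm[i + 1]], mm[i + 1])]
  }
  d <- duplex_energy(m, tgt)
  expect_equal(d$delta_g, unname(hand))
  expect_equal(d$pairing, strrep("|", 8))
  # no complementarity -> zero energy, empty pairing
  d0 <- duplex_energy("AAAAAAAA", "AAAAAAAA")
  expect_equal(d0$delta_g, 0)
  expect_equal(d0$pairing, strrep(" ", 8))
  expect_error(duplex_energy("ACGU", strrep("A", 41)), "40")
})

test_that("duplex DP equals the exhaustive enumeration oracle on short windows", {
  withr::with_seed(77, {
    for (i in 1:40) {
      m <- random_rna(1, sample(5:10, 1))
      u <- random_rna(1, sample(5:12, 1))
      expect_equal(duplex_energy(m, u)$delta_g, brute_duplex_dg(m, u),
                   tolerance = 1e-9, info = paste(m, u))
    }
  })
})

test_that("hit invariants hold: pairing length and non-positive energies", {
  withr::with_seed(31, {
    for (i in 1:20) {
      m <- random_rna(1, 22)
      u <- random_rna(1, 30)
      d <- duplex_energy(m, u)
      expect_equal(nchar(d$pairing), 22)
      expect_lte(d$delta_g, 0)
    }
  })
})

test_that("dinucleotide shuffling preserves counts exactly and is seeded", {
  withr::with_seed(2, x <- random_rna(1, 300))
  s1 <- dinucleotide_shuffle(x, seed = 5)
  s2 <- dinucleotide_shuffle(x, seed = 5)
  s3 <- dinucleotide_shuffle(x, seed = 6)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_equal(dinuc_counts(s1), dinuc_counts(x))
  expect_equal(dinuc_counts(s3), dinuc_counts(x))
  # endpoints are fixed by the Eulerian-walk construction
  expect_equal(substr(s1, 1, 1), substr(x, 1, 1))
  expect_equal(substr(s1, 300, 300), substr(x, 300, 300))
})

test_that("empirical p-values follow the add-one formula at the boundaries", {
  # hit no better than any shuffle -> p = 1; better than all -> 1/(n+1)
  p_hi <- site_pvalue(0, mir34, "unused", null_energies = rep(-30, 99))
  expect_equal(p_hi, 1)
  p_lo <- site_pvalue(-40, mir34, "unused", null_energies = rep(-10, 99))
  expect_equal(p_lo, 1 / 100)
  expect_error(site_pvalue(-30, mir34, strrep("ACGU", 30), n_shuffles = 10),
               "19")
})

test_that("hit filtering applies strict inequalities on both axes", {
  hits <- tibble::tibble(delta_g = c(-21, -20, -25, -19, -30),
                         p_value = c(0.01, 0.01, 0.05, 0.01, 0.049))
  kept <- filter_hits(hits)
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$delta_g < -20 & kept$p_value < 0.05))
  expect_false(any(kept$delta_g == -20))
  expect_false(any(kept$p_value == 0.05))
})

test_that("seed classification follows the pairing-string rule table", {
  pad <- function(seed7, rest) paste0("|", seed7, "    ", rest, "  ")
  # positions: 1 + 7 seed + 4 central + 7 comp + 2 tail = 21
  expect_equal(classify_seed(pad(strrep("|", 7), strrep("|", 7))), "canonical")
  expect_equal(classify_seed(pad("||:||||", strrep("|", 7))), "gu_seed")
  expect_equal(classify_seed(pad("|| ||||", strrep("|", 7))), "compensatory")
  expect_equal(classify_seed(pad("|| ||||", "||| |||")), "seedless")
  expect_equal(classify_seed(pad("||:|| |", strrep(":", 7))), "compensatory")
})

test_that("planted MREs are recovered with their classes by the full scanner", {
  classes <- c("canonical", "compensatory", "gu_seed")
  found <- 0; total <- 0
  for (s in 1:4) {
    g <- gen_utr_with_mres(mir34, n_sites = 3, classes = classes,
                           utr_len = 600, seed = 100 + s)
    hits <- predict_targets(tibble::tibble(id = "mir", seq = mir34), g$utr,
                            compute_pvalues = FALSE, filter = FALSE)
    for (i in seq_len(nrow(g$truth))) {
      tr <- g$truth[i, ]
      total <- total + 1
      ov <- hits[hits$start < tr$end & hits$end > tr$start, ]
      if (nrow(ov) > 0 && any(ov$seed_class == tr$class)) found <- found + 1
    }
  }
  expect_equal(found, total)
})

test_that("conserved network intersects species predictions through orthologs", {
  hits_a <- tibble::tibble(mirna_id = "m1", gene_id = paste0("a", 1:5),
                           delta_g = -25, p_value = 0.01, seed_class = "canonical")
  hits_b <- hits_a[1:3, ] |> dplyr::mutate(gene_id = paste0("b", 1:3))
  orth <- tibble::tibble(gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5))
  net <- conserved_network(hits_a, hits_b, orth)
  expect_equal(nrow(net$edges), 5)
  expect_equal(sum(net$edges$conserved), 3)
  # toy with identity orthologs: everything conserved
  net_id <- conserved_network(hits_a, hits_a,
                              tibble::tibble(gene_a = paste0("a", 1:5),
                                             gene_b = paste0("a", 1:5)))
  expect_true(all(net_id$edges$conserved))
  # empty species-B hits -> nothing conserved
  net0 <- conserved_network(hits_a, hits_b[0, ], orth)
  expect_false(any(net0$edges$conserved))
  # conserved edges form a subset of the species-A edge set
  expect_true(all(paste(net$edges$mirna_id, net$edges$gene_id)[net$edges$conserved]
                  %in% paste(hits_a$mirna_id, hits_a$gene_id)))
  expect_warning(conserved_network(hits_a, hits_b, orth, genes_a = paste0("a", 1:3)),
                 "ignored")
})

test_that("degree statistics match hand counts with n-1 SD and degenerate flags", {
  edges <- tibble::tibble(mirna_id = rep(c("m1", "m2"), c(2, 4)),
                          gene_id = paste0("g", 1:6),
                          delta_g = -25, p_value = 0.01, seed_class = "canonical")
  net <- conserved_network(edges, edges,
                           tibble::tibble(gene_a = paste0("g", 1:6),
                                          gene_b = paste0("g", 1:6)))
  st <- degree_stats(net)
  expect_equal(st$degrees$n_targets, c(2L, 4L))
  expect_equal(st$summary$mean, 3)
  expect_equal(st$summary$sd, sqrt(2), tolerance = 1e-4)
  expect_equal(st$summary$argmax, "m2")
  # single-miRNA network: SD reported 0 and flagged undefined
  one <- conserved_network(edges[1:2, ], edges[1:2, ],
                           tibble::tibble(gene_a = paste0("g", 1:2),
                                          gene_b = paste0("g", 1:2)))
  s1 <- degree_stats(one)
  expect_equal(s1$summary$sd, 0)
  expect_false(s1$summary$sd_defined)
  # empty network
  s0 <- degree_stats(structure(list(edges = edges[0, ] |>
                                      dplyr::mutate(conserved = logical(0))),
                               class = "target_network"))
  expect_equal(s0$summary$mean, 0)
})
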