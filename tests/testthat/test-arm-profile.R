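test_that("profiles accumulate weighted starts and coverage exactly", {
  pre <- tibble::tibble(id = "p1", seq = strrep("A", 40))
  aln <- tibble::tibble(read_id = paste0("r", 1:10), precursor_id = "p1",
                        start = 5L, length = 22L, mismatches = 0L, weight = 1)
  prof <- build_profile(aln, pre)
  expect_equal(prof$profile$start_count[6], 10)
  expect_equal(sum(prof$profile$start_count), 10)
  expect_true(all(prof$profile$coverage[6:27] == 10))
  expect_true(all(prof$profile$coverage[c(1:5, 28:40)] == 0))

  # empty alignments -> all-zero profile
  empty <- build_profile(aln[0, ], pre)
  expect_true(all(empty$profile$start_count == 0))
  expect_true(all(empty$profile$coverage == 0))

  # mixed fractional weights match brute-force accumulation
  withr::with_seed(8, {
    aln2 <- tibble::tibble(read_id = paste0("r", 1:30), precursor_id = "p1",
                           start = sample(0L:17L, 30, replace = TRUE),
                           length = sample(19L:22L, 30, replace = TRUE),
                           mismatches = 0L,
                           weight = sample(c(1, 0.5), 30, replace = TRUE))
    prof2 <- build_profile(aln2, pre)
    brute_sc <- numeric(40); brute_cov <- numeric(40)
    for (i in 1:30) {
      brute_sc[aln2$start[i] + 1] <- brute_sc[aln2$start[i] + 1] + aln2$weight[i]
      span <- (aln2$start[i] + 1):min(40, aln2$start[i] + aln2$length[i])
      brute_cov[span] <- brute_cov[span] + aln2$weight[i]
    }
    expect_equal(prof2$profile$start_count, brute_sc)
    expect_equal(prof2$profile$coverage, brute_cov)
    expect_equal(sum(prof2$profile$start_count), sum(aln2$weight))
  })
})

test_that("arm splitting finds the loop from the structure with a midpoint fallback", {
  pre <- tibble::tibble(id = "p", seq = strrep("A", 12), structure = "((((....))))")
  r <- split_arms(pre)
  expect_equal(r$loop, c(4L, 8L))
  expect_equal(r$five, c(0L, 4L))
  expect_equal(r$three, c(8L, 12L))
  expect_false(r$fallback)

  pre$structure <- "............"
  r2 <- split_arms(pre)
  expect_true(r2$fallback)
  expect_equal(r2$five, c(0L, 6L))
  expect_equal(r2$three, c(6L, 12L))

  # generated hairpin: loop region matches the generator's construction
  hp <- gen_hairpin("h", stem_len = 30, loop_len = 6, bulge_rate = 0, seed = 2)
  r3 <- split_arms(hp$precursor)
  expect_equal(r3$loop, c(30L, 36L))
})

test_that("peak calling respects the support threshold and jittered truth", {
  hp <- gen_hairpin("h", stem_len = 30, loop_len = 6, bulge_rate = 0, seed = 14)
  # 12 reads at one 5' position, length 22
  aln <- tibble::tibble(read_id = paste0("r", 1:12), precursor_id = "h",
                        start = 2L, length = 22L, mismatches = 0L, weight = 1)
  prof <- build_profile(aln, hp$precursor)
  calls <- call_matures(prof, hp$precursor, min_support = 10)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$arm, "5p")
  expect_equal(c(calls$start, calls$end), c(2L, 24L))

  # support 9 < 10 -> no call
  prof9 <- build_profile(aln[1:9, ], hp$precursor)
  expect_equal(nrow(call_matures(prof9, hp$precursor, min_support = 10)), 0)

  # modal length tie (21 and 22 equally frequent) resolves toward 22
  aln_tie <- tibble::tibble(read_id = paste0("t", 1:12), precursor_id = "h",
                            start = 2L, length = rep(c(21L, 22L), 6),
                            mismatches = 0L, weight = 1)
  ct <- call_matures(build_profile(aln_tie, hp$precursor), hp$precursor)
  expect_equal(ct$end - ct$start, 22L)
})

test_that("folding matches the exhaustive enumeration oracle up to 15 nt", {
  expect_equal(fold_hairpin("GGGAAACCC"), "(((...)))")
  expect_equal(fold_hairpin("AAAAAA"), "......")
  withr::with_seed(99, {
    for (i in 1:60) {
      s <- random_rna(1, sample(5:15, 1))
      db <- fold_hairpin(s)
      expect_true(db_min_loop_ok(db))
      expect_equal(db_pair_count(db), brute_max_pairs(s), info = s)
    }
  })
  expect_error(fold_hairpin("ACGN"), "outside")
})

test_that("stem check separates stem matures from loop decoys on generated hairpins", {
  for (i in 1:20) {
    hp <- gen_hairpin("h", stem_len = 30, loop_len = 25, bulge_rate = 0.05,
                      seed = i)
    truth5 <- hp$matures[hp$matures$arm == "5p", ]
    expect_true(stem_check(truth5, hp$precursor$structure))
    decoy <- tibble::tibble(start = 32L, end = 54L)  # sits in the 25-nt loop
    expect_false(stem_check(decoy, hp$precursor$structure))
  }
})

test_that("novelty flags use reciprocal 50% overlap against annotations", {
  known <- tibble::tibble(precursor_id = "p", arm = "5p", start = 10L, end = 32L)
  same <- tibble::tibble(precursor_id = "p", arm = "5p", start = 10L, end = 32L)
  expect_false(flag_novel(same, known)$novel)
  # the opposite, unannotated arm is novel
  other_arm <- tibble::tibble(precursor_id = "p", arm = "3p", start = 50L, end = 72L)
  expect_true(flag_novel(other_arm, known)$novel)
  # 40% overlap is below the reciprocal threshold
  part <- tibble::tibble(precursor_id = "p", arm = "5p", start = 23L, end = 45L)
  ov <- 32 - 23
  expect_lt(ov / 22, 0.5)
  expect_true(flag_novel(part, known)$novel)
  # shifted by 1 nt: 21/22 overlap, clearly known
  near <- tibble::tibble(precursor_id = "p", arm = "5p", start = 11L, end = 33L)
  expect_false(flag_novel(near, known)$novel)
})

test_that("cohort profiling recovers planted matures and never calls across the loop", {
  cohort <- small_cohort(n = 6, depth = 2000, seed = 52, error_rate = 0.001)
  calls <- profile_cohort(cohort$aln, cohort$hp$precursors,
                          known = cohort$hp$matures)
  expect_lte(nrow(calls), 2 * 6)
  expect_true(all(!calls$novel))   # planted arms are annotated
  expect_true(all(calls$in_stem))
  # at most one call per arm and intervals inside the correct arm
  expect_false(any(duplicated(paste(calls$precursor_id, calls$arm))))
  for (i in seq_len(nrow(calls))) {
    pre <- cohort$hp$precursors[cohort$hp$precursors$id == calls$precursor_id[i], ]
    reg <- split_arms(pre)
    r <- if (calls$arm[i] == "5p") reg$five else reg$three
    expect_gte(calls$start[i], r[1])
    expect_lte(calls$end[i], r[2] + 2)  # 3' end may jitter past the arm edge
  }
})
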