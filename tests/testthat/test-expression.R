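toy_calls <- tibble::tibble(precursor_id = c("p1", "p1"), arm = c("5p", "3p"),
                            start = c(2L, 40L), end = c(24L, 62L),
                            support = c(50, 50))

test_that("counting sums stage weights inside the peak window and conserves weight", {
  aln <- tibble::tibble(read_id = paste0("r", 1:50), stage = "s1",
                        precursor_id = "p1", start = 2L, length = 22L,
                        mismatches = 0L, weight = 1)
  expr <- suppressWarnings(count_matrix(aln, toy_calls[1, ]))
  expect_equal(expr$count[expr$stage == "s1"], 50)

  # a read split 0.5/0.5 across two precursors contributes 0.5 to each
  calls2 <- dplyr::bind_rows(toy_calls[1, ],
                             dplyr::mutate(toy_calls[1, ], precursor_id = "p2"))
  aln2 <- tibble::tibble(read_id = "r", stage = "s1",
                         precursor_id = c("p1", "p2"), start = 2L,
                         length = 22L, mismatches = 0L, weight = 0.5)
  expr2 <- count_matrix(aln2, calls2)
  expect_equal(expr2$count, c(0.5, 0.5))
  expect_equal(sum(expr2$count), 1)
  expect_error(count_matrix(aln2, calls2, stages = c("s1", "s1")), "collision")
})

test_that("RPM columns are scaled to one million with zero-column warnings", {
  expr <- tibble::tibble(mature_id = c("m1", "m2", "m1", "m2"),
                         precursor_id = "p", arm = rep(c("5p", "3p"), 2),
                         stage = rep(c("s1", "s2"), each = 2),
                         count = c(1, 3, 0, 0))
  expect_warning(out <- rpm(expr), "zero total")
  expect_equal(out$rpm[out$stage == "s1"], c(250000, 750000))
  expect_equal(out$rpm[out$stage == "s2"], c(0, 0))
  s1 <- sum(out$rpm[out$stage == "s1"])
  expect_lt(abs(s1 - 1e6) / 1e6, 1e-6)
})

test_that("entropy matches closed forms and is bounded by ln(n)", {
  base_expr <- function(counts) {
    tibble::tibble(mature_id = paste0("m", seq_along(counts)),
                   precursor_id = "p", arm = "5p", stage = "s",
                   count = counts, rpm = counts)
  }
  expect_equal(shannon_entropy(base_expr(c(10, 0, 0)))$entropy, 0)
  for (k in c(2, 5, 17)) {
    H <- shannon_entropy(base_expr(rep(3, k)))$entropy
    expect_equal(H, log(k), tolerance = 1e-12)
  }
  expect_equal(shannon_entropy(base_expr(c(2, 1, 1)))$entropy, 1.0397,
               tolerance = 1e-4)
  expect_equal(shannon_entropy(base_expr(c(2, 1, 1)), base = 2)$entropy, 1.5)
  withr::with_seed(3, {
    for (i in 1:20) {
      counts <- rpois(sample(2:30, 1), 20) + 1
      H <- shannon_entropy(base_expr(counts))$entropy
      expect_gte(H, 0)
      expect_lte(H, log(length(counts)) + 1e-12)
    }
  })
  expect_error(shannon_entropy(base_expr(c(0, 0))), "all-zero")
})

test_that("dominance and switching follow the rule table including tie and low stages", {
  mk <- function(rpm5, rpm3, stages = paste0("s", seq_along(rpm5))) {
    tibble::tibble(mature_id = rep(c("p-5p", "p-3p"), each = length(rpm5)),
                   precursor_id = "p", arm = rep(c("5p", "3p"), each = length(rpm5)),
                   stage = rep(stages, 2), count = c(rpm5, rpm3),
                   rpm = c(rpm5, rpm3))
  }
  # dominant 5p everywhere -> no switch
  d1 <- arm_dominance(mk(c(90, 80, 70, 60), c(10, 20, 30, 40)))
  expect_true(all(d1$dominant == "5p"))
  expect_false(any(d1$switching))
  # (5p, 5p, 3p, 3p) -> switch
  d2 <- arm_dominance(mk(c(90, 80, 10, 20), c(10, 20, 90, 80)))
  expect_true(all(d2$switching))
  # (5p, low, low, 3p) -> switch; low stages excluded from dominance
  d3 <- arm_dominance(mk(c(90, 2, 1, 10), c(10, 2, 1, 90)), min_total_rpm = 5)
  expect_equal(d3$dominant[order(d3$stage)], c("5p", "low", "low", "3p"))
  expect_true(all(d3$switching))
  # (5p, tie, tie, tie) -> no switch
  d4 <- arm_dominance(mk(c(90, 50, 50, 50), c(10, 50, 50, 50)))
  expect_equal(sort(unique(d4$dominant)), c("5p", "tie"))
  expect_false(any(d4$switching))
  # arm fractions lie in [0,1] and are complementary
  frac <- d1$rpm_5p / (d1$rpm_5p + d1$rpm_3p)
  expect_true(all(frac >= 0 & frac <= 1))
  expect_equal(frac + d1$rpm_3p / (d1$rpm_5p + d1$rpm_3p), rep(1, 4))
})

test_that("stage clustering recovers planted correlation structure deterministically", {
  withr::with_seed(7, {
    base1 <- rpois(40, 50); base2 <- rpois(40, 50)
    counts <- cbind(a_like1 = base1 + rpois(40, 3),
                    a_like2 = base1 + rpois(40, 3),
                    b_like1 = base2 + rpois(40, 3),
                    b_like2 = base2 + rpois(40, 3))
  })
  expr <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(counts), mature_id = paste0("m", 1:40),
                  precursor_id = paste0("p", 1:40), arm = "5p"),
    cols = dplyr::starts_with(c("a_", "b_")), names_to = "stage",
    values_to = "count")
  expr <- rpm(expr)
  cl <- cluster_stages(expr)
  merges <- tidy(cl)
  expect_setequal(merges$members[1:2], c("a_like1,a_like2", "b_like1,b_like2"))
  # heights non-decreasing; identical columns merge at distance ~0
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  wide <- tidyr::pivot_wider(expr[, c("mature_id", "stage", "count")],
                             names_from = "stage", values_from = "count")
  wide$a_like2 <- wide$a_like1
  expr_dup <- tidyr::pivot_longer(wide, -mature_id, names_to = "stage",
                                  values_to = "count")
  expr_dup$precursor_id <- expr_dup$mature_id
  expr_dup$arm <- "5p"
  cl2 <- cluster_stages(rpm(expr_dup))
  expect_lt(tidy(cl2)$height[1], 1e-12)
  expect_true(grepl("^\\(", cl$newick))
  expect_error(cluster_stages(expr[expr$stage == "a_like1", ]), "two stages")
})

test_that("simulated cohort counts track planted arm fractions", {
  frac <- tidyr::expand_grid(precursor_id = sprintf("hp%03d", 1:4),
                             stage = c("s1", "s2")) %>%
    dplyr::mutate(fraction_5p = 0.7)
  cohort <- small_cohort(n = 4, depth = 10000, seed = 61, error_rate = 0.001,
                         stages = c("s1", "s2"), arm_fractions = frac)
  calls <- profile_cohort(cohort$aln, cohort$hp$precursors,
                          known = cohort$hp$matures)
  expr <- count_matrix(cohort$aln, calls)
  by_pre <- expr %>%
    dplyr::group_by(precursor_id, stage) %>%
    dplyr::summarise(f5 = sum(count[arm == "5p"]) / sum(count), .groups = "drop")
  expect_true(all(abs(by_pre$f5 - 0.7) < 0.05))
})
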