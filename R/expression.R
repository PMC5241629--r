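#' Count mature miRNA expression per stage
#'
#' A read contributes its alignment weight to a mature call when it maps
#' to the call's precursor with a start within one nucleotide of the
#' call's 5' peak, matching the support window of [call_matures()]. The
#' result is a long table over every (mature, stage) combination, with
#' zero counts filled in, plus an RPM column (reads per million mapped
#' reads in the stage column).
#'
#' @param alignments Alignment tibble with a `stage` column.
#' @param calls Mature-call tibble from [call_matures()]/[profile_cohort()].
#' @param stages Optional stage ordering; defaults to sorted unique stages
#'   in `alignments`. Duplicated labels are an error.
#' @return Long expression tibble: `mature_id`, `precursor_id`, `arm`,
#'   `stage`, `count`, `rpm`.
#' @export
count_matrix <- function(alignments, calls, stages = NULL) {
  if (!"stage" %in% names(alignments)) abort("alignments need a stage column")
  if (is.null(stages)) stages <- sort(unique(alignments$stage))
  if (anyDuplicated(stages)) abort(sprintf("stage label collision: %s",
                                           stages[duplicated(stages)][1]))
  calls <- mutate(calls, mature_id = paste0(.data$precursor_id, "-", .data$arm))
  cells <- purrr::map(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    hit <- alignments$precursor_id == cl$precursor_id &
      alignments$start >= cl$start - 1 & alignments$start <= cl$start + 1
    aln <- alignments[hit, ]
    agg <- aln %>% group_by(.data$stage) %>%
      summarise(count = sum(.data$weight), .groups = "drop")
    tibble(mature_id = cl$mature_id, precursor_id = cl$precursor_id,
           arm = cl$arm, stage = stages,
           count = agg$count[match(stages, agg$stage)])
  })
  expr <- bind_rows(cells)
  expr$count[is.na(expr$count)] <- 0
  rpm(expr)
}

#' Add / refresh the RPM normalisation column
#'
#' RPM = count * 1e6 / (stage column sum). An all-zero stage column yields
#' zero RPM with a warning.
#'
#' @param expr Long expression tibble with `stage` and `count`.
#' @return `expr` with an `rpm` column; each non-empty stage's RPM sums to
#'   1e6.
#' @export
rpm <- function(expr) {
  out <- expr %>% group_by(.data$stage) %>%
    mutate(rpm = if (sum(.data$count) > 0) .data$count * 1e6 / sum(.data$count) else 0) %>%
    ungroup()
  zero <- unique(expr$stage[!expr$stage %in% expr$stage[expr$count > 0]])
  if (length(zero) > 0) {
    warn(sprintf("stage(s) with zero total counts: %s", paste(zero, collapse = ", ")))
  }
  out
}

#' Shannon entropy of miRNA expression diversity per stage
#'
#' H = -sum(p_i * log(p_i)) with p_i the count fraction of each expressed
#' unit (mature miRNAs by default, or precursors by summing arms) within a
#' stage. Zero cells contribute nothing. The logarithm base is
#' configurable (natural log by default).
#'
#' @param expr Long expression tibble.
#' @param stage Optional single stage; default computes all stages.
#' @param base Logarithm base (`exp(1)` for nats, `2` for bits).
#' @param level `"mature"` or `"precursor"`.
#' @return Tibble `stage`, `entropy`.
#' @export
shannon_entropy <- function(expr, stage = NULL, base = exp(1),
                            level = c("mature", "precursor")) {
  level <- match.arg(level)
  if (!is.null(stage)) {
    expr <- expr[expr$stage %in% stage, ]
    if (nrow(expr) == 0) abort(sprintf("unknown stage: %s", stage))
  }
  unit <- if (level == "mature") "mature_id" else "precursor_id"
  out <- expr %>%
    group_by(.data$stage, .data[[unit]]) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    group_by(.data$stage) %>%
    summarise(entropy = {
      tot <- sum(.data$count)
      if (tot == 0) abort("cannot compute entropy of an all-zero stage column")
      p <- .data$count[.data$count > 0] / tot
      -sum(p * log(p, base = base))
    }, .groups = "drop")
  out
}

#' Arm dominance and arm-switching calls per precursor
#'
#' Per precursor and stage, the dominant arm is the one with strictly
#' larger RPM; equal RPM is a `"tie"`, and stages whose 5p + 3p RPM falls
#' below `min_total_rpm` are `"low"` (too shallow to call). A precursor is
#' flagged as switching when, across stages and ignoring tie/low stages,
#' the 5p arm dominates at least one stage and the 3p arm another.
#'
#' @param expr Long expression tibble containing both arms of each
#'   precursor (missing arms count as zero).
#' @param min_total_rpm Minimum 5p + 3p RPM for a dominance call.
#' @return An `arm_dynamics` tibble: `precursor_id`, `stage`, `rpm_5p`,
#'   `rpm_3p`, `dominant`, `switching` (per precursor, repeated across its
#'   stages).
#' @export
arm_dominance <- function(expr, min_total_rpm = 5) {
  wide <- expr %>%
    select("precursor_id", "arm", "stage", "rpm") %>%
    tidyr::pivot_wider(names_from = "arm", values_from = "rpm",
                       names_prefix = "rpm_", values_fill = 0)
  if (!"rpm_5p" %in% names(wide)) wide$rpm_5p <- 0
  if (!"rpm_3p" %in% names(wide)) wide$rpm_3p <- 0
  wide <- wide %>%
    mutate(dominant = dplyr::case_when(
      .data$rpm_5p + .data$rpm_3p < min_total_rpm ~ "low",
      .data$rpm_5p > .data$rpm_3p ~ "5p",
      .data$rpm_3p > .data$rpm_5p ~ "3p",
      TRUE ~ "tie"
    )) %>%
    group_by(.data$precursor_id) %>%
    mutate(switching = any(.data$dominant == "5p") & any(.data$dominant == "3p")) %>%
    ungroup() %>%
    arrange(.data$precursor_id, .data$stage)
  class(wide) <- c("arm_dynamics", class(wide))
  wide
}

#' Hierarchical clustering of developmental stages
#'
#' Stages are clustered on 1 - Pearson correlation of their log2(RPM + 1)
#' expression vectors with average linkage. Stage columns are ordered
#' alphabetically before clustering so leaf order is deterministic. A
#' zero-variance stage vector has undefined correlation; its distances are
#' defined as 1 with a warning.
#'
#' @param expr Long expression tibble with >= 2 stages.
#' @return A `stage_clust` object: list with the `hclust` fit, the
#'   distance matrix, and a Newick string of the dendrogram.
#' @export
cluster_stages <- function(expr) {
  mat <- expr %>%
    select("mature_id", "stage", "rpm") %>%
    tidyr::pivot_wider(names_from = "stage", values_from = "rpm", values_fill = 0)
  m <- as.matrix(mat[, -1, drop = FALSE])
  m <- m[, order(colnames(m)), drop = FALSE]
  if (ncol(m) < 2) abort("need at least two stages to cluster")
  lm <- log2(m + 1)
  const <- apply(lm, 2, sd) == 0
  if (any(const)) {
    warn(sprintf("constant expression column(s): %s; distances set to 1",
                 paste(colnames(lm)[const], collapse = ", ")))
  }
  cc <- suppressWarnings(cor(lm))
  d <- 1 - cc
  d[is.na(d)] <- 1
  diag(d) <- 0
  fit <- hclust(as.dist(d), method = "average")
  phylo <- ape::as.phylo(fit)
  structure(list(hclust = fit, dist = d,
                 newick = ape::write.tree(phylo)),
            class = "stage_clust")
}

#' @export
print.stage_clust <- function(x, ...) {
  cat("<stage_clust>", length(x$hclust$labels), "stages;",
      "merge heights:", paste(signif(x$hclust$height, 4), collapse = ", "), "\n")
  cat(x$newick, "\n")
  invisible(x)
}
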