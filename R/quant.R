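#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Per condition, dCt = mean over replicates of (target Ct - reference Ct);
#' ddCt = dCt(condition) - dCt(calibrator); relative quantity
#' RQ = 2^-ddCt, so the calibrator has RQ = 1 by construction and
#' log2(RQ) = -ddCt exactly.
#'
#' @param records Tibble with columns `condition`, `target_ct`,
#'   `reference_ct` (one row per replicate; a `sample_id` column is
#'   allowed and ignored).
#' @param calibrator Condition label used as calibrator.
#' @return Tibble `condition`, `n_replicates`, `delta_ct`,
#'   `delta_delta_ct`, `rq`.
#' @examples
#' rec <- tibble::tibble(condition = c("a", "a", "b", "b"),
#'                       target_ct = c(20, 20.2, 18, 18.2),
#'                       reference_ct = c(15, 15.2, 15, 15.2))
#' ddct(rec, calibrator = "a")
#' @export
ddct <- function(records, calibrator) {
  need <- c("condition", "target_ct", "reference_ct")
  if (!all(need %in% names(records))) {
    abort(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyNA(records$reference_ct)) {
    bad <- which(is.na(records$reference_ct))[1]
    abort(sprintf("missing reference-gene Ct at record %d", bad))
  }
  if (anyNA(records$target_ct)) abort("missing target-gene Ct")
  if (any(records$target_ct <= 0) || any(records$reference_ct <= 0)) {
    abort("Ct values must be positive")
  }
  if (!calibrator %in% records$condition) {
    abort(sprintf("calibrator condition '%s' not present", calibrator))
  }
  out <- records %>%
    group_by(.data$condition) %>%
    summarise(n_replicates = n(),
              delta_ct = mean(.data$target_ct - .data$reference_ct),
              .groups = "drop")
  cal <- out$delta_ct[out$condition == calibrator]
  out %>%
    mutate(delta_delta_ct = .data$delta_ct - cal,
           rq = 2^(-.data$delta_delta_ct))
}

#' Two-sample t-test for condition comparisons
#'
#' Two-sided Welch (unequal-variance) t-test by default, with a pooled
#' variant behind `var_equal = TRUE`. Significance uses a strict
#' p < alpha. When both groups have zero variance, equal means give
#' t = 0, p = 1; unequal means give p = 0 (infinite separation).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances instead of Welch.
#' @param alpha Significance level (strict).
#' @return One-row tibble `statistic`, `df`, `p_value`, `significant`,
#'   `method`.
#' @export
two_sample_ttest <- function(group_a, group_b, var_equal = FALSE, alpha = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2) abort("each group needs n >= 2")
  method <- if (var_equal) "pooled t-test" else "Welch t-test"
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(tibble(statistic = 0, df = NA_real_, p_value = 1,
                    significant = FALSE, method = method))
    }
    return(tibble(statistic = sign(mean(group_a) - mean(group_b)) * Inf,
                  df = NA_real_, p_value = 0, significant = TRUE,
                  method = method))
  }
  fit <- t.test(group_a, group_b, var.equal = var_equal)
  tibble(statistic = unname(fit$statistic), df = unname(fit$parameter),
         p_value = fit$p.value, significant = fit$p.value < alpha,
         method = method)
}
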