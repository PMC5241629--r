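#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_tile geom_segment labs theme_minimal scale_fill_gradient facet_wrap
NULL

#' Plot a precursor coverage profile
#'
#' Coverage depth and weighted read-start counts along the precursor.
#'
#' @param object A `coverage_profile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.coverage_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(object$profile, c("start_count", "coverage"),
                            names_to = "track", values_to = "value")
  ggplot(df, aes(x = .data$pos, y = .data$value)) +
    geom_col(width = 1) +
    facet_wrap(~track, ncol = 1, scales = "free_y") +
    labs(title = object$precursor_id, x = "precursor position (0-based)",
         y = "weighted reads") +
    theme_minimal()
}

#' Plot arm dynamics across stages
#'
#' 5p fraction of RPM per precursor and stage; switching precursors cross
#' the 0.5 line.
#'
#' @param object An `arm_dynamics` tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.arm_dynamics <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(frac_5p = ifelse(.data$rpm_5p + .data$rpm_3p > 0,
                            .data$rpm_5p / (.data$rpm_5p + .data$rpm_3p), NA))
  ggplot(df, aes(x = .data$stage, y = .data$frac_5p,
                 group = .data$precursor_id, colour = .data$switching)) +
    geom_line() + geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    labs(y = "5p fraction of arm RPM", x = NULL) +
    theme_minimal()
}

#' Expression heatmap of matures by stages
#'
#' @param expr Long expression tibble from [count_matrix()].
#' @return A ggplot of log2(RPM + 1).
#' @export
plot_expression_heatmap <- function(expr) {
  ggplot(expr, aes(x = .data$stage, y = .data$mature_id,
                   fill = log2(.data$rpm + 1))) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = "log2(RPM+1)") +
    theme_minimal()
}

#' Plot a stage dendrogram
#'
#' @param object A `stage_clust`.
#' @param ... Ignored.
#' @return A ggplot drawn from the hclust merge structure.
#' @export
autoplot.stage_clust <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  # leaf x-coordinates in dendrogram order
  xleaf <- setNames(match(seq_len(n), hc$order), seq_len(n))
  xs <- numeric(nrow(hc$merge)); segs <- list()
  node_x <- function(k) if (k < 0) xleaf[[-k]] else xs[k]
  node_h <- function(k) if (k < 0) 0 else hc$height[k]
  for (k in seq_len(nrow(hc$merge))) {
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    xa <- node_x(a); xb <- node_x(b); h <- hc$height[k]
    xs[k] <- (xa + xb) / 2
    segs[[length(segs) + 1]] <- tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(node_h(a), node_h(b), h), yend = c(h, h, h))
  }
  ggplot(bind_rows(segs)) +
    geom_segment(aes(x = .data$x, xend = .data$xend,
                     y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n),
                                labels = hc$labels[hc$order]) +
    labs(x = NULL, y = "1 - Pearson (average linkage)") +
    theme_minimal()
}

#' Plot per-miRNA target degrees of a network
#'
#' @param object A `target_network`.
#' @param ... Ignored.
#' @return A ggplot bar chart of conserved target counts per miRNA.
#' @export
autoplot.target_network <- function(object, ...) {
  deg <- degree_stats(object)$degrees
  ggplot(deg, aes(x = stats::reorder(.data$mirna_id, -.data$n_targets),
                  y = .data$n_targets)) +
    geom_col() +
    labs(x = NULL, y = "conserved targets") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a conservation profile of an MSA
#'
#' @param object A `mir_msa`.
#' @param ... Ignored.
#' @return A ggplot of per-column conserved fractions, labelled with the
#'   consensus letters.
#' @export
autoplot.mir_msa <- function(object, ...) {
  prof <- conservation_profile(object)
  ggplot(prof, aes(x = .data$position, y = .data$fraction)) +
    geom_col() +
    ggplot2::geom_text(aes(label = .data$consensus), vjust = -0.4, size = 3) +
    ggplot2::ylim(0, 1.1) +
    labs(x = "alignment column", y = "conserved fraction") +
    theme_minimal()
}
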