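#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a stage clustering
#'
#' One row per merge of the average-linkage dendrogram.
#'
#' @param x A `stage_clust`.
#' @param ... Ignored.
#' @return Tibble `merge`, `height`, `members` (comma-joined stage labels
#'   of the merged cluster).
#' @export
tidy.stage_clust <- function(x, ...) {
  hc <- x$hclust
  members <- function(k) {
    if (k < 0) return(hc$labels[-k])
    c(members(hc$merge[k, 1]), members(hc$merge[k, 2]))
  }
  tibble(merge = seq_len(nrow(hc$merge)),
         height = hc$height,
         members = vapply(seq_len(nrow(hc$merge)),
                          function(k) paste(sort(members(k)), collapse = ","),
                          character(1)))
}

#' @rdname tidy.stage_clust
#' @export
glance.stage_clust <- function(x, ...) {
  tibble(n_stages = length(x$hclust$labels),
         min_height = min(x$hclust$height),
         max_height = max(x$hclust$height))
}

#' Tidy a target network
#'
#' @param x A `target_network`.
#' @param ... Ignored.
#' @return The edge tibble (one row per miRNA-gene edge).
#' @export
tidy.target_network <- function(x, ...) {
  x$edges
}

#' @rdname tidy.target_network
#' @export
glance.target_network <- function(x, ...) {
  st <- degree_stats(x)
  tibble(n_edges = nrow(x$edges),
         n_conserved = sum(x$edges$conserved),
         n_mirnas = length(unique(x$edges$mirna_id)),
         n_genes = length(unique(x$edges$gene_id)),
         mean_degree = st$summary$mean,
         sd_degree = st$summary$sd,
         max_degree = st$summary$max,
         top_mirna = st$summary$argmax)
}

#' Tidy an MSA
#'
#' @param x A `mir_msa`.
#' @param ... Ignored.
#' @return The per-column conservation profile tibble.
#' @export
tidy.mir_msa <- function(x, ...) {
  conservation_profile(x)
}

#' @rdname tidy.mir_msa
#' @export
glance.mir_msa <- function(x, ...) {
  prof <- conservation_profile(x)
  tibble(n_sequences = nrow(x), n_columns = nrow(prof),
         mean_conservation = mean(prof$fraction),
         fully_conserved = sum(prof$fraction == 1),
         center = attr(x, "center"))
}

#' Tidy a coverage profile
#'
#' @param x A `coverage_profile`.
#' @param ... Ignored.
#' @return Tibble `precursor_id`, `pos`, `start_count`, `coverage`.
#' @export
tidy.coverage_profile <- function(x, ...) {
  mutate(x$profile, precursor_id = x$precursor_id, .before = 1)
}
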