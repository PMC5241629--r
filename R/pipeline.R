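#' Default pipeline configuration
#'
#' Every tunable of the pipeline is a config key; [run_pipeline()] merges
#' user values (from a YAML file or a list) over these defaults.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_precursors = 5L, stem_len = 30L, loop_len = 6L, bulge_rate = 0.05,
      stages = list(blastoderm = 2000L, gastrulation = 2000L,
                    germ_band = 2000L, larval_body = 2000L),
      default_fraction_5p = 0.8, error_rate = 0.001,
      adapter = "TGGAATTCTCGGGTGCCAAGG", read_cycles = 36L,
      arm_switch = list()   # list of list(precursor_id, stages_5p, stages_3p)
    ),
    preprocess = list(min_len = 19L, max_len = 24L, min_overlap = 8L,
                      max_mismatch_rate = 0.1),
    align = list(max_mismatch = 1L),
    arms = list(min_support = 10, min_paired_fraction = 0.6),
    expression = list(min_total_rpm = 5, entropy_base = "e")
  )
}

#' Run the simulate - preprocess - align - profile - expression pipeline
#'
#' End-to-end driver on simulated data: generates a hairpin cohort and
#' stage libraries, trims and length-filters the reads, maps them to the
#' precursors, calls mature 5p/3p miRNAs, and computes the expression
#' table, arm dynamics, Shannon entropies, and the stage dendrogram. All
#' tables are written as TSV under `out_dir` together with a JSON run
#' manifest (package version, seed, full parameter set, output
#' checksums). Reruns with the same config are byte-identical.
#'
#' @param config A nested list (see [default_config()]) or path to a YAML
#'   file with the same structure; partial configs are merged over the
#'   defaults.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results (`precursors`,
#'   `truth`, `calls`, `expr`, `dynamics`, `entropy`, `clust`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_config(), config, keep.null = TRUE)
  # stage maps and switch lists replace wholesale rather than key-merge
  if (!is.null(config$simulate$stages)) cfg$simulate$stages <- config$simulate$stages
  if (!is.null(config$simulate$arm_switch)) cfg$simulate$arm_switch <- config$simulate$arm_switch
  if (missing(out_dir) || is.null(out_dir)) abort("out_dir is required")
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  # --- simulate ------------------------------------------------------
  sim_cfg <- cfg$simulate
  hp <- gen_hairpins(sim_cfg$n_precursors, stem_len = sim_cfg$stem_len,
                     loop_len = sim_cfg$loop_len, bulge_rate = sim_cfg$bulge_rate,
                     seed = seed)
  stages <- tibble(stage = names(sim_cfg$stages),
                   depth = as.integer(unlist(sim_cfg$stages)))
  fractions <- tidyr::expand_grid(precursor_id = hp$precursors$id,
                                  stage = stages$stage) %>%
    mutate(fraction_5p = sim_cfg$default_fraction_5p)
  for (sw in sim_cfg$arm_switch) {
    fractions <- plant_arm_switch(fractions, sw$precursor_id,
                                  sw$stages_5p, sw$stages_3p)
  }
  lib <- simulate_library(hp$precursors, hp$matures, stages,
                          arm_fractions = fractions,
                          error_rate = sim_cfg$error_rate,
                          adapter = sim_cfg$adapter,
                          read_cycles = sim_cfg$read_cycles,
                          seed = seed + 1L)

  # --- preprocess ----------------------------------------------------
  pp <- cfg$preprocess
  trimmed <- trim_adapter(lib$reads, sim_cfg$adapter,
                          min_overlap = pp$min_overlap,
                          max_mismatch_rate = pp$max_mismatch_rate)
  filtered <- length_filter(trimmed, pp$min_len, pp$max_len)

  # --- align ---------------------------------------------------------
  aln <- map_reads(filtered, hp$precursors, max_mismatch = cfg$align$max_mismatch)

  # --- arm profile ---------------------------------------------------
  calls <- profile_cohort(aln, hp$precursors, known = hp$matures,
                          min_support = cfg$arms$min_support,
                          min_paired_fraction = cfg$arms$min_paired_fraction)

  # --- expression ----------------------------------------------------
  expr <- count_matrix(aln, calls, stages = sort(stages$stage))
  dynamics <- arm_dominance(expr, min_total_rpm = cfg$expression$min_total_rpm)
  base <- if (identical(cfg$expression$entropy_base, "2")) 2 else exp(1)
  entropy <- shannon_entropy(expr, base = base)
  clust <- cluster_stages(expr)

  # --- write artifacts ----------------------------------------------
  write_fasta(hp$precursors[, c("id", "seq")], file.path(out_dir, "precursors.fasta"))
  readr::write_tsv(hp$matures, file.path(out_dir, "truth_matures.tsv"))
  readr::write_tsv(lib$truth, file.path(out_dir, "truth_reads.tsv"))
  for (st in stages$stage) {
    write_fastq(lib$reads[lib$reads$stage == st, ],
                file.path(out_dir, paste0("reads_", st, ".fastq")))
  }
  readr::write_tsv(aln, file.path(out_dir, "alignments.tsv"))
  readr::write_tsv(calls, file.path(out_dir, "mature_calls.tsv"))
  write_counts_table(expr, file.path(out_dir, "counts.tsv"), value = "count")
  write_counts_table(expr, file.path(out_dir, "rpm.tsv"), value = "rpm")
  readr::write_tsv(as_tibble(dynamics), file.path(out_dir, "arm_dynamics.tsv"))
  readr::write_tsv(entropy, file.path(out_dir, "entropy.tsv"))
  writeLines(clust$newick, file.path(out_dir, "stage_dendrogram.nwk"))

  arts <- list.files(out_dir, full.names = TRUE)
  arts <- arts[!grepl("manifest\\.json$", arts)]
  manifest <- list(
    package = "mirarm",
    version = as.character(utils::packageVersion("mirarm")),
    seed = seed,
    config = cfg,
    stages = c("simulate", "preprocess", "align", "arm_profile", "expression"),
    artifacts = as.list(setNames(unname(tools::md5sum(sort(arts))),
                                 basename(sort(arts))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(precursors = hp$precursors, truth = lib$truth,
                 truth_matures = hp$matures, fractions = fractions,
                 calls = calls, expr = expr, dynamics = dynamics,
                 entropy = entropy, clust = clust, manifest = manifest))
}

validate_config <- function(cfg) {
  sim <- cfg$simulate
  if (is.null(sim$n_precursors) || sim$n_precursors < 1) {
    abort("config error: simulate.n_precursors must be >= 1")
  }
  if (is.null(sim$stages) || length(sim$stages) == 0) {
    abort("config error: simulate.stages must name at least one stage")
  }
  if (anyDuplicated(names(sim$stages))) abort("config error: duplicate stage labels")
  if (cfg$preprocess$min_len > cfg$preprocess$max_len) {
    abort("config error: preprocess.min_len > preprocess.max_len")
  }
  for (sw in sim$arm_switch) {
    if (is.null(sw$precursor_id) || is.null(sw$stages_5p) || is.null(sw$stages_3p)) {
      abort("config error: arm_switch entries need precursor_id, stages_5p, stages_3p")
    }
    if (!all(c(sw$stages_5p, sw$stages_3p) %in% names(sim$stages))) {
      abort("config error: arm_switch references unknown stage")
    }
  }
  invisible(cfg)
}
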