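#' Run the full population-to-network pipeline
#'
#' Executes the stages in order — materialize, scan, fates, network,
#' annotate, enrich, evaluate — writing each stage's tables under
#' `config$out_dir` and a JSON run manifest recording parameters, completed
#' and skipped stages, and the MD5 checksum of the edge list (reruns with an
#' identical config and seed are byte-identical for the deterministic
#' stages). Stages whose optional inputs are missing are skipped with a
#' notice.
#'
#' @param config Named list:
#'   * `panel` — an [ecotype_panel()] (alternatively `mirna_fasta`,
#'     `transcript_fasta`, `vcf` paths to build one);
#'   * `out_dir` — output directory (required);
#'   * `threshold` (default 0.85), `mode` (`"extended"`), `percentile`
#'     (0.15), `n_reps` (1000), `seed` (1);
#'   * optional inputs enabling stages: `expression` (long tibble for
#'     [preprocess_expression()]), `stress` (tibble `mirna_id`, `stress`),
#'     `climate` (tibble for [climate_sd_tests()]), `mirna_ages` (tibble
#'     `mirna_id`, `conserved`, `age` as from [filter_mirna_hits()]).
#' @return Invisibly, a list with the fate profiles, network, topology,
#'   optional evaluation results, and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) abort("config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  threshold <- config$threshold %||% 0.85
  mode <- config$mode %||% "extended"
  percentile <- config$percentile %||% 0.15
  n_reps <- config$n_reps %||% 1000L
  seed <- config$seed %||% 1L
  stages <- list()
  done <- function(name, note = NULL) {
    stages[[length(stages) + 1L]] <<- list(stage = name, status = "completed",
                                           note = note)
  }
  skip <- function(name, why) {
    inform(paste0("stage ", name, " skipped: ", why))
    stages[[length(stages) + 1L]] <<- list(stage = name, status = "skipped",
                                           note = why)
  }

  panel <- config$panel
  if (is.null(panel)) {
    mir <- read_fasta(config$mirna_fasta, "mirna")
    tx <- read_fasta(config$transcript_fasta, "transcript")
    seqs <- bind_rows(mir, tx)
    panel <- ecotype_panel(seqs, read_variants(config$vcf, seqs))
  }

  # materialize: singleton filter + per-ecotype sequence status
  variants <- filter_singletons(panel$variants)
  work <- panel; work$variants <- variants
  mat <- materialize_all(work)
  utils::write.table(
    dplyr::select(mat, -"sequence"),
    file.path(config$out_dir, "materialized_status.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  done("materialize")

  # scan + fates
  profiles <- population_fate_profiles(work, drop_singletons = FALSE)
  write_fate_matrix(profiles, file.path(config$out_dir, "fates.tsv"))
  done("scan")
  done("fates")

  # network
  network <- build_network(profiles, threshold = threshold, mode = mode)
  net_paths <- write_network(network, config$out_dir)
  done("network")

  # annotate
  ages <- config$mirna_ages
  if (!is.null(ages)) {
    utils::write.table(ages, file.path(config$out_dir, "mirna_ages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    done("annotate")
  } else {
    skip("annotate", "no miRNA age/conservation table supplied")
  }

  # enrich
  enrichment <- NULL
  if (!is.null(ages) && nrow(network$edges) > 0L) {
    cats <- setNames(ifelse(ages$conserved, "conserved", "non-conserved"),
                     ages$mirna_id)
    known <- network$edges$mirna_i %in% names(cats) &
      network$edges$mirna_j %in% names(cats)
    if (any(known)) {
      set.seed(seed)
      enrichment <- enrichment_matrix(network$edges[known, ], cats,
                                      scheme = "label_permute",
                                      n_reps = n_reps)
      utils::write.table(enrichment,
                         file.path(config$out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      done("enrich")
    } else skip("enrich", "no annotated edge endpoints")
  } else {
    skip("enrich", "needs miRNA ages and a nonempty network")
  }

  # evaluate: topology always; expression / stress / climate when supplied
  evaluation <- list()
  if (nrow(network$edges) > 0L) {
    evaluation$topology <- topology(network, percentile = percentile)
    utils::write.table(evaluation$topology$nodes,
                       file.path(config$out_dir, "topology_nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(config$expression)) {
    expr <- preprocess_expression(config$expression)
    evaluation$sweep <- threshold_sweep(profiles, expr, mode = mode)
    utils::write.table(as.data.frame(evaluation$sweep),
                       file.path(config$out_dir, "threshold_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else skip("evaluate:sweep", "no expression compendium supplied")
  if (!is.null(config$stress) && nrow(network$edges) > 0L) {
    set.seed(seed + 1L)
    evaluation$stress <- stress_share_test(network$edges, config$stress,
                                           n_perm = n_reps)
  } else skip("evaluate:stress", "no stress table supplied or empty network")
  if (!is.null(config$climate)) {
    groups <- dynamic_groups_for_climate(profiles)
    if (length(groups)) {
      evaluation$climate <- climate_sd_tests(groups, config$climate,
                                             n_perm = n_reps,
                                             seed = seed + 2L)
      utils::write.table(evaluation$climate,
                         file.path(config$out_dir, "climate_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else skip("evaluate:climate", "no dynamic regulation groups")
  } else skip("evaluate:climate", "no climate table supplied")
  done("evaluate")

  manifest <- list(
    parameters = list(threshold = threshold, mode = mode,
                      percentile = percentile, n_reps = n_reps, seed = seed),
    stages = stages,
    edge_list_md5 = unname(tools::md5sum(net_paths[["edges"]])))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(profiles = profiles, network = network,
                 evaluation = evaluation, manifest = manifest))
}

# ecotype gain/loss groups of dynamically co-regulated targets, keyed
# "target/mirna", for the climate stage
dynamic_groups_for_climate <- function(profiles, min_size = 2L) {
  regs <- profiles$regulations
  dyn <- which(regs$general_fate %in% c("KL", "G"))
  groups <- list()
  for (i in dyn) {
    sym <- if (regs$general_fate[i] == "KL") "l" else "g"
    ecos <- profiles$ecotypes[profiles$fates[i, ] == sym]
    if (length(ecos) >= min_size) {
      groups[[paste0(regs$transcript_id[i], "/", regs$mirna_id[i])]] <- ecos
    }
  }
  groups
}
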