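#' Topology report: hubs, bottlenecks, bridges
#'
#' Computes node degree, node betweenness and edge betweenness (shortest-path
#' betweenness, unnormalized, with multiplicity split evenly across the
#' shortest paths of a pair). Hubs are the top `percentile` of nodes by
#' degree, bottlenecks the top `percentile` by node betweenness, bridges the
#' top `percentile` of edges by edge betweenness; the top set is the first
#' `ceiling(percentile * N)` elements in descending order, extended through
#' value ties. Nodes are partitioned into four classes by the hub and
#' bottleneck flags.
#'
#' @param x A `crosstalk_network`, an igraph object, or an edge data frame
#'   (first two columns = endpoints).
#' @param percentile Top fraction for hub/bottleneck/bridge flags.
#' @return A `mirna_topology` object: list of `nodes` and `edges` tibbles.
#' @export
topology <- function(x, percentile = 0.15) {
  g <- if (inherits(x, "igraph")) x
  else if (inherits(x, "crosstalk_network")) as_igraph(x)
  else igraph::graph_from_data_frame(as.data.frame(x)[1:2], directed = FALSE)
  if (igraph::vcount(g) == 0L) abort("empty graph")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  ebt <- igraph::edge_betweenness(g, directed = FALSE)
  nodes <- tibble(node = igraph::V(g)$name,
                  degree = unname(deg),
                  betweenness = unname(btw)) %>%
    mutate(hub = top_frac_flag(.data$degree, percentile),
           bottleneck = top_frac_flag(.data$betweenness, percentile),
           node_class = dplyr::case_when(
             hub & bottleneck ~ "hub-bottleneck",
             hub & !bottleneck ~ "hub-nonbottleneck",
             !hub & bottleneck ~ "nonhub-bottleneck",
             TRUE ~ "nonhub-nonbottleneck"))
  el <- igraph::as_edgelist(g)
  edges <- tibble(from = el[, 1], to = el[, 2], betweenness = ebt) %>%
    mutate(bridge = top_frac_flag(.data$betweenness, percentile))
  structure(list(nodes = nodes, edges = edges, percentile = percentile),
            class = "mirna_topology")
}

# TRUE for the ceiling(p * n) largest values, extended through ties
top_frac_flag <- function(values, p) {
  n <- length(values)
  k <- min(n, ceiling(p * n))
  if (k == 0L) return(rep(FALSE, n))
  cut <- sort(values, decreasing = TRUE)[k]
  values >= cut
}

#' @export
print.mirna_topology <- function(x, ...) {
  cat("<mirna_topology> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges; ", sum(x$nodes$hub), " hubs, ", sum(x$nodes$bottleneck),
      " bottlenecks, ", sum(x$edges$bridge), " bridges (top ",
      x$percentile * 100, "%)\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname topology
#' @param type `"nodes"` or `"edges"`.
#' @param ... Unused.
tidy.mirna_topology <- function(x, type = c("nodes", "edges"), ...) {
  x[[match.arg(type)]]
}

#' Preprocess a miRNA expression compendium
#'
#' Averages replicate measurements per sample, log2-transforms the averaged
#' values (zero abundances are treated as missing, no pseudocount), and drops
#' miRNAs with values in fewer than 6 samples.
#'
#' @param raw Long tibble with columns `mirna_id`, `sample`, `value`
#'   (nonnegative abundance, e.g. reads per million) and optionally
#'   `replicate`.
#' @param min_samples Minimum number of samples with a value (default 6).
#' @return Wide tibble (`mirna_id` + one column per sample) of log2 values
#'   with `NA` for missing, class `mirna_expression`.
#' @export
preprocess_expression <- function(raw, min_samples = 6L) {
  raw <- as_tibble(raw)
  if (any(raw$value < 0, na.rm = TRUE)) abort("abundances must be nonnegative")
  avg <- raw %>%
    group_by(.data$mirna_id, .data$sample) %>%
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") %>%
    mutate(value = ifelse(.data$value > 0, log2(.data$value), NA_real_))
  kept <- avg %>%
    group_by(.data$mirna_id) %>%
    summarise(n_present = sum(!is.na(.data$value)), .groups = "drop") %>%
    filter(.data$n_present >= min_samples) %>%
    pull(.data$mirna_id)
  out <- avg %>%
    filter(.data$mirna_id %in% kept) %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "value")
  class(out) <- c("mirna_expression", class(out))
  out
}

expression_vector <- function(expr, mirna_id) {
  i <- which(expr$mirna_id == mirna_id)
  if (!length(i)) return(NULL)
  unlist(expr[i, -match("mirna_id", names(expr))])
}

#' Pairwise Pearson expression correlations
#'
#' Pearson correlation over the samples where both miRNAs have a value;
#' pairs with fewer than 3 common samples (or a missing profile) are skipped
#' with a warning. P-values are BH-adjusted over the emitted family.
#'
#' @param expr A `mirna_expression` wide tibble from
#'   [preprocess_expression()].
#' @param pairs Tibble with columns `mirna_i`, `mirna_j`.
#' @return Tibble: `mirna_i`, `mirna_j`, `n_samples`, `r`, `p_raw`, `p_adj`.
#' @export
pair_correlations <- function(expr, pairs) {
  mat <- as.matrix(expr[-match("mirna_id", names(expr))])
  rownames(mat) <- expr$mirna_id
  rows <- purrr::map(seq_len(nrow(pairs)), function(k) {
    i <- pairs$mirna_i[k]; j <- pairs$mirna_j[k]
    if (!i %in% rownames(mat) || !j %in% rownames(mat)) return(NULL)
    xi <- mat[i, ]; xj <- mat[j, ]
    ok <- !is.na(xi) & !is.na(xj)
    if (sum(ok) < 3L) return(NULL)
    if (sd(xi[ok]) == 0 || sd(xj[ok]) == 0) return(NULL)
    ct <- cor.test(xi[ok], xj[ok], method = "pearson")
    tibble(mirna_i = i, mirna_j = j, n_samples = sum(ok),
           r = unname(ct$estimate), p_raw = ct$p.value)
  })
  skipped <- sum(purrr::map_lgl(rows, is.null))
  if (skipped) {
    warn(paste0("pair_correlations: skipped ", skipped,
                " pair(s) with <3 common samples or missing profile"))
  }
  out <- bind_rows(rows)
  if (nrow(out)) out$p_adj <- bh_adjust(out$p_raw)
  out
}

#' Coreg threshold sweep against expression support
#'
#' For each threshold on a grid, partitions the miRNA pairs that share at
#' least one target into the "final" set (at least one motif surviving at
#' that threshold) and the "deleted" set (all motifs removed), and reports
#' the mean pairwise expression correlation of each set. A threshold where
#' the deleted set's mean correlation rises sharply while the final set
#' stays high is a natural operating point.
#'
#' @param profiles A `fate_profiles` object.
#' @param expr A `mirna_expression` tibble.
#' @param grid Thresholds in `[0, 1]`.
#' @param mode Coreg mode, see [coreg_score()].
#' @return A `threshold_sweep` tibble: `threshold`, `mean_r_final`,
#'   `mean_r_deleted`, `n_final_pairs`, `n_deleted_pairs`.
#' @export
threshold_sweep <- function(profiles, expr, grid = seq(0, 1, by = 0.05),
                            mode = c("extended", "literal")) {
  mode <- match.arg(mode)
  if (any(grid < 0 | grid > 1)) abort("grid must lie in [0, 1]")
  motifs <- coreg_motifs(profiles, mode)
  pairs <- distinct(motifs[c("mirna_i", "mirna_j")])
  cors <- suppressWarnings(pair_correlations(expr, pairs))
  pair_key <- function(a, b) paste(a, b, sep = "\r")
  r_of <- setNames(cors$r, pair_key(cors$mirna_i, cors$mirna_j))
  motif_pair <- pair_key(motifs$mirna_i, motifs$mirna_j)
  all_pairs <- unique(motif_pair)
  rows <- purrr::map(grid, function(th) {
    final <- unique(motif_pair[motifs$coreg >= th])
    deleted <- setdiff(all_pairs, final)
    tibble(threshold = th,
           mean_r_final = mean(r_of[final], na.rm = TRUE),
           mean_r_deleted = if (length(deleted))
             mean(r_of[deleted], na.rm = TRUE) else NA_real_,
           n_final_pairs = length(final),
           n_deleted_pairs = length(deleted))
  })
  out <- bind_rows(rows)
  out$mean_r_final[is.nan(out$mean_r_final)] <- NA_real_
  out$mean_r_deleted[is.nan(out$mean_r_deleted)] <- NA_real_
  class(out) <- c("threshold_sweep", class(out))
  out
}

#' @export
#' @rdname threshold_sweep
#' @param object A `threshold_sweep` tibble.
#' @param ... Unused.
autoplot.threshold_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("threshold", "mean_r_final", "mean_r_deleted")],
    cols = c("mean_r_final", "mean_r_deleted"),
    names_to = "set", values_to = "mean_r")
  long$set <- ifelse(long$set == "mean_r_final", "final", "deleted")
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$mean_r,
                                     colour = .data$set)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(final = "red3",
                                            deleted = "darkgreen")) +
    ggplot2::labs(x = "coreg threshold", y = "mean Pearson r", colour = NULL)
}

#' Stress-sharing fraction of network edges with an empirical p-value
#'
#' Fraction of edges whose two miRNAs are annotated with at least one common
#' stress type, compared against same-size uniform samples of unordered
#' miRNA pairs from the pair universe.
#'
#' @param edges Edge tibble (`mirna_i`, `mirna_j`).
#' @param stress_table Tibble with columns `mirna_id`, `stress` (one row per
#'   association).
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @param universe Character vector of miRNA ids to draw null pairs from;
#'   defaults to the union of annotated miRNAs and edge endpoints.
#' @return Tibble: `fraction_sharing`, `p_empirical`, `n_edges`, `n_perm`.
#' @export
stress_share_test <- function(edges, stress_table, n_perm = 1000L,
                              seed = NULL, universe = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stress_sets <- split(stress_table$stress, stress_table$mirna_id)
  shares <- function(a, b) {
    sa <- stress_sets[[a]]; sb <- stress_sets[[b]]
    !is.null(sa) && !is.null(sb) && length(intersect(sa, sb)) > 0L
  }
  obs <- mean(purrr::map2_lgl(edges$mirna_i, edges$mirna_j, shares))
  universe <- universe %||%
    union(names(stress_sets), c(edges$mirna_i, edges$mirna_j))
  k <- nrow(edges)
  null_frac <- purrr::map_dbl(seq_len(n_perm), function(r) {
    a <- sample(universe, k, replace = TRUE)
    b <- purrr::map_chr(a, function(x) sample(setdiff(universe, x), 1L))
    mean(purrr::map2_lgl(a, b, shares))
  })
  tibble(fraction_sharing = obs,
         p_empirical = mean(null_frac >= obs),
         n_edges = k, n_perm = n_perm)
}

#' Climatic similarity of an ecotype group (SD permutation test)
#'
#' Tests whether a group of ecotypes experiences unusually similar values of
#' a bioclimatic variable: the observed standard deviation is compared to
#' the SD of `n_perm` uniform same-size samples of ecotypes, and the
#' empirical p-value is the fraction of permutations with a strictly smaller
#' SD (zero is a legal p-value; no pseudocount).
#'
#' @param group Character vector of ecotype ids (length >= 2).
#' @param climate_table Tibble with an `ecotype` column and one column per
#'   bioclimatic variable.
#' @param variable Variable (column) name.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return One-row tibble: `variable`, `n_group`, `sd_observed`,
#'   `p_empirical`.
#' @export
climate_sd_test <- function(group, climate_table, variable, n_perm = 1000L,
                            seed = NULL) {
  if (length(group) < 2L) abort("group must contain at least 2 ecotypes")
  if (!variable %in% names(climate_table)) {
    abort(paste0("variable not in climate table: ", variable))
  }
  if (!is.null(seed)) set.seed(seed)
  vals <- setNames(climate_table[[variable]], climate_table$ecotype)
  missing <- setdiff(group, names(vals))
  if (length(missing)) {
    abort(paste0("ecotypes missing from climate table: ",
                 paste(missing, collapse = ", ")))
  }
  sd_obs <- sd(vals[group])
  k <- length(group)
  sd_perm <- purrr::map_dbl(seq_len(n_perm), function(r) {
    sd(vals[sample.int(length(vals), k)])
  })
  tibble(variable = variable, n_group = k, sd_observed = sd_obs,
         p_empirical = mean(sd_perm < sd_obs))
}

#' Climate SD tests over many groups and variables with BH adjustment
#'
#' @param groups Named list of ecotype-id vectors.
#' @param climate_table See [climate_sd_test()].
#' @param variables Variable names; defaults to all non-coordinate columns.
#' @param n_perm,seed See [climate_sd_test()].
#' @return Tibble with one row per (group, variable): adds `group` and
#'   `p_adj` (BH across the whole emitted family).
#' @export
climate_sd_tests <- function(groups, climate_table, variables = NULL,
                             n_perm = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  variables <- variables %||%
    setdiff(names(climate_table), c("ecotype", "lat", "lon"))
  out <- purrr::map(names(groups), function(g) {
    bind_rows(purrr::map(variables, function(v) {
      mutate(climate_sd_test(groups[[g]], climate_table, v, n_perm = n_perm),
             group = g, .before = 1)
    }))
  })
  out <- bind_rows(out)
  out$p_adj <- bh_adjust(out$p_empirical)
  out
}

#' Gain/loss ecotype groups of a dynamically regulated target
#'
#' For every dynamic regulation (general fate `KL` or `G`) toward a target,
#' returns the set of ecotypes in which it is lost (`l`, for `KL`) or gained
#' (`g`, for `G`), plus the pairwise overlaps of those sets — the question
#' being whether multiple dynamic regulations toward one transcript are
#' reprogrammed in the same ecotype group.
#'
#' @param profiles A `fate_profiles` object.
#' @param target_t Transcript id with at least one dynamic regulation.
#' @return List with `groups` (tibble: `mirna_id`, `general_fate`,
#'   `ecotypes` list-column, `n`) and `overlap` (tibble of pairwise
#'   intersection sizes and Jaccard indices).
#' @export
dynamic_ecotype_groups <- function(profiles, target_t) {
  regs <- profiles$regulations
  idx <- which(regs$transcript_id == target_t &
                 regs$general_fate %in% c("KL", "G"))
  if (!length(idx)) abort("target has no dynamic regulation")
  groups <- purrr::map(idx, function(i) {
    sym <- if (regs$general_fate[i] == "KL") "l" else "g"
    ecos <- profiles$ecotypes[profiles$fates[i, ] == sym]
    tibble(mirna_id = regs$mirna_id[i], general_fate = regs$general_fate[i],
           ecotypes = list(ecos), n = length(ecos))
  })
  groups <- bind_rows(groups)
  overlap <- if (nrow(groups) >= 2L) {
    prs <- combn(nrow(groups), 2L)
    bind_rows(purrr::map(seq_len(ncol(prs)), function(c) {
      a <- groups$ecotypes[[prs[1, c]]]; b <- groups$ecotypes[[prs[2, c]]]
      tibble(mirna_i = groups$mirna_id[prs[1, c]],
             mirna_j = groups$mirna_id[prs[2, c]],
             n_overlap = length(intersect(a, b)),
             jaccard = if (length(union(a, b)))
               length(intersect(a, b)) / length(union(a, b)) else NA_real_)
    }))
  } else {
    tibble(mirna_i = character(), mirna_j = character(),
           n_overlap = integer(), jaccard = numeric())
  }
  list(groups = groups, overlap = overlap)
}
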