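#' Randomization Z-score and normal p-value
#'
#' `z = (x_obs - mean(rand)) / sd(rand)` over a vector of randomized counts;
#' the p-value is the two-sided normal tail `2 * min(pnorm(z), 1 - pnorm(z))`
#' (one-sided upper tail available by flag). Cells with zero randomization
#' spread report `z = NA` and `p = 1` (conservative) rather than an infinite
#' Z-score.
#'
#' @param x_obs Observed count.
#' @param rand_counts Nonempty numeric vector of randomized counts.
#' @param alternative `"two.sided"` or `"greater"`.
#' @return Named list with `z` and `p_raw`.
#' @export
zscore <- function(x_obs, rand_counts, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(rand_counts)) abort("rand_counts must be nonempty")
  s <- sd(rand_counts)
  if (is.na(s) || s == 0) return(list(z = NA_real_, p_raw = 1))
  z <- (x_obs - mean(rand_counts)) / s
  p <- if (alternative == "two.sided") 2 * min(pnorm(z), 1 - pnorm(z))
  else 1 - pnorm(z)
  list(z = z, p_raw = min(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate control with monotonicity
#' enforcement, order-preserving with respect to the input indexing.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must be in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Shuffle general fates over a regulation network
#'
#' Randomly reassigns the edges' general fates while keeping the topology
#' fixed; the multiset of fates is preserved exactly.
#'
#' @param edges Tibble with a `general_fate` column.
#' @return The edge tibble with `general_fate` permuted.
#' @export
randomize_fate_assignment <- function(edges) {
  edges$general_fate <- sample(edges$general_fate)
  edges
}

#' Permute node identifiers over a fixed topology
#'
#' Relabels the nodes of an edge list through a uniform permutation of the
#' node identifiers; the degree sequence and any per-node annotation
#' multiset (e.g. ages) are preserved.
#'
#' @param edges Tibble with columns `mirna_i`, `mirna_j`.
#' @return The edge tibble with endpoints relabeled.
#' @export
randomize_node_labels <- function(edges) {
  nodes <- unique(c(edges$mirna_i, edges$mirna_j))
  perm <- setNames(sample(nodes), nodes)
  edges$mirna_i <- unname(perm[edges$mirna_i])
  edges$mirna_j <- unname(perm[edges$mirna_j])
  edges
}

#' Uniform edge subsample
#'
#' @param edges Edge tibble.
#' @param k Number of edges to draw without replacement (`k <= nrow(edges)`).
#' @return A tibble of `k` sampled edges.
#' @export
randomize_edge_sample <- function(edges, k) {
  if (k > nrow(edges)) abort("k exceeds the number of edges")
  edges[sample.int(nrow(edges), k), , drop = FALSE]
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' @param a,b,c,d Nonnegative integer cell counts, row-wise.
#' @return The exact two-sided p-value (1 for an all-zero table).
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("cell counts must be nonnegative")
  if (all(cells == 0)) return(1)
  fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

#' Randomization enrichment matrix
#'
#' Compares observed category-pair edge counts against counts in randomized
#' networks, one Z-score and normal p-value per cell, with BH adjustment
#' across all cells of the matrix jointly (the multiple-testing family is
#' one matrix).
#'
#' Three randomization schemes are supported:
#' * `"fate_shuffle"` - edges carry a `stratum` column (e.g. the general
#'   fate) plus endpoint categories; each randomization permutes the strata
#'   over the fixed topology. Cells are (stratum, row category, column
#'   category) with ordered endpoints (e.g. miRNA age x target age).
#' * `"label_permute"` - node identifiers are permuted over the fixed
#'   topology (degree sequence and category multiset preserved). Cells are
#'   unordered category pairs.
#' * `"edge_sample"` - for each stratum (e.g. crosstalk type) with `k`
#'   observed edges, each randomization draws `k` edges uniformly from the
#'   whole network. Cells are (stratum, unordered category pair).
#'
#' @param edges Edge tibble with columns `mirna_i`, `mirna_j` and, for the
#'   stratified schemes, `stratum`.
#' @param categories Node categories: a named vector `node -> category`, or
#'   a list `list(from = , to = )` of two named vectors for ordered
#'   (bipartite-style) matrices.
#' @param scheme Randomization scheme.
#' @param n_reps Number of randomizations (default 1000).
#' @param seed Optional integer seed.
#' @param alternative Passed to [zscore()].
#' @return A `mirna_enrichment` tibble: `stratum`, `row_category`,
#'   `col_category`, `x_observed`, `rand_mean`, `rand_sd`, `z`, `p_raw`,
#'   `p_adj`.
#' @export
enrichment_matrix <- function(edges, categories,
                              scheme = c("fate_shuffle", "label_permute",
                                         "edge_sample"),
                              n_reps = 1000L, seed = NULL,
                              alternative = "two.sided") {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  edges <- as_tibble(edges)
  if (n_reps < 1L) abort("n_reps must be >= 1")
  cat_from <- if (is.list(categories)) categories$from else categories
  cat_to <- if (is.list(categories)) categories$to else categories
  ordered <- is.list(categories)
  cell_of <- function(e) {
    ci <- unname(cat_from[e$mirna_i]); cj <- unname(cat_to[e$mirna_j])
    if (!ordered) {
      lo <- pmin(ci, cj); hi <- pmax(ci, cj)
      ci <- lo; cj <- hi
    }
    paste(ci, cj, sep = "\r")
  }
  pair_levels <- {
    u_from <- sort(unique(unname(cat_from[c(edges$mirna_i,
                                            if (!ordered) edges$mirna_j)])))
    u_to <- sort(unique(unname(cat_to[c(edges$mirna_j,
                                        if (!ordered) edges$mirna_i)])))
    grid <- expand.grid(from = u_from, to = u_to, stringsAsFactors = FALSE)
    if (!ordered) grid <- grid[grid$from <= grid$to, , drop = FALSE]
    paste(grid$from, grid$to, sep = "\r")
  }
  strata <- if (scheme == "label_permute") rep("all", nrow(edges))
  else {
    if (!"stratum" %in% names(edges)) {
      abort(paste0("scheme ", scheme, " needs a 'stratum' edge column"))
    }
    as.character(edges$stratum)
  }
  s_levels <- sort(unique(strata))
  cell_levels <- as.vector(outer(s_levels, pair_levels, paste, sep = "\r"))
  count_cells <- function(strat, pair) {
    tabulate(match(paste(strat, pair, sep = "\r"), cell_levels),
             nbins = length(cell_levels))
  }
  obs_pair <- cell_of(edges)
  obs <- count_cells(strata, obs_pair)
  rand <- matrix(0L, nrow = length(cell_levels), ncol = n_reps)
  for (r in seq_len(n_reps)) {
    rand[, r] <- switch(
      scheme,
      fate_shuffle = count_cells(sample(strata), obs_pair),
      label_permute = count_cells(strata, cell_of(randomize_node_labels(edges))),
      edge_sample = {
        counts <- integer(length(cell_levels))
        for (s in s_levels) {
          k <- sum(strata == s)
          drawn <- obs_pair[sample.int(nrow(edges), k)]
          counts <- counts + count_cells(rep(s, k), drawn)
        }
        counts
      })
  }
  parts <- strsplit(cell_levels, "\r", fixed = TRUE)
  res <- tibble(
    stratum = purrr::map_chr(parts, 1),
    row_category = purrr::map_chr(parts, 2),
    col_category = purrr::map_chr(parts, 3),
    x_observed = obs,
    rand_mean = rowMeans(rand),
    rand_sd = apply(rand, 1, sd))
  zs <- purrr::map2(res$x_observed, seq_len(nrow(res)), function(x, i) {
    zscore(x, rand[i, ], alternative = alternative)
  })
  res$z <- purrr::map_dbl(zs, "z")
  res$p_raw <- purrr::map_dbl(zs, "p_raw")
  res$p_adj <- bh_adjust(res$p_raw)
  class(res) <- c("mirna_enrichment", class(res))
  res
}

#' Heatmap of an enrichment matrix
#'
#' @param object A `mirna_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot object: tiles colored by Z-score, faceted by stratum,
#'   significant cells (adjusted p < 0.05) starred.
#' @export
autoplot.mirna_enrichment <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$col_category, .data$row_category,
                               fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(!is.na(.data$p_adj) & .data$p_adj < 0.05, "*", ""))) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "red3", na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z")
}
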