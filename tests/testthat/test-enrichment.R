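test_that("Z-score and normal p-value follow the definition", {
  out <- zscore(10, c(3, 5, 7))  # mean 5, sd 2
  expect_equal(out$z, 2.5)
  expect_equal(out$p_raw, 2 * (1 - pnorm(2.5)), tolerance = 1e-12)
  expect_equal(out$p_raw, 0.01242, tolerance = 1e-3)
  degenerate <- zscore(4, rep(4, 100))
  expect_true(is.na(degenerate$z))
  expect_equal(degenerate$p_raw, 1)
  expect_error(zscore(1, numeric()), "nonempty")
  one_sided <- zscore(10, c(3, 5, 7), alternative = "greater")
  expect_equal(one_sided$p_raw, 1 - pnorm(2.5))
})

test_that("BH adjustment matches an independent textbook implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.5, 10)), rep(0.5, 10))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    got <- bh_adjust(p)
    want <- oracle_bh(p)
    expect_equal(got, want, tolerance = 1e-12)
    # monotone nondecreasing on sorted raw p, never below raw p
    expect_true(all(diff(got[order(p)]) >= -1e-12))
    expect_true(all(got >= p - 1e-12))
  }
})

test_that("fate shuffling preserves the fate multiset and topology", {
  edges <- tibble::tibble(mirna_i = letters[1:5], mirna_j = letters[6:10],
                          general_fate = c("K", "K", "K", "G", "G"))
  set.seed(1)
  r <- randomize_fate_assignment(edges)
  expect_equal(sort(r$general_fate), sort(edges$general_fate))
  expect_equal(r$mirna_i, edges$mirna_i)
  # determinism under seed
  set.seed(99); a <- randomize_fate_assignment(edges)$general_fate
  set.seed(99); b <- randomize_fate_assignment(edges)$general_fate
  expect_identical(a, b)
  # uniformity: each fate lands on each edge position at ~equal frequency
  set.seed(5)
  hits <- replicate(3000, randomize_fate_assignment(edges)$general_fate[1])
  expect_equal(mean(hits == "G"), 0.4, tolerance = 0.05)
})

test_that("node-label permutation preserves degrees and label multiset", {
  edges <- tibble::tibble(mirna_i = c("a", "a", "b", "c"),
                          mirna_j = c("b", "c", "c", "d"))
  deg <- function(e) sort(table(c(e$mirna_i, e$mirna_j)))
  set.seed(2)
  r <- randomize_node_labels(edges)
  expect_equal(unname(deg(r)), unname(deg(edges)))
  expect_setequal(c(r$mirna_i, r$mirna_j), c("a", "b", "c", "d"))
  expect_equal(nrow(r), nrow(edges))
})

test_that("edge sampling is uniform without replacement", {
  edges <- tibble::tibble(mirna_i = letters[1:10], mirna_j = LETTERS[1:10])
  expect_equal(nrow(randomize_edge_sample(edges, 10)), 10L)
  expect_equal(nrow(randomize_edge_sample(edges, 0)), 0L)
  expect_error(randomize_edge_sample(edges, 11), "exceeds")
  set.seed(3)
  freq <- rowMeans(replicate(2000, {
    letters[1:10] %in% randomize_edge_sample(edges, 3)$mirna_i
  }))
  expect_true(all(abs(freq - 0.3) < 0.05))
})

test_that("Fisher 2x2 matches the exact hypergeometric computation", {
  expect_equal(fisher_2x2(3, 1, 1, 3), 0.4857, tolerance = 1e-4)
  expect_equal(fisher_2x2(0, 0, 0, 0), 1)
  expect_equal(fisher_2x2(3, 1, 1, 3), fisher_2x2(3, 1, 1, 3))
  # symmetric under transpose
  expect_equal(fisher_2x2(5, 2, 7, 3), fisher_2x2(5, 7, 2, 3))
  expect_error(fisher_2x2(-1, 0, 0, 0), "nonnegative")
})

test_that("a planted excess of within-category edges is detected", {
  set.seed(17)
  nodes <- paste0("n", 1:40)
  cats <- setNames(rep(c("old", "young"), each = 20), nodes)
  # plant: many old-old edges, few cross edges
  old <- nodes[1:20]; young <- nodes[21:40]
  mk <- function(pool_a, pool_b, k) {
    tibble::tibble(mirna_i = sample(pool_a, k, TRUE),
                   mirna_j = sample(pool_b, k, TRUE))
  }
  edges <- dplyr::distinct(dplyr::bind_rows(
    mk(old, old, 60), mk(young, young, 10), mk(old, young, 10)))
  edges <- edges[edges$mirna_i != edges$mirna_j, ]
  res <- enrichment_matrix(edges, cats, scheme = "label_permute",
                           n_reps = 300, seed = 7)
  cell <- res[res$row_category == "old" & res$col_category == "old", ]
  expect_gt(cell$z, 2)
  expect_lt(cell$p_adj, 0.05)
  # all cells carry finite observations and BH within the family
  expect_equal(res$p_adj, bh_adjust(res$p_raw))
})

test_that("stratified fate-shuffle matrices count what they should", {
  set.seed(19)
  edges <- tibble::tibble(
    mirna_i = sample(paste0("m", 1:6), 40, TRUE),
    mirna_j = sample(paste0("t", 1:6), 40, TRUE),
    stratum = sample(c("K", "KL", "G"), 40, TRUE))
  cats <- list(from = setNames(rep(c("cm1", "cm2"), each = 3), paste0("m", 1:6)),
               to = setNames(rep(c("ct1", "ct2"), each = 3), paste0("t", 1:6)))
  res <- enrichment_matrix(edges, cats, scheme = "fate_shuffle",
                           n_reps = 100, seed = 11)
  # cells form the full stratum x row x col grid
  expect_equal(nrow(res), 3L * 2L * 2L)
  expect_equal(sum(res$x_observed), nrow(edges))
  # randomization preserves per-pair totals: mean counts per cell group sum
  per_pair <- res %>% dplyr::group_by(row_category, col_category) %>%
    dplyr::summarise(obs = sum(x_observed), rand = sum(rand_mean),
                     .groups = "drop")
  expect_equal(per_pair$rand, per_pair$obs, tolerance = 1e-9)
})
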