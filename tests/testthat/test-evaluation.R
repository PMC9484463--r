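test_that("betweenness on canonical small graphs", {
  # path a-b-c: b carries the single a<->c shortest path
  path3 <- tibble::tibble(from = c("a", "b"), to = c("b", "c"))
  top <- topology(path3, percentile = 0.34)
  expect_equal(top$nodes$betweenness[top$nodes$node == "b"], 1)
  expect_equal(top$nodes$betweenness[top$nodes$node == "a"], 0)
  # star with 3 leaves: center carries C(3,2) = 3 pair paths
  star <- tibble::tibble(from = "hub", to = c("l1", "l2", "l3"))
  ts <- topology(star)
  expect_equal(ts$nodes$betweenness[ts$nodes$node == "hub"], 3)
  expect_error(topology(igraph::make_empty_graph(0)), "empty graph")
})

test_that("betweenness agrees with the path-enumeration oracle", {
  set.seed(41)
  for (i in 1:12) {
    n <- sample(6:12, 1)
    adj <- matrix(FALSE, n, n)
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (runif(1) < 0.3) adj[a, b] <- adj[b, a] <- TRUE
    }
    if (!any(adj)) next
    el <- which(adj & upper.tri(adj), arr.ind = TRUE)
    edges <- tibble::tibble(from = paste0("v", el[, 1]),
                            to = paste0("v", el[, 2]))
    top <- topology(edges)
    want <- oracle_betweenness(adj)
    present <- sort(unique(c(el[, 1], el[, 2])))
    got_node <- setNames(top$nodes$betweenness, top$nodes$node)
    expect_equal(unname(got_node[paste0("v", present)]),
                 want$node[present], tolerance = 1e-9)
    for (k in seq_len(nrow(top$edges))) {
      a <- as.integer(sub("v", "", top$edges$from[k]))
      b <- as.integer(sub("v", "", top$edges$to[k]))
      expect_equal(top$edges$betweenness[k],
                   want$edge[min(a, b), max(a, b)], tolerance = 1e-9)
    }
  }
})

test_that("top-15% flags use ceiling with tie extension and classes partition", {
  edges <- tibble::tibble(from = paste0("n", 1:10),
                          to = paste0("n", c(2:10, 1)))
  top <- topology(edges, percentile = 0.15)
  # ring: all degrees tie at 2, so tie extension flags everyone
  expect_true(all(top$nodes$hub))
  # 10 nodes at 15% -> ceil(1.5) = 2 before tie extension
  expect_equal(ceiling(0.15 * 10), 2)
  expect_true(all(top$nodes$node_class %in%
                    c("hub-bottleneck", "hub-nonbottleneck",
                      "nonhub-bottleneck", "nonhub-nonbottleneck")))
  star <- tibble::tibble(from = "hub", to = paste0("l", 1:9))
  # k = ceil(0.05 * 10) = 1 and the center's degree is unique: only the hub
  ts <- topology(star, percentile = 0.05)
  expect_equal(sum(ts$nodes$hub), 1L)
  expect_true(ts$nodes$hub[ts$nodes$node == "hub"])
  # at 15% the cut falls among the tied leaves and ties extend the set
  ts15 <- topology(star, percentile = 0.15)
  expect_equal(sum(ts15$nodes$hub), 10L)
})

test_that("expression preprocessing averages, logs, and filters", {
  raw <- tibble::tibble(
    mirna_id = c(rep("mA", 12), rep("mB", 5)),
    sample = c(rep(paste0("s", 1:6), each = 2), paste0("s", 1:5)),
    replicate = c(rep(c("r1", "r2"), 6), rep("r1", 5)),
    value = c(rbind(rep(4, 6), rep(8, 6)), rep(2, 5)))
  expr <- preprocess_expression(raw)
  expect_equal(expr$mirna_id, "mA")             # mB in 5 samples: dropped
  expect_equal(unname(unlist(expr[1, -1])), rep(log2(6), 6))
  raw6 <- raw
  raw6$value[17] <- 3
  raw6 <- dplyr::bind_rows(raw6, tibble::tibble(
    mirna_id = "mB", sample = "s6", replicate = "r1", value = 2))
  expect_equal(nrow(preprocess_expression(raw6)), 2L)  # 6 samples: retained
  bad <- raw; bad$value[1] <- -1
  expect_error(preprocess_expression(bad), "nonnegative")
  # zeros are missing, not -Inf
  z <- raw; z$value[z$sample == "s1" & z$mirna_id == "mA"] <- 0
  out <- suppressWarnings(preprocess_expression(z, min_samples = 3))
  expect_true(is.na(out$s1[out$mirna_id == "mA"]))
})

test_that("pair correlations hit the analytic anchors", {
  expr <- tibble::tibble(mirna_id = c("up", "up2", "down"),
                         s1 = c(1, 1, 4), s2 = c(2, 2, 3),
                         s3 = c(3, 3, 2), s4 = c(4, 4, 1))
  class(expr) <- c("mirna_expression", class(expr))
  pairs <- tibble::tibble(mirna_i = c("up", "up"), mirna_j = c("up2", "down"))
  out <- pair_correlations(expr, pairs)
  expect_equal(out$r, c(1, -1), tolerance = 1e-12)
  skip_pairs <- tibble::tibble(mirna_i = "up", mirna_j = "absent")
  expect_warning(empty <- pair_correlations(expr, skip_pairs), "skipped")
  expect_equal(nrow(empty), 0L)
})

test_that("planted correlation structure is recovered from the generator", {
  panel <- small_panel()
  raw <- generate_expression(panel)
  expr <- preprocess_expression(raw)
  coop <- panel$truth[panel$truth$planted, ]
  got <- pair_correlations(expr, coop[c("mirna_i", "mirna_j")])
  expect_true(all(got$r > 0.6))   # rho_high = 0.9
  # background pairs stay near zero on average
  others <- tibble::tibble(mirna_i = coop$mirna_i,
                           mirna_j = rev(coop$mirna_j))
  others <- others[others$mirna_i != others$mirna_j, ]
  bg <- pair_correlations(expr, others)
  expect_lt(mean(abs(bg$r)), 0.4)
})

test_that("threshold sweep separates concordant from discordant pairs", {
  panel <- small_panel()
  prof <- small_profiles()
  expr <- preprocess_expression(generate_expression(panel))
  sweep <- suppressWarnings(
    threshold_sweep(prof, expr, grid = c(0, 0.5, 0.85, 1)))
  expect_s3_class(sweep, "threshold_sweep")
  # vacuous filter: nothing deleted
  expect_equal(sweep$n_deleted_pairs[1], 0L)
  expect_true(is.na(sweep$mean_r_deleted[1]))
  # monotone: final pair count nonincreasing in the threshold
  expect_true(all(diff(sweep$n_final_pairs) <= 0))
  # planted gap: cooperative (high-rho) pairs survive at 0.85, discordant do not
  row <- sweep[sweep$threshold == 0.85, ]
  expect_gt(row$mean_r_final, row$mean_r_deleted)
})

test_that("stress sharing fraction and empirical p behave at the anchors", {
  edges <- tibble::tibble(mirna_i = c("a", "b"), mirna_j = c("b", "c"))
  stress <- tibble::tibble(mirna_id = c("a", "b", "c"),
                           stress = c("drought", "drought", "cold"))
  out <- stress_share_test(edges, stress, n_perm = 50, seed = 1)
  expect_equal(out$fraction_sharing, 0.5)  # a-b share drought; b-c none
  none <- stress_share_test(edges, stress[0, ], n_perm = 20, seed = 1)
  expect_equal(none$fraction_sharing, 0)
  expect_equal(none$p_empirical, 1)
  # planted enrichment: annotated clique vs sparse universe
  set.seed(8)
  shared <- paste0("s", 1:8)
  lone <- paste0("u", 1:40)
  stress2 <- dplyr::bind_rows(
    tibble::tibble(mirna_id = shared, stress = "heat"),
    tibble::tibble(mirna_id = lone, stress = paste0("x", seq_along(lone))))
  e2 <- tibble::tibble(mirna_i = shared[c(1, 3, 5, 7, 1, 2)],
                       mirna_j = shared[c(2, 4, 6, 8, 3, 4)])
  res <- stress_share_test(e2, stress2, n_perm = 300, seed = 2)
  expect_equal(res$fraction_sharing, 1)
  expect_lt(res$p_empirical, 0.05)
})

test_that("climate SD test arithmetic and input checking", {
  climate <- tibble::tibble(ecotype = paste0("e", 1:50),
                            temperature_seasonality = c(rep(0.01, 5),
                                                        rnorm(45, 0, 10)))
  tight <- paste0("e", 1:5)
  out <- climate_sd_test(tight, climate, "temperature_seasonality",
                         n_perm = 200, seed = 3)
  expect_equal(out$p_empirical, 0)  # tighter than every permutation
  expect_error(climate_sd_test("e1", climate, "temperature_seasonality"),
               "at least 2")
  expect_error(climate_sd_test(tight, climate, "nope"), "not in climate")
  multi <- climate_sd_tests(list(g1 = tight, g2 = paste0("e", 6:10)),
                            climate, "temperature_seasonality",
                            n_perm = 100, seed = 4)
  expect_equal(nrow(multi), 2L)
  expect_equal(multi$p_adj, bh_adjust(multi$p_empirical))
})

test_that("dynamic ecotype groups report gain/loss sets and overlaps", {
  prof <- small_profiles()
  truth <- small_panel()$truth
  dd <- truth[truth$class == "dd_loss", ][1, ]
  out <- dynamic_ecotype_groups(prof, dd$target)
  expect_equal(nrow(out$groups), 2L)
  expect_setequal(out$groups$ecotypes[[1]], dd$cluster[[1]])
  expect_setequal(out$groups$ecotypes[[2]], dd$cluster[[1]])
  expect_equal(out$overlap$n_overlap, length(dd$cluster[[1]]))
  ss <- truth[truth$class == "ss", ][1, ]
  expect_error(dynamic_ecotype_groups(prof, ss$target), "no dynamic")
})
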