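test_that("coreg score anchors: identity, discordance, counted example", {
  ident <- fate_profile("m1", "t", rep("k", 10), TRUE)
  ident2 <- fate_profile("m2", "t", rep("k", 10), TRUE)
  expect_equal(coreg_score(ident, ident2), 1)

  f2 <- rep("l", 10); f2[1] <- "k"  # KL partner disagreeing except nowhere
  disc <- fate_profile("m2", "t", c("l", rep("o", 9)), TRUE, general = "KL")
  expect_equal(coreg_score(ident, disc), 0)

  # 10 ecotypes, joint fates (k,k)x7, (k,l)x2, (l,l)x1, both KL -> 0.8
  fi <- c(rep("k", 7), "k", "k", "l")
  fj <- c(rep("k", 7), "l", "l", "l")
  pi <- fate_profile("m1", "t", fi, TRUE, general = "KL")
  pj <- fate_profile("m2", "t", fj, TRUE, general = "KL")
  expect_equal(coreg_score(pi, pj), 0.8)
})

test_that("KL/KL with disjoint losses is forced to zero", {
  fi <- c("l", "l", rep("k", 8))
  fj <- c(rep("k", 8), "l", "l")
  pi <- fate_profile("m1", "t", fi, TRUE)
  pj <- fate_profile("m2", "t", fj, TRUE)
  expect_equal(pi$general_fate, "KL")
  # naive agreement would be 6/10, but EcoL is empty
  expect_equal(coreg_score(pi, pj), 0)
})

test_that("extended mode counts joint absence and guards G/G; literal does not", {
  n <- 50L
  fi <- rep("n", n); fi[1:5] <- "g"
  fj <- rep("n", n); fj[1:5] <- "g"
  pi <- fate_profile("m1", "t", fi, FALSE)
  pj <- fate_profile("m2", "t", fj, FALSE)
  expect_equal(coreg_score(pi, pj, mode = "extended"), 1)
  expect_equal(coreg_score(pi, pj, mode = "literal"), 5 / n)
  # disjoint gains: extended forces 0
  fk <- rep("n", n); fk[6:10] <- "g"
  pk <- fate_profile("m3", "t", fk, FALSE)
  expect_equal(coreg_score(pi, pk, mode = "extended"), 0)
  # joint (o,o) is never agreement
  fo <- rep("k", 10); fo[1] <- "o"
  po1 <- fate_profile("m1", "t", fo, TRUE)
  po2 <- fate_profile("m2", "t", fo, TRUE)
  expect_equal(coreg_score(po1, po2), 0.9)
})

test_that("coreg matches the brute-force joint-fate counter on random draws", {
  set.seed(33)
  for (i in 1:300) {
    mode <- if (i %% 2) "extended" else "literal"
    pi <- draw_profile(25, mirna = "m1")
    pj <- draw_profile(25, mirna = "m2")
    got <- suppressWarnings(coreg_score(pi, pj, mode = mode))
    want <- oracle_coreg(pi$fates, pj$fates, pi$general_fate, pj$general_fate,
                         mode)
    expect_identical(got, want)
    # symmetry
    expect_identical(suppressWarnings(coreg_score(pj, pi, mode = mode)), got)
    # bounds
    if (!is.na(got)) expect_true(got >= 0 && got <= 1)
  }
})

test_that("empty shared universe yields NA with a warning", {
  pi <- fate_profile("m1", "t", c("k", "."), TRUE, general = "K")
  pj <- fate_profile("m2", "t", c(".", "k"), TRUE, general = "K")
  expect_warning(out <- coreg_score(pi, pj), "empty shared ecotype universe")
  expect_true(is.na(out))
})

test_that("motif co-regulation types follow the general-fate grid", {
  expect_equal(motif_coreg_type("K", "K"), "ss")
  expect_equal(motif_coreg_type("K", "KL"), "sd")
  expect_equal(motif_coreg_type("KL", "K"), "sd")
  expect_equal(motif_coreg_type("KL", "KL"), "dd")
  expect_equal(motif_coreg_type("G", "G"), "dd")
  expect_equal(motif_coreg_type("K", "G"), "excluded")
  expect_equal(motif_coreg_type("KL", "G"), "excluded")
  expect_equal(motif_coreg_type("L", "K"), "excluded")
})

test_that("crosstalk type requires a strict majority", {
  expect_equal(crosstalk_type(c(rep("dd", 16), rep("ss", 2))), "DD")
  expect_equal(crosstalk_type(c(rep("ss", 12), "dd")), "SS")
  expect_equal(crosstalk_type(c(rep("ss", 5), rep("sd", 5))), "unclassified")
  expect_equal(crosstalk_type("sd"), "SD")
  expect_error(crosstalk_type(character()), "at least one")
})

test_that("shared targets come from profile co-membership", {
  prof <- small_profiles()
  truth <- small_panel()$truth
  row <- truth[truth$class == "ss", ][1, ]
  expect_equal(shared_targets(prof, row$mirna_i, row$mirna_j), row$target)
  expect_equal(length(shared_targets(prof, row$mirna_i, "mir999")), 0L)
  expect_error(shared_targets(prof, "a", "a"), "must differ")
})

test_that("network filtering honors the threshold at both extremes", {
  prof <- small_profiles()
  net0 <- suppressWarnings(build_network(prof, threshold = 0))
  expect_equal(nrow(net0$deleted_pairs), 0L)
  expect_equal(nrow(net0$edges), nrow(net0$unfiltered_pairs))
  net1 <- suppressWarnings(build_network(prof, threshold = 1))
  expect_true(all(net1$motifs$coreg[net1$motifs$surviving] == 1))
  expect_error(build_network(prof, threshold = 1.5), "threshold")

  # default threshold separates the planted from the discordant pairs
  net <- suppressWarnings(build_network(prof, threshold = 0.85))
  truth <- small_panel()$truth
  planted <- truth[truth$planted, ]
  disc <- truth[!truth$planted, ]
  key <- function(a, b) paste(a, b)
  ek <- key(net$edges$mirna_i, net$edges$mirna_j)
  expect_setequal(ek, key(planted$mirna_i, planted$mirna_j))
  expect_true(all(key(disc$mirna_i, disc$mirna_j) %in%
                    key(net$deleted_pairs$mirna_i, net$deleted_pairs$mirna_j)))
  m <- match(ek, key(planted$mirna_i, planted$mirna_j))
  expect_equal(net$edges$crosstalk_type, planted$expected_crosstalk[m])

  # motif scores agree with the planted agreement fractions
  motif_key <- key(net$motifs$mirna_i, net$motifs$mirna_j)
  tm <- match(motif_key, key(truth$mirna_i, truth$mirna_j))
  measured <- net$motifs$coreg[!is.na(tm)]
  expected <- truth$expected_coreg[tm[!is.na(tm)]]
  expect_true(all(abs(measured - expected) < 0.12))
})

test_that("network accessors and exports are consistent", {
  prof <- small_profiles()
  net <- suppressWarnings(build_network(prof))
  expect_equal(tidy(net), net$edges)
  gl <- glance(net)
  expect_equal(gl$n_edges, nrow(net$edges))
  g <- as_igraph(net)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_false(igraph::any_loop(g))
  dir <- withr::local_tempdir()
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  back <- read.delim(paths[["edges"]])
  expect_equal(nrow(back), nrow(net$edges))
})
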