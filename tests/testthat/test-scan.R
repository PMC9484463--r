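test_that("duplex scoring matches hand-scored cases", {
  sa <- scheme_a()
  m <- "UGACCUAGCUAAGCUAGGCGU"
  wc <- c(A = "T", C = "G", G = "C", U = "A")
  mc <- strsplit(m, "")[[1]]
  perfect <- paste(rev(unname(wc[mc])), collapse = "")
  expect_equal(score_duplex(m, perfect, sa), 0)

  # single G:U at miRNA position 15 (outside core 2-13): m15 is U, site G
  s <- strsplit(perfect, "")[[1]]
  stopifnot(mc[15] == "U")
  s[21 - 15 + 1] <- "G"
  expect_equal(score_duplex(m, paste(s, collapse = ""), sa), 0.5)

  # single mismatch at position 5 (inside core, multiplier 2, mismatch 1)
  s <- strsplit(perfect, "")[[1]]
  stopifnot(mc[5] == "C")
  s[21 - 5 + 1] <- "A"
  expect_equal(score_duplex(m, paste(s, collapse = ""), sa), 2)

  # 3 core mismatches: 6 > cutoff 4
  s <- strsplit(perfect, "")[[1]]
  mm <- c(A = "C", C = "A", G = "A", U = "C")
  for (p in c(4, 6, 8)) s[21 - p + 1] <- unname(mm[mc[p]])
  sc <- score_duplex(m, paste(s, collapse = ""), sa)
  expect_equal(sc, 6)
  expect_gt(sc, sa$cutoff)

  expect_error(score_duplex(m, "ACGT", sa), "equal length")
})

test_that("scanning finds planted sites at correct coordinates", {
  sa <- scheme_a()
  set.seed(5)
  m <- random_rna(21)
  wc <- c(A = "T", C = "G", G = "C", U = "A")
  site <- paste(rev(unname(wc[strsplit(m, "")[[1]]])), collapse = "")
  tx <- paste0(random_dna(30), site, random_dna(40), site, random_dna(20))
  hits <- scan_transcript(c(mir = m), c(tx = tx), sa)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start, c(31L, 92L))
  expect_equal(hits$end, hits$start + 20L)
  expect_equal(hits$score, c(0, 0))
  expect_true(all(hits$end - hits$start + 1L == 21L))

  expect_warning(out <- scan_transcript(c(mir = m), c(short = "ACGT"), sa),
                 "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("scan agrees with the naive window-enumeration oracle", {
  set.seed(101)
  schemes <- list(scheme_a(), scheme_b())
  for (draw in 1:30) {
    scheme <- schemes[[(draw %% 2) + 1]]
    m <- random_rna(sample(19:24, 1))
    tx <- random_dna(sample(60:120, 1))
    # bias half the draws toward hits by planting a degraded complement
    if (draw %% 2 == 0) {
      wc <- c(A = "T", C = "G", G = "C", U = "A")
      site <- rev(unname(wc[strsplit(m, "")[[1]]]))
      k <- sample(0:4, 1)
      if (k > 0) {
        at <- sample(length(site), k)
        site[at] <- sample(c("A", "C", "G", "T"), k, TRUE)
      }
      start <- sample(nchar(tx) - length(site) + 1, 1)
      substr(tx, start, start + length(site) - 1) <- paste(site, collapse = "")
    }
    got <- suppressWarnings(scan_transcript(c(m = m), c(t = tx), scheme))
    want <- oracle_scan(m, tx, scheme)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$score, want$score)
    }
  }
})

test_that("adding a mismatch never decreases the duplex score", {
  set.seed(7)
  sa <- scheme_a()
  wc <- c(A = "T", C = "G", G = "C", U = "A")
  for (i in 1:25) {
    m <- random_rna(21)
    mc <- strsplit(m, "")[[1]]
    site <- rev(unname(wc[mc]))
    base <- score_duplex(m, paste(site, collapse = ""), sa)
    p <- sample(21, 1)
    mm <- c(A = "C", C = "A", G = "A", U = "C")[mc[p]]
    site2 <- site
    site2[21 - p + 1] <- unname(mm)
    expect_gt(score_duplex(m, paste(site2, collapse = ""), sa), base)
  }
})

test_that("prediction caching reuses wild pairs and rescans mutants", {
  set.seed(9)
  sa <- scheme_a()
  wc <- c(A = "T", C = "G", G = "C", U = "A")
  m1 <- random_rna(21); m2 <- random_rna(21)
  site1 <- paste(rev(unname(wc[strsplit(m1, "")[[1]]])), collapse = "")
  tx1 <- paste0(random_dna(40), site1, random_dna(40))
  tx2 <- random_dna(120)
  mirnas <- tibble::tibble(id = c("m1", "m2"), sequence = c(m1, m2))
  txs <- tibble::tibble(id = c("t1", "t2"), sequence = c(tx1, tx2))
  ref <- predict_all(mirnas, txs, sa)
  expect_equal(nrow(ref$pairs), 1L)
  expect_equal(ref$pairs$mirna_id, "m1")

  # all-wild ecotype: identical predictions
  eco_same <- predict_all(mirnas, txs, sa, genome_label = "ecoX",
                          reference = ref, mutant_ids = character())
  expect_equal(eco_same$sites, ref$sites)

  # mutant transcript destroying the site core: pair absent
  broken <- tx1
  mm <- c(A = "C", C = "A", G = "A", U = "C")
  mc <- strsplit(m1, "")[[1]]
  for (p in c(5, 7, 9)) {
    substr(broken, 40 + (21 - p + 1), 40 + (21 - p + 1)) <- unname(mm[mc[p]])
  }
  txs_mut <- txs
  txs_mut$sequence[1] <- broken
  eco_mut <- predict_all(mirnas, txs_mut, sa, genome_label = "ecoY",
                         reference = ref, mutant_ids = "t1")
  expect_equal(nrow(eco_mut$pairs), 0L)
})

test_that("external prediction tables adapt into prediction sets", {
  df <- data.frame(mirna_id = c("m1", "m1"), transcript_id = c("t1", "t2"),
                   start = c(5L, 9L), end = c(25L, 29L), score = c(1, 2))
  ps <- as_prediction_set(df, "reference", "toolX")
  expect_s3_class(ps, "prediction_set")
  expect_equal(nrow(ps$pairs), 2L)
  expect_error(as_prediction_set(data.frame(x = 1), "reference", "toolX"),
               "must contain")
})
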