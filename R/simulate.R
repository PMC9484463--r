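#' Specification for a synthetic ecotype panel
#'
#' Describes a fully synthetic population with known ground truth:
#' miRNA/transcript panels with planted complementary sites, SNPs that
#' create or destroy sites in designated ecotype clusters, sprinkled
#' singleton and indel variants, a correlated expression compendium, and a
#' geographically clustered climate table.
#'
#' Planted cooperative pairs cycle through four classes: `ss` (both sites
#' intact everywhere), `dd_loss` (both sites destroyed by SNPs in the same
#' ecotype cluster), `dd_gain` (both sites created by SNPs in the same
#' cluster), and `sd` (one regulation static, the other lost through a SNP
#' in the miRNA sequence). Discordant pairs are `dd_loss`-style pairs whose
#' two loss clusters barely overlap, tuned to the stated agreement fraction.
#'
#' @param seed Integer seed; mandatory, every draw derives from it.
#' @param n_ecotypes,n_mirnas,n_transcripts Panel dimensions.
#' @param mirna_length,transcript_length Sequence lengths (nt).
#' @param n_coop_pairs Number of planted cooperative miRNA pairs
#'   (agreement 1 for `ss`/`dd` classes, `1 - sd_cluster_size/n_ecotypes`
#'   for `sd`).
#' @param n_discordant_pairs Number of discordant pairs.
#' @param discordant_agreement True fate-agreement fraction of discordant
#'   pairs (must be `< 1`).
#' @param dd_cluster_size,sd_cluster_size Ecotype-cluster sizes for the
#'   planted loss/gain events.
#' @param singleton_rate Per-transcript probability of one singleton SNP.
#' @param background_snp_rate Per-transcript probability of one neutral
#'   (outside any site) SNP carried by a few ecotypes.
#' @param indel_rate Per-transcript probability of one short indel carried
#'   by a few ecotypes (those ecotypes are discarded for that transcript).
#' @param n_samples,n_replicates Expression compendium dimensions
#'   (`n_samples >= 6`).
#' @param rho_high,rho_low Expression correlation of planted cooperative
#'   pairs vs everything else.
#' @param climate_within_sd,climate_between_sd Within-cluster and
#'   between-cluster spread of the bioclimatic variables.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed,
                         n_ecotypes = 100L, n_mirnas = 30L,
                         n_transcripts = 60L,
                         mirna_length = 21L, transcript_length = 300L,
                         n_coop_pairs = 10L, n_discordant_pairs = 10L,
                         discordant_agreement = 0.3,
                         dd_cluster_size = 20L, sd_cluster_size = 10L,
                         singleton_rate = 0.05, background_snp_rate = 0.05,
                         indel_rate = 0.1,
                         n_samples = 30L, n_replicates = 2L,
                         rho_high = 0.9, rho_low = 0,
                         climate_within_sd = 0.5, climate_between_sd = 10) {
  if (missing(seed) || is.null(seed)) abort("fixture_spec requires a seed")
  if (any(c(singleton_rate, background_snp_rate, indel_rate,
            discordant_agreement, rho_high, abs(rho_low)) < 0 |
          c(singleton_rate, background_snp_rate, indel_rate,
            discordant_agreement, rho_high, abs(rho_low)) > 1)) {
    abort("rates must be in [0, 1]")
  }
  if (2L * (mirna_length + 40L) > transcript_length) {
    abort("transcript_length too short to host two planted sites")
  }
  if (n_mirnas < 2L * n_coop_pairs) {
    abort("need n_mirnas >= 2 * n_coop_pairs (cooperative pairs are disjoint)")
  }
  if (n_transcripts < n_coop_pairs + n_discordant_pairs) {
    abort("need one transcript per planted pair")
  }
  structure(as.list(environment()), class = "fixture_spec")
}

bioclim_variables <- function() {
  c("temperature_seasonality", "max_temp_warmest_month",
    "mean_temp_wettest_quarter", "mean_temp_coldest_quarter",
    "precip_wettest_month", "precip_driest_month", "precip_seasonality")
}

# base-pairing helper tables (miRNA base -> transcript DNA base)
WC_DNA <- c(A = "T", C = "G", G = "C", U = "A")
MISMATCH_DNA <- c(A = "C", C = "A", G = "A", U = "C")
WOBBLE_DNA <- c(G = "T", U = "G")
MISMATCH_RNA <- c(A = "C", C = "A", G = "A", U = "C")

random_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_mirna <- function(len) {
  s <- strsplit(random_seq(len, c("A", "C", "G", "U")), "")[[1]]
  s[len - 1L] <- sample(c("G", "U"), 1L)  # wobble-capable base at position L-1
  paste(s, collapse = "")
}

# Build a binding site for `mirna` in transcript orientation.
# template "perfect": full reverse complement.
# template "marginal": perfect minus 2 mismatches (miRNA pos L-3, L-2) and a
#   G:U wobble (pos L-1) -- present under both default schemes, and one core
#   substitution away from absent under both.
# template "gainable": marginal plus a core mismatch at `snp_mirna_pos` --
#   absent under both schemes until the SNP reverts the mismatch.
planted_site <- function(mirna, template = c("perfect", "marginal", "gainable"),
                         snp_mirna_pos = 10L) {
  template <- match.arg(template)
  m <- strsplit(mirna, "")[[1]]
  L <- length(m)
  site <- rev(unname(WC_DNA[m]))  # site[L - p + 1] pairs miRNA position p
  at <- function(p) L - p + 1L
  if (template != "perfect") {
    site[at(L - 3L)] <- MISMATCH_DNA[m[L - 3L]]
    site[at(L - 2L)] <- MISMATCH_DNA[m[L - 2L]]
    site[at(L - 1L)] <- WOBBLE_DNA[m[L - 1L]]
  }
  if (template == "gainable") {
    site[at(snp_mirna_pos)] <- MISMATCH_DNA[m[snp_mirna_pos]]
  }
  list(site = paste(site, collapse = ""),
       snp_offset = at(snp_mirna_pos),  # offset within site, 1-based
       wc_base = unname(WC_DNA[m[snp_mirna_pos]]),
       mm_base = unname(MISMATCH_DNA[m[snp_mirna_pos]]))
}

splice_site <- function(transcript, site, start) {
  substr(transcript, start, start + nchar(site) - 1L) <- site
  transcript
}

#' Generate a synthetic ecotype panel with known ground truth
#'
#' @param spec A [fixture_spec()].
#' @return An [ecotype_panel()] with an extra `truth` element: a tibble with
#'   one row per planted miRNA pair (`mirna_i`, `mirna_j`, `target`,
#'   `class`, `planted`, `expected_coreg`, `expected_crosstalk`, and the
#'   event-cluster ecotypes as a list column).
#' @export
generate_panel <- function(spec) {
  set.seed(spec$seed)
  L <- spec$mirna_length
  ecotypes <- sprintf("eco%03d", seq_len(spec$n_ecotypes))
  mirna_ids <- sprintf("mir%03d", seq_len(spec$n_mirnas))
  tx_ids <- sprintf("tx%03d", seq_len(spec$n_transcripts))
  mirna_seq <- setNames(vapply(mirna_ids, function(i) random_mirna(L),
                               character(1)), mirna_ids)
  tx_seq <- setNames(vapply(tx_ids, function(i) {
    random_seq(spec$transcript_length, c("A", "C", "G", "T"))
  }, character(1)), tx_ids)

  classes <- rep(c("ss", "dd_loss", "dd_gain", "sd"),
                 length.out = spec$n_coop_pairs)
  coop_m <- matrix(mirna_ids[seq_len(2L * spec$n_coop_pairs)], nrow = 2L)
  rest <- setdiff(mirna_ids, as.vector(coop_m))
  disc_candidates <- if (length(rest) >= 2L) combn(rest, 2L) else
    matrix(character(), nrow = 2L)
  if (ncol(disc_candidates) < spec$n_discordant_pairs) {
    abort("not enough leftover miRNAs for the discordant pairs")
  }
  disc_m <- disc_candidates[, sample.int(ncol(disc_candidates),
                                         spec$n_discordant_pairs), drop = FALSE]

  site_start <- c(41L, 41L + L + 40L)
  variants <- list()
  truth <- list()
  site_spans <- list()  # per transcript: positions covered by planted sites
  add_snp <- function(seq_id, pos, ref, alt, carriers) {
    variants[[length(variants) + 1L]] <<- tibble(
      seq_id = seq_id, pos = pos, ref = ref, alt = alt, type = "snp",
      carriers = list(carriers))
  }

  plant_pair <- function(pair_idx, m_i, m_j, tx, class, planted) {
    cl_size <- if (class == "sd") spec$sd_cluster_size else spec$dd_cluster_size
    cluster <- sort(sample(ecotypes, cl_size))
    templates <- switch(class,
                        ss = c("perfect", "perfect"),
                        dd_loss = c("marginal", "marginal"),
                        dd_gain = c("gainable", "gainable"),
                        sd = c("perfect", "marginal"),
                        discordant = c("marginal", "marginal"))
    clusters <- switch(class,
                       ss = list(NULL, NULL),
                       dd_loss = list(cluster, cluster),
                       dd_gain = list(cluster, cluster),
                       sd = list(NULL, cluster),
                       discordant = {
                         s <- round(0.4 * spec$n_ecotypes)
                         o <- round(spec$n_ecotypes *
                                      (spec$discordant_agreement - 1) / 2 + s)
                         if (o < 0L || o > s) {
                           abort("infeasible discordant_agreement for this panel size")
                         }
                         u <- sample(ecotypes, 2L * s - o)
                         list(sort(u[seq_len(s)]), sort(u[(s - o + 1L):(2L * s - o)]))
                       })
    for (k in 1:2) {
      m_id <- c(m_i, m_j)[k]
      ps <- planted_site(mirna_seq[[m_id]], templates[k])
      tx_seq[[tx]] <<- splice_site(tx_seq[[tx]], ps$site, site_start[k])
      site_spans[[tx]] <<- c(site_spans[[tx]],
                             site_start[k]:(site_start[k] + L - 1L))
      ev <- clusters[[k]]
      if (!is.null(ev)) {
        if (class == "sd") {
          # loss SNP in the dynamic miRNA's own sequence (core position 10)
          m_chars <- strsplit(mirna_seq[[m_id]], "")[[1]]
          add_snp(m_id, 10L, m_chars[10L], unname(MISMATCH_RNA[m_chars[10L]]),
                  ev)
        } else if (class == "dd_gain") {
          add_snp(tx, site_start[k] + ps$snp_offset - 1L, ps$mm_base,
                  ps$wc_base, ev)
        } else {
          add_snp(tx, site_start[k] + ps$snp_offset - 1L, ps$wc_base,
                  ps$mm_base, ev)
        }
      }
    }
    truth[[length(truth) + 1L]] <<- tibble(
      mirna_i = min(m_i, m_j), mirna_j = max(m_i, m_j), target = tx,
      class = class, planted = planted,
      expected_coreg = switch(class,
                              ss = 1, dd_loss = 1, dd_gain = 1,
                              sd = 1 - spec$sd_cluster_size / spec$n_ecotypes,
                              discordant = spec$discordant_agreement),
      expected_crosstalk = switch(class, ss = "SS", dd_loss = "DD",
                                  dd_gain = "DD", sd = "SD",
                                  discordant = NA_character_),
      cluster = list(cluster))
  }

  tx_cursor <- 0L
  for (p in seq_len(spec$n_coop_pairs)) {
    tx_cursor <- tx_cursor + 1L
    plant_pair(p, coop_m[1, p], coop_m[2, p], tx_ids[tx_cursor], classes[p],
               planted = TRUE)
  }
  for (p in seq_len(spec$n_discordant_pairs)) {
    tx_cursor <- tx_cursor + 1L
    plant_pair(p, disc_m[1, p], disc_m[2, p], tx_ids[tx_cursor], "discordant",
               planted = FALSE)
  }

  # sprinkle neutral variation outside the planted sites
  free_pos <- function(tx) {
    used <- site_spans[[tx]] %||% integer()
    setdiff(10:(spec$transcript_length - 10L), used)
  }
  for (tx in tx_ids) {
    pos_pool <- free_pos(tx)
    chars <- strsplit(tx_seq[[tx]], "")[[1]]
    if (runif(1) < spec$singleton_rate) {
      p <- sample(pos_pool, 1L)
      add_snp(tx, p, chars[p], sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L),
              sample(ecotypes, 1L))
      pos_pool <- setdiff(pos_pool, p)
    }
    if (runif(1) < spec$background_snp_rate) {
      p <- sample(pos_pool, 1L)
      add_snp(tx, p, chars[p], sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L),
              sample(ecotypes, sample(2:4, 1L)))
      pos_pool <- setdiff(pos_pool, p)
    }
    if (runif(1) < spec$indel_rate) {
      p <- sample(pos_pool[pos_pool < spec$transcript_length - 1L], 1L)
      variants[[length(variants) + 1L]] <- tibble(
        seq_id = tx, pos = p, ref = paste0(chars[p], chars[p + 1L]),
        alt = chars[p], type = "indel",
        carriers = list(sample(ecotypes, sample(2:3, 1L))))
    }
  }

  sequences <- bind_rows(
    tibble(id = mirna_ids, kind = "mirna", gene_id = NA_character_,
           sequence = unname(mirna_seq[mirna_ids])),
    tibble(id = tx_ids, kind = "transcript",
           gene_id = sub("tx", "g", tx_ids), sequence = unname(tx_seq[tx_ids])))
  panel <- ecotype_panel(sequences, bind_rows(variants), ecotypes)
  panel$truth <- bind_rows(truth)
  panel$spec <- spec
  panel
}

#' Generate a correlated synthetic expression compendium
#'
#' Log-normal abundance profiles in which each planted cooperative pair
#' shares a latent factor giving pairwise correlation `rho_high`; all other
#' miRNAs are uncorrelated (`rho_low = 0` structure via pairwise factors).
#'
#' @param panel A panel from [generate_panel()] (uses its `truth` and
#'   `spec`).
#' @return Long tibble `mirna_id`, `sample`, `replicate`, `value` suitable
#'   for [preprocess_expression()].
#' @export
generate_expression <- function(panel) {
  spec <- panel$spec
  if (spec$n_samples < 6L) {
    abort("n_samples must be >= 6 (downstream expression filter)")
  }
  set.seed(spec$seed + 1L)
  mirnas <- panel$sequences$id[panel$sequences$kind == "mirna"]
  samples <- sprintf("s%02d", seq_len(spec$n_samples))
  mu <- setNames(rnorm(length(mirnas), mean = 6, sd = 1), mirnas)
  z <- matrix(rnorm(length(mirnas) * spec$n_samples), nrow = length(mirnas),
              dimnames = list(mirnas, samples))
  coop <- panel$truth[panel$truth$planted, , drop = FALSE]
  rho <- spec$rho_high
  for (i in seq_len(nrow(coop))) {
    f <- rnorm(spec$n_samples)
    for (m in c(coop$mirna_i[i], coop$mirna_j[i])) {
      z[m, ] <- sqrt(rho) * f + sqrt(1 - rho) * rnorm(spec$n_samples)
    }
  }
  rows <- purrr::map(seq_len(spec$n_replicates), function(r) {
    noise <- matrix(rnorm(length(z), sd = 0.05), nrow = nrow(z))
    tibble(mirna_id = rep(mirnas, times = length(samples)),
           sample = rep(samples, each = length(mirnas)),
           replicate = paste0("r", r),
           value = as.vector(2^(mu[mirnas] + z + noise)))
  })
  bind_rows(rows)
}

#' Generate a clustered synthetic climate table
#'
#' Draws the seven default bioclimatic variables plus coordinates. Ecotypes
#' in a designated group share a group mean with small within-group spread;
#' all other ecotypes are drawn from the wide background distribution. With
#' `groups = NULL` the whole panel is one homogeneous background, which is
#' the null condition for calibrating [climate_sd_test()].
#'
#' @param panel A panel from [generate_panel()].
#' @param groups Optional named list of ecotype-id vectors to make
#'   climatically tight clusters.
#' @return Tibble: `ecotype`, `lat`, `lon`, and one column per bioclimatic
#'   variable.
#' @export
generate_climate <- function(panel, groups = NULL) {
  spec <- panel$spec
  set.seed(spec$seed + 2L)
  ecotypes <- panel$ecotypes
  vars <- bioclim_variables()
  out <- tibble(ecotype = ecotypes,
                lat = runif(length(ecotypes), 35, 65),
                lon = runif(length(ecotypes), -10, 30))
  for (v in vars) {
    center <- rnorm(1, 0, spec$climate_between_sd)
    vals <- rnorm(length(ecotypes), center, spec$climate_between_sd)
    for (g in groups %||% list()) {
      g_mean <- rnorm(1, center, spec$climate_between_sd)
      vals[match(g, ecotypes)] <- rnorm(length(g), g_mean,
                                        spec$climate_within_sd)
    }
    out[[v]] <- vals
  }
  if (!is.null(groups)) {
    for (g in groups) {
      i <- match(g, ecotypes)
      out$lat[i] <- rnorm(length(g), mean(out$lat[i][1]), 0.5)
      out$lon[i] <- rnorm(length(g), mean(out$lon[i][1]), 0.5)
    }
  }
  out
}

#' Packaged worked-example fixture: one miRNA pair, 18 shared targets
#'
#' Two miRNAs co-regulate 18 transcripts: 2 targets are statically
#' co-regulated (co-regulation type `ss`) and 16 are dynamically
#' co-regulated (`dd`), lost together in one 22-ecotype cluster — so 11% of
#' the motifs are `ss`, 89% are `dd`, and the pair's crosstalk type is `DD`.
#'
#' @param n_ecotypes Panel size.
#' @param seed Seed (fixed default makes the fixture a stable reference).
#' @return An [ecotype_panel()] with `truth` describing the planted motifs.
#' @export
fixture_fig1e <- function(n_ecotypes = 100L, seed = 42L) {
  set.seed(seed)
  L <- 21L
  ecotypes <- sprintf("eco%03d", seq_len(n_ecotypes))
  mirna_ids <- c("mirX", "mirY")
  tx_ids <- sprintf("txE%02d", 1:18)
  mirna_seq <- setNames(c(random_mirna(L), random_mirna(L)), mirna_ids)
  cluster <- sort(sample(ecotypes, 22L))
  site_start <- c(41L, 41L + L + 40L)
  variants <- list()
  tx_rows <- purrr::map(seq_along(tx_ids), function(i) {
    tx <- tx_ids[i]
    seq <- random_seq(300L, c("A", "C", "G", "T"))
    template <- if (i <= 2L) "perfect" else "marginal"
    for (k in 1:2) {
      ps <- planted_site(mirna_seq[[k]], template)
      seq <- splice_site(seq, ps$site, site_start[k])
      if (template == "marginal") {
        variants[[length(variants) + 1L]] <<- tibble(
          seq_id = tx, pos = site_start[k] + ps$snp_offset - 1L,
          ref = ps$wc_base, alt = ps$mm_base, type = "snp",
          carriers = list(cluster))
      }
    }
    tibble(id = tx, kind = "transcript", gene_id = sub("txE", "gE", tx),
           sequence = seq)
  })
  sequences <- bind_rows(
    tibble(id = mirna_ids, kind = "mirna", gene_id = NA_character_,
           sequence = unname(mirna_seq)),
    bind_rows(tx_rows))
  panel <- ecotype_panel(sequences, bind_rows(variants), ecotypes)
  panel$truth <- tibble(
    mirna_i = "mirX", mirna_j = "mirY", target = tx_ids,
    class = c("ss", "ss", rep("dd_loss", 16L)), planted = TRUE,
    expected_coreg = 1,
    expected_crosstalk = "DD", cluster = list(cluster))
  panel
}

#' Packaged case-study fixture: family-wide gain in one ecotype cluster
#'
#' Seven homologous miRNAs (identical mature sequences) all lack a target in
#' the reference genome; a single SNP in the shared binding site of the
#' target's 3' region, carried by the same 22 ecotypes, restores the site so
#' that all seven regulations are gained in exactly those ecotypes.
#'
#' @param n_ecotypes Panel size.
#' @param seed Seed (fixed default).
#' @return An [ecotype_panel()] with a `truth` element holding the gain
#'   cluster.
#' @export
fixture_fig7a <- function(n_ecotypes = 100L, seed = 7L) {
  set.seed(seed)
  L <- 21L
  ecotypes <- sprintf("eco%03d", seq_len(n_ecotypes))
  fam_seq <- random_mirna(L)
  mirna_ids <- sprintf("mirF%d", 1:7)
  cluster <- sort(sample(ecotypes, 22L))
  tx <- "txG01"
  seq <- random_seq(300L, c("A", "C", "G", "T"))
  ps <- planted_site(fam_seq, "gainable")
  seq <- splice_site(seq, ps$site, 201L)  # 3'-region site
  variants <- tibble(seq_id = tx, pos = 201L + ps$snp_offset - 1L,
                     ref = ps$mm_base, alt = ps$wc_base, type = "snp",
                     carriers = list(cluster))
  sequences <- bind_rows(
    tibble(id = mirna_ids, kind = "mirna", gene_id = NA_character_,
           sequence = fam_seq),
    tibble(id = tx, kind = "transcript", gene_id = "gG01", sequence = seq))
  panel <- ecotype_panel(sequences, variants, ecotypes)
  panel$truth <- tibble(mirna_id = mirna_ids, target = tx,
                        general_fate = "G", cluster = list(cluster))
  panel
}
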