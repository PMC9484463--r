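# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation: character-level
# if/else scoring, loop-based counting, DFS path enumeration.

# --- naive duplex scorer ----------------------------------------------------
# miRNA position p (5'->3') pairs antiparallel with site position L-p+1.
oracle_duplex_score <- function(mirna, site, mismatch, gu, core_from, core_to,
                                core_mult) {
  m <- strsplit(toupper(mirna), "")[[1]]
  s <- strsplit(toupper(site), "")[[1]]
  m[m == "T"] <- "U"
  s[s == "U"] <- "T"
  L <- length(m)
  total <- 0
  for (p in seq_len(L)) {
    b <- s[L - p + 1]
    pen <- if ((m[p] == "A" && b == "T") || (m[p] == "C" && b == "G") ||
               (m[p] == "G" && b == "C") || (m[p] == "U" && b == "A")) 0
    else if ((m[p] == "G" && b == "T") || (m[p] == "U" && b == "G")) gu
    else mismatch
    if (p >= core_from && p <= core_to) pen <- pen * core_mult
    total <- total + pen
  }
  total
}

# enumerate every window and keep those at or below the cutoff
oracle_scan <- function(mirna, transcript, scheme) {
  L <- nchar(mirna)
  n <- nchar(transcript)
  hits <- list()
  if (n >= L) {
    for (s in seq_len(n - L + 1)) {
      site <- substr(transcript, s, s + L - 1)
      sc <- oracle_duplex_score(mirna, site, scheme$mismatch, scheme$gu_wobble,
                                scheme$core[1], scheme$core[2],
                                scheme$core_multiplier)
      if (sc <= scheme$cutoff) {
        hits[[length(hits) + 1]] <- data.frame(start = s, score = sc)
      }
    }
  }
  do.call(rbind, hits)
}

# --- brute-force joint-fate coreg counter -----------------------------------
oracle_coreg <- function(fi, fj, gi, gj, mode = "extended") {
  n_eco <- 0; n_agree <- 0; n_l <- 0; n_g <- 0
  for (e in seq_along(fi)) {
    if (fi[e] == "." || fj[e] == ".") next
    n_eco <- n_eco + 1
    same <- fi[e] == fj[e]
    if (same && fi[e] == "l") n_l <- n_l + 1
    if (same && fi[e] == "g") n_g <- n_g + 1
    if (same && fi[e] %in% c("k", "l", "g")) n_agree <- n_agree + 1
    if (mode == "extended" && same && fi[e] == "n") n_agree <- n_agree + 1
  }
  if (n_eco == 0) return(NA_real_)
  pair <- sort(c(gi, gj))
  if (pair[1] == "K" && pair[2] == "G") return(0)
  if (pair[1] == "G" && pair[2] == "KL") return(0)
  if (any(pair == "L")) return(0)
  if (gi == "KL" && gj == "KL" && n_l == 0) return(0)
  if (mode == "extended" && gi == "G" && gj == "G" && n_g == 0) return(0)
  n_agree / n_eco
}

# random single-regulation profile consistent with a general fate
draw_profile <- function(n_eco, target = "t1", mirna = "m") {
  kind <- sample(c("K", "KL", "G"), 1)
  fates <- switch(kind,
    K = sample(c("k", "o", "."), n_eco, TRUE, prob = c(0.7, 0.2, 0.1)),
    KL = sample(c("k", "l", "o", "."), n_eco, TRUE, prob = c(0.5, 0.3, 0.1, 0.1)),
    G = sample(c("g", "n", "o", "."), n_eco, TRUE, prob = c(0.3, 0.5, 0.1, 0.1)))
  # enforce the defining symbol
  if (kind == "KL" && !any(fates == "l")) fates[sample(n_eco, 1)] <- "l"
  if (kind == "G" && !any(fates == "g")) fates[sample(n_eco, 1)] <- "g"
  if (kind == "K") fates[fates == "l"] <- "k"
  names(fates) <- paste0("eco", seq_len(n_eco))
  fate_profile(mirna, target, fates, in_reference = kind != "G",
               general = kind)
}

# --- textbook step-up BH ----------------------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(ranked[i:n] * n / seq(i, n))
  }
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# --- brute-force betweenness via shortest-path enumeration ------------------
# adj: logical adjacency matrix of a simple undirected graph
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  node_b <- numeric(n)
  edge_b <- matrix(0, n, n)
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in which(adj[u, ])) if (d[v] == Inf) {
        d[v] <- d[u] + 1; queue <- c(queue, v)
      }
    }
    d
  }
  all_shortest_paths <- function(s, t, dst) {
    paths <- list()
    walk <- function(path) {
      u <- path[length(path)]
      if (u == t) { paths[[length(paths) + 1]] <<- path; return() }
      if (length(path) - 1 >= dst) return()
      for (v in which(adj[u, ])) {
        if (!v %in% path) walk(c(path, v))
      }
    }
    walk(s)
    paths[vapply(paths, length, 1L) == dst + 1]
  }
  for (s in 1:(n - 1)) {
    d <- bfs_dist(s)
    for (t in (s + 1):n) {
      if (!is.finite(d[t])) next
      paths <- all_shortest_paths(s, t, d[t])
      np <- length(paths)
      if (!np) next
      for (p in paths) {
        interior <- p[-c(1, length(p))]
        node_b[interior] <- node_b[interior] + 1 / np
        for (i in seq_len(length(p) - 1)) {
          a <- min(p[i], p[i + 1]); b <- max(p[i], p[i + 1])
          edge_b[a, b] <- edge_b[a, b] + 1 / np
        }
      }
    }
  }
  list(node = node_b, edge = edge_b)
}

# --- small shared panels ----------------------------------------------------
small_spec <- function(seed = 11) {
  fixture_spec(seed = seed, n_ecotypes = 40, n_mirnas = 12, n_transcripts = 20,
               n_coop_pairs = 4, n_discordant_pairs = 3,
               dd_cluster_size = 8, sd_cluster_size = 4)
}

small_profiles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panel <- generate_panel(small_spec())
      cache <<- suppressMessages(population_fate_profiles(panel))
    }
    cache
  }
})

small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_panel(small_spec())
    cache
  }
})

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
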