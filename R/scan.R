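#' Complementarity scoring schemes
#'
#' A scheme scores a gapless antiparallel miRNA:site duplex by summing
#' per-position penalties over miRNA positions 1..L counted from the miRNA 5'
#' end: 0 for a Watson-Crick pair, `gu_wobble` for a G:U wobble, `mismatch`
#' otherwise; penalties at positions inside `core` (5'-proximal seed-like
#' region) are multiplied by `core_multiplier`. A candidate window is a
#' predicted target site when its score is less than or equal to `cutoff`
#' (ties at the cutoff are accepted).
#'
#' `scheme_a()` is an Allen-style scorer (core 2-13, multiplier 2, cutoff 4);
#' `scheme_b()` is a stricter 5'-weighted scorer (core 2-17, multiplier 1.5,
#' cutoff 2.5). Running both and intersecting their pair-level predictions
#' mirrors the common practice of requiring agreement between two independent
#' plant target prediction tools.
#'
#' @param name Scheme label used in outputs.
#' @param mismatch Penalty for a non-pairing position (>= 0).
#' @param gu_wobble Penalty for a G:U wobble pair (>= 0).
#' @param core Integer vector `c(first, last)` of the core region in miRNA
#'   coordinates (5' to 3').
#' @param core_multiplier Multiplier applied to penalties inside the core.
#' @param cutoff Maximum (inclusive) duplex score for a predicted site.
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(name, mismatch = 1, gu_wobble = 0.5,
                           core = c(2L, 13L), core_multiplier = 2,
                           cutoff = 4) {
  if (mismatch < 0 || gu_wobble < 0) abort("penalties must be >= 0")
  if (cutoff <= 0) abort("cutoff must be > 0")
  if (length(core) != 2L || core[1] < 1L || core[2] < core[1]) {
    abort("core must be c(first, last) with 1 <= first <= last")
  }
  structure(list(name = name, mismatch = mismatch, gu_wobble = gu_wobble,
                 core = as.integer(core), core_multiplier = core_multiplier,
                 cutoff = cutoff),
            class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
scheme_a <- function() scoring_scheme("A", mismatch = 1, gu_wobble = 0.5,
                                      core = c(2L, 13L), core_multiplier = 2,
                                      cutoff = 4)

#' @rdname scoring_scheme
#' @export
scheme_b <- function() scoring_scheme("B", mismatch = 1, gu_wobble = 0.5,
                                      core = c(2L, 17L), core_multiplier = 1.5,
                                      cutoff = 2.5)

# A=1 C=2 G=3 U/T=4
encode_nt <- function(x) {
  m <- c(A = 1L, C = 2L, G = 3L, U = 4L, T = 4L)
  unname(m[strsplit(x, "", fixed = TRUE)[[1]]])
}

# penalty matrix: rows miRNA base, cols transcript base
penalty_matrix <- function(scheme) {
  p <- matrix(scheme$mismatch, 4, 4)
  p[1, 4] <- 0; p[2, 3] <- 0; p[3, 2] <- 0; p[4, 1] <- 0   # WC
  p[3, 4] <- scheme$gu_wobble; p[4, 3] <- scheme$gu_wobble # G:U
  p
}

#' Score a gapless miRNA:site duplex
#'
#' The site is given in transcript orientation (5' to 3'); pairing is
#' antiparallel, so miRNA position `p` pairs with site position
#' `L - p + 1`.
#'
#' @param mirna_seq miRNA sequence, 5' to 3'.
#' @param site_seq Candidate site sequence of the same length, 5' to 3'.
#' @param scheme A [scoring_scheme()].
#' @return The duplex penalty score (0 for a perfect complement).
#' @export
score_duplex <- function(mirna_seq, site_seq, scheme) {
  m <- encode_nt(mirna_seq)
  t <- encode_nt(site_seq)
  if (length(m) != length(t)) abort("miRNA and site must have equal length")
  p <- penalty_matrix(scheme)
  w <- duplex_weights(length(m), scheme)
  sum(w * p[cbind(m, rev(t))])
}

duplex_weights <- function(len, scheme) {
  w <- rep(1, len)
  core <- scheme$core[1]:min(scheme$core[2], len)
  w[core] <- scheme$core_multiplier
  w
}

#' Scan a transcript for target sites of one miRNA
#'
#' Exhaustively scores every gapless window of miRNA length along the
#' transcript and returns the windows whose duplex score is at or below the
#' scheme cutoff.
#'
#' @param mirna One-row tibble (or list) with `id` and `sequence` of the
#'   miRNA, or a plain named character `c(id = sequence)`.
#' @param transcript Same for the transcript.
#' @param scheme A [scoring_scheme()].
#' @return A tibble of sites: `mirna_id`, `transcript_id`, `start`, `end`
#'   (1-based inclusive transcript coordinates), `score`, `scheme`.
#' @export
scan_transcript <- function(mirna, transcript, scheme) {
  mirna <- as_seq_record(mirna)
  transcript <- as_seq_record(transcript)
  scores <- window_scores(mirna$sequence, transcript$sequence, scheme)
  empty <- tibble(mirna_id = character(), transcript_id = character(),
                  start = integer(), end = integer(), score = numeric(),
                  scheme = character())
  if (is.null(scores)) {
    warn(paste0("transcript ", transcript$id, " shorter than miRNA ",
                mirna$id, "; no windows"))
    return(empty)
  }
  hit <- which(scores <= scheme$cutoff)
  if (!length(hit)) return(empty)
  len <- nchar(mirna$sequence)
  tibble(mirna_id = mirna$id, transcript_id = transcript$id,
         start = hit, end = hit + len - 1L, score = scores[hit],
         scheme = scheme$name)
}

as_seq_record <- function(x) {
  if (is.character(x) && !is.null(names(x))) {
    list(id = names(x)[1], sequence = unname(x)[1])
  } else {
    list(id = x$id[[1]], sequence = x$sequence[[1]])
  }
}

# vector of duplex scores for every window start, or NULL if transcript
# shorter than the miRNA
window_scores <- function(mirna_seq, transcript_seq, scheme) {
  m <- encode_nt(mirna_seq)
  t <- encode_nt(transcript_seq)
  L <- length(m); n <- length(t)
  if (n < L) return(NULL)
  p <- penalty_matrix(scheme)
  w <- duplex_weights(L, scheme)
  # window position q (1..L) pairs with miRNA position L - q + 1
  mr <- rev(m); wr <- rev(w)
  nw <- n - L + 1L
  scores <- numeric(nw)
  for (q in seq_len(L)) {
    scores <- scores + wr[q] * p[mr[q], t[q:(q + nw - 1L)]]
  }
  scores
}

#' Predict all target sites of a sequence panel under one scheme
#'
#' Scans every (miRNA, transcript) pair and collects the predicted sites into
#' a prediction set. For an ecotype run, pass the reference prediction set
#' via `reference` together with the identifiers of mutant-type sequences:
#' pairs in which both sequences are wild type reuse the reference sites
#' unchanged and only pairs touched by a mutant miRNA or transcript are
#' rescanned.
#'
#' @param mirnas,transcripts Sequence tibbles (columns `id`, `sequence`),
#'   already materialized for the genome being scanned (discarded sequences
#'   removed).
#' @param scheme A [scoring_scheme()].
#' @param genome_label `"reference"` or an ecotype id.
#' @param reference Optional reference `prediction_set` of the same scheme.
#' @param mutant_ids Character vector of sequence ids that are mutant type in
#'   this genome (required when `reference` is supplied).
#' @return A `prediction_set`: list with `genome_label`, `scheme_name`,
#'   `sites` (site tibble) and `pairs` (distinct `mirna_id`, `transcript_id`).
#' @export
predict_all <- function(mirnas, transcripts, scheme,
                        genome_label = "reference", reference = NULL,
                        mutant_ids = NULL) {
  if (!is.null(reference) && reference$scheme_name != scheme$name) {
    abort("reference prediction set was computed under a different scheme")
  }
  mutant_ids <- mutant_ids %||% character()
  kept <- NULL
  if (!is.null(reference)) {
    # cache contract: rescan only pairs with a mutant component
    touched <- reference$sites$mirna_id %in% mutant_ids |
      reference$sites$transcript_id %in% mutant_ids
    kept <- reference$sites[!touched &
                              reference$sites$mirna_id %in% mirnas$id &
                              reference$sites$transcript_id %in% transcripts$id,
                            , drop = FALSE]
  }
  m_enc <- lapply(mirnas$sequence, encode_nt)
  t_enc <- lapply(transcripts$sequence, encode_nt)
  pmat <- penalty_matrix(scheme)
  mut_m <- mirnas$id %in% mutant_ids
  mut_t <- transcripts$id %in% mutant_ids
  out <- vector("list", 256L); n_out <- 0L
  for (i in seq_along(m_enc)) {
    jj <- if (is.null(reference)) seq_along(t_enc)
    else if (mut_m[i]) seq_along(t_enc) else which(mut_t)
    if (!length(jj)) next
    m <- m_enc[[i]]
    wr <- rev(duplex_weights(length(m), scheme))
    mr <- rev(m)
    for (j in jj) {
      t <- t_enc[[j]]
      nw <- length(t) - length(m) + 1L
      if (nw < 1L) {
        warn(paste0("transcript ", transcripts$id[j], " shorter than miRNA ",
                    mirnas$id[i], "; no windows"))
        next
      }
      scores <- numeric(nw)
      for (q in seq_along(m)) {
        scores <- scores + wr[q] * pmat[mr[q], t[q:(q + nw - 1L)]]
      }
      hit <- which(scores <= scheme$cutoff)
      if (length(hit)) {
        n_out <- n_out + 1L
        out[[n_out]] <- tibble(
          mirna_id = mirnas$id[i], transcript_id = transcripts$id[j],
          start = hit, end = hit + length(m) - 1L, score = scores[hit],
          scheme = scheme$name)
      }
    }
  }
  sites <- bind_rows(out[seq_len(n_out)])
  if (nrow(sites) == 0L) {
    sites <- tibble(mirna_id = character(), transcript_id = character(),
                    start = integer(), end = integer(), score = numeric(),
                    scheme = character())
  }
  if (!is.null(kept)) sites <- bind_rows(kept, sites)
  new_prediction_set(sites, genome_label, scheme$name)
}

new_prediction_set <- function(sites, genome_label, scheme_name) {
  structure(list(genome_label = genome_label, scheme_name = scheme_name,
                 sites = as_tibble(sites),
                 pairs = distinct(sites[c("mirna_id", "transcript_id")])),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("<prediction_set> genome ", x$genome_label, ", scheme ", x$scheme_name,
      ": ", nrow(x$sites), " sites, ", nrow(x$pairs), " pairs\n", sep = "")
  invisible(x)
}

#' Adapt an external prediction table to a prediction set
#'
#' Accepts any data frame of target predictions (e.g. parsed output of an
#' external plant target prediction tool) holding at least a miRNA and a
#' transcript identifier column, so genuine tool predictions can stand in for
#' the built-in scorers anywhere a prediction set is consumed.
#'
#' @param x Data frame of predictions.
#' @param genome_label `"reference"` or an ecotype id.
#' @param scheme_name Label for the source tool.
#' @param mirna_col,transcript_col,start_col,end_col,score_col Column names in
#'   `x`; the site coordinate/score columns are optional.
#' @return A `prediction_set`.
#' @export
as_prediction_set <- function(x, genome_label, scheme_name,
                              mirna_col = "mirna_id",
                              transcript_col = "transcript_id",
                              start_col = "start", end_col = "end",
                              score_col = "score") {
  x <- as_tibble(x)
  if (!all(c(mirna_col, transcript_col) %in% names(x))) {
    abort("prediction table must contain miRNA and transcript id columns")
  }
  sites <- tibble(
    mirna_id = as.character(x[[mirna_col]]),
    transcript_id = as.character(x[[transcript_col]]),
    start = if (start_col %in% names(x)) as.integer(x[[start_col]]) else NA_integer_,
    end = if (end_col %in% names(x)) as.integer(x[[end_col]]) else NA_integer_,
    score = if (score_col %in% names(x)) as.numeric(x[[score_col]]) else NA_real_,
    scheme = scheme_name)
  new_prediction_set(sites, genome_label, scheme_name)
}

#' Write or read a site report TSV
#'
#' @param x A `prediction_set`.
#' @param path File path.
#' @return `write_sites()` returns `path` invisibly; `read_sites()` returns a
#'   `prediction_set`.
#' @export
write_sites <- function(x, path) {
  utils::write.table(x$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @param genome_label,scheme_name Labels for the restored set.
#' @export
read_sites <- function(path, genome_label, scheme_name) {
  sites <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  new_prediction_set(sites, genome_label, scheme_name)
}
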