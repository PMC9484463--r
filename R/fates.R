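#' Classify the fate of one regulation in one ecotype
#'
#' Given whether the (miRNA, transcript) pair is predicted by scheme A and
#' scheme B in the reference genome and in the ecotype genome, assigns the
#' per-ecotype fate symbol:
#'
#' * `k` (kept): both schemes agree in the reference and both agree in the
#'   ecotype;
#' * `l` (lost): both schemes agree in the reference, neither detects it in
#'   the ecotype;
#' * `g` (gained): neither scheme detects it in the reference, both agree in
#'   the ecotype;
#' * `n` (absent): detected by no scheme in either genome;
#' * `o` (ambiguous): exactly one scheme detects the pair in the reference
#'   or in the ecotype genome, i.e. tool agreement fails somewhere.
#'
#' The full 16-row decision table follows from those rules: with `R` the
#' number of detecting schemes in the reference and `E` in the ecotype,
#' `(R,E) = (2,2) -> k`, `(2,0) -> l`, `(0,2) -> g`, `(0,0) -> n`, and any
#' combination with `R == 1` or `E == 1` is `o`.
#'
#' @param in_ref_a,in_ref_b,in_eco_a,in_eco_b Logical scalars or vectors:
#'   predicted by scheme A/B in the reference/ecotype genome.
#' @return Character vector of fate symbols in `{k, l, g, o, n}`.
#' @export
classify_pair_in_ecotype <- function(in_ref_a, in_ref_b, in_eco_a, in_eco_b) {
  r <- as.integer(in_ref_a) + as.integer(in_ref_b)
  e <- as.integer(in_eco_a) + as.integer(in_eco_b)
  dplyr::case_when(
    r == 2L & e == 2L ~ "k",
    r == 2L & e == 0L ~ "l",
    r == 0L & e == 2L ~ "g",
    r == 0L & e == 0L ~ "n",
    TRUE ~ "o")
}

#' Build regulation fate profiles across a population
#'
#' Combines reference and per-ecotype prediction sets into one fate profile
#' per regulation. Profiles are built for every (miRNA, transcript) pair that
#' is in the reference two-scheme intersection or is gained (`g`) in at least
#' one ecotype. Ecotypes in which the miRNA or the transcript was discarded
#' (indel-bearing) carry no fate and are marked `"."`.
#'
#' @param ref_a,ref_b Reference `prediction_set`s of scheme A and B (or any
#'   tibbles with `mirna_id`, `transcript_id`).
#' @param ecotype_predictions Named list (one element per ecotype) of lists
#'   with elements `a` and `b` (that ecotype's prediction sets) and
#'   `discarded` (character vector of discarded sequence ids).
#' @return A `fate_profiles` object: `regulations` tibble (`mirna_id`,
#'   `transcript_id`, `in_reference`, `general_fate`), the fate matrix
#'   (regulations x ecotypes, symbols in `{k,l,g,o,n,.}`), and the ecotype
#'   vector.
#' @export
build_fate_profiles <- function(ref_a, ref_b, ecotype_predictions) {
  pa <- prediction_pairs(ref_a)
  pb <- prediction_pairs(ref_b)
  key <- function(p) paste(p$mirna_id, p$transcript_id, sep = "\r")
  ref_int <- inner_join(pa, pb, by = c("mirna_id", "transcript_id"))
  ref_any_keys <- union(key(pa), key(pb))
  eco_pairs <- purrr::map(ecotype_predictions, function(e) {
    list(a = key(prediction_pairs(e$a)), b = key(prediction_pairs(e$b)),
         discarded = e$discarded %||% character())
  })
  gained_keys <- unique(unlist(purrr::map(eco_pairs, function(e) {
    setdiff(intersect(e$a, e$b), ref_any_keys)
  })))
  keys <- union(key(ref_int), gained_keys)
  if (!length(keys)) abort("no regulation passes the profile criteria")
  parts <- strsplit(keys, "\r", fixed = TRUE)
  regs <- tibble(mirna_id = purrr::map_chr(parts, 1),
                 transcript_id = purrr::map_chr(parts, 2))
  ra <- keys %in% key(pa)
  rb <- keys %in% key(pb)
  ecotypes <- names(ecotype_predictions)
  fates <- matrix(".", nrow = length(keys), ncol = length(ecotypes),
                  dimnames = list(keys, ecotypes))
  for (eco in ecotypes) {
    e <- eco_pairs[[eco]]
    avail <- !(regs$mirna_id %in% e$discarded |
                 regs$transcript_id %in% e$discarded)
    f <- classify_pair_in_ecotype(ra, rb, keys %in% e$a, keys %in% e$b)
    fates[avail, eco] <- f[avail]
  }
  regs$in_reference <- ra & rb
  has_fate <- rowSums(fates != ".") > 0L
  regs$general_fate <- NA_character_
  regs$general_fate[has_fate] <- vapply(which(has_fate), function(i) {
    general_fate_symbols(fates[i, ], regs$in_reference[i])
  }, character(1))
  keep <- !is.na(regs$general_fate)
  structure(list(regulations = regs[keep, , drop = FALSE],
                 fates = fates[keep, , drop = FALSE],
                 ecotypes = ecotypes),
            class = "fate_profiles")
}

prediction_pairs <- function(x) {
  if (inherits(x, "prediction_set")) x$pairs
  else distinct(as_tibble(x)[c("mirna_id", "transcript_id")])
}

#' General fate of a regulation
#'
#' Population-level summary of a fate profile: `K` when the regulation is in
#' the reference intersection and never lost, `KL` when it is lost in at
#' least one (but not every) ecotype, `L` when lost in every ecotype with a
#' defined fate, and `G` when absent from the reference but gained in at
#' least one ecotype. Regulations with general fate `K` are "static";
#' `KL` and `G` are "dynamic".
#'
#' @param profile A `fate_profile` (see [fate_profile()]) or a row of a
#'   `fate_profiles` object extracted with [profile_at()].
#' @return One of `"K"`, `"KL"`, `"G"`, `"L"`.
#' @export
general_fate <- function(profile) {
  out <- general_fate_symbols(profile$fates, profile$in_reference)
  if (is.na(out)) abort("profile has no ecotype qualifying for a general fate")
  out
}

general_fate_symbols <- function(fates, in_reference) {
  defined <- fates[fates != "."]
  if (!length(defined)) abort("profile has zero defined fates")
  if (in_reference) {
    n_l <- sum(defined == "l")
    if (n_l == 0L) "K"
    else if (all(defined == "l")) "L"
    else "KL"
  } else {
    if (any(defined == "g")) "G" else NA_character_
  }
}

#' Construct a single regulation fate profile
#'
#' Lightweight constructor used for direct co-regulation scoring and in
#' tests; the population pipeline builds whole [build_fate_profiles()]
#' objects instead.
#'
#' @param mirna_id,transcript_id Regulation key.
#' @param fates Named character vector of per-ecotype fate symbols in
#'   `{k,l,g,o,n,.}` (`.` marks ecotypes with a discarded sequence).
#' @param in_reference Was the pair found by both schemes in the reference?
#' @param general Optional general fate; computed from the fates if `NULL`.
#' @return A `fate_profile` object.
#' @export
fate_profile <- function(mirna_id, transcript_id, fates, in_reference,
                         general = NULL) {
  if (is.null(names(fates))) {
    names(fates) <- paste0("eco", seq_along(fates))
  }
  bad <- setdiff(unique(fates), c("k", "l", "g", "o", "n", "."))
  if (length(bad)) abort(paste0("unknown fate symbol: ", paste(bad, collapse = ", ")))
  p <- structure(list(mirna_id = mirna_id, transcript_id = transcript_id,
                      fates = fates, in_reference = in_reference,
                      general_fate = general),
                 class = "fate_profile")
  if (is.null(p$general_fate)) p$general_fate <- general_fate(p)
  p
}

#' Extract one regulation's profile from a population object
#'
#' @param profiles A `fate_profiles` object.
#' @param mirna_id,transcript_id Regulation key.
#' @return A [fate_profile()].
#' @export
profile_at <- function(profiles, mirna_id, transcript_id) {
  i <- which(profiles$regulations$mirna_id == mirna_id &
               profiles$regulations$transcript_id == transcript_id)
  if (!length(i)) abort("no profile for this regulation")
  fate_profile(mirna_id, transcript_id, profiles$fates[i, ],
               profiles$regulations$in_reference[i],
               profiles$regulations$general_fate[i])
}

#' @export
print.fate_profiles <- function(x, ...) {
  cat("<fate_profiles> ", nrow(x$regulations), " regulations x ",
      length(x$ecotypes), " ecotypes\n", sep = "")
  print(count(x$regulations, .data$general_fate))
  invisible(x)
}

#' Tidy a fate profile collection
#'
#' @param x A `fate_profiles` object.
#' @param ... Unused.
#' @return Long tibble: `mirna_id`, `transcript_id`, `ecotype`, `fate`.
#' @export
tidy.fate_profiles <- function(x, ...) {
  regs <- x$regulations
  tibble(mirna_id = rep(regs$mirna_id, times = length(x$ecotypes)),
         transcript_id = rep(regs$transcript_id, times = length(x$ecotypes)),
         ecotype = rep(x$ecotypes, each = nrow(regs)),
         fate = as.vector(x$fates))
}

#' @rdname tidy.fate_profiles
#' @export
glance.fate_profiles <- function(x, ...) {
  gf <- x$regulations$general_fate
  tibble(n_regulations = nrow(x$regulations),
         n_ecotypes = length(x$ecotypes),
         n_K = sum(gf == "K"), n_KL = sum(gf == "KL"),
         n_G = sum(gf == "G"), n_L = sum(gf == "L"),
         n_static = sum(gf == "K"), n_dynamic = sum(gf %in% c("KL", "G")))
}

#' Write a fate matrix to TSV
#'
#' Rows are regulations, columns ecotypes, cells the fate symbols
#' (`.` = sequence discarded); a second TSV holds the general-fate summary.
#'
#' @param profiles A `fate_profiles` object.
#' @param path Path for the fate matrix TSV; the summary is written next to
#'   it with suffix `_general.tsv`.
#' @return The two paths, invisibly.
#' @export
write_fate_matrix <- function(profiles, path) {
  mat <- as.data.frame(profiles$fates)
  out <- bind_cols(profiles$regulations[c("mirna_id", "transcript_id")], mat)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sum_path <- sub("\\.tsv$", "_general.tsv", path)
  utils::write.table(profiles$regulations, sum_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(path, sum_path))
}
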