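#' Materialize the sequence of one ecotype
#'
#' Builds the pseudo-sequence an ecotype carries for a given miRNA or
#' transcript. Ecotypes carrying at least one indel in the sequence are
#' discarded (frameshift semantics); ecotypes carrying only SNPs receive a
#' mutant-type sequence with the substitutions applied; ecotypes with no
#' variant are wild type and keep the reference sequence.
#'
#' Substitution validates the reference allele at each position, so applying
#' variants to an already-materialized mutant sequence fails rather than
#' silently re-mutating.
#'
#' @param panel An [ecotype_panel()].
#' @param seq_id Sequence identifier.
#' @param ecotype_id Ecotype identifier.
#' @return A one-row tibble with columns `seq_id`, `ecotype_id`, `status`
#'   (`"wild"`, `"mutant"` or `"discarded"`) and `sequence` (`NA` when
#'   discarded).
#' @export
materialize <- function(panel, seq_id, ecotype_id) {
  i <- which(panel$sequences$id == seq_id)
  if (!length(i)) abort(paste0("unknown seq_id: ", seq_id))
  if (!ecotype_id %in% panel$ecotypes) {
    abort(paste0("unknown ecotype: ", ecotype_id))
  }
  v <- panel$variants[panel$variants$seq_id == seq_id, , drop = FALSE]
  v <- v[purrr::map_lgl(v$carriers, ~ ecotype_id %in% .x), , drop = FALSE]
  ref_seq <- panel$sequences$sequence[i[1]]
  kind <- panel$sequences$kind[i[1]]
  if (nrow(v) == 0L) {
    status <- "wild"; seq <- ref_seq
  } else if (any(v$type == "indel")) {
    status <- "discarded"; seq <- NA_character_
  } else {
    status <- "mutant"
    seq <- apply_snps(ref_seq, v$pos, v$ref, v$alt, kind)
  }
  tibble(seq_id = seq_id, ecotype_id = ecotype_id, status = status,
         sequence = seq)
}

apply_snps <- function(sequence, pos, ref, alt, kind) {
  if (anyDuplicated(pos)) {
    abort(paste0("conflicting SNP alleles at one position (multi-allelic ",
                 "conflict) at pos ", paste(pos[duplicated(pos)], collapse = ", ")))
  }
  ref <- canonicalize_seq(ref, kind)
  alt <- canonicalize_seq(alt, kind)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (any(chars[pos] != ref)) {
    bad <- pos[chars[pos] != ref]
    abort(paste0("reference allele mismatch at position ",
                 paste(bad, collapse = ", "),
                 " (variants may already be applied)"))
  }
  chars[pos] <- alt
  paste(chars, collapse = "")
}

#' Materialize all sequences for all ecotypes
#'
#' Sparse summary of [materialize()] over the whole panel: only ecotypes that
#' deviate from wild type appear in the returned rows; every absent
#' (sequence, ecotype) combination is wild type. For each sequence,
#' `|wild| + |mutant| + |discarded|` equals the number of panel ecotypes.
#'
#' @param panel An [ecotype_panel()].
#' @return A tibble with columns `seq_id`, `ecotype_id`, `status`, `sequence`
#'   covering all non-wild combinations.
#' @export
materialize_all <- function(panel) {
  v <- panel$variants
  if (nrow(v) == 0L) {
    return(tibble(seq_id = character(), ecotype_id = character(),
                  status = character(), sequence = character()))
  }
  long <- tidyr::unnest(
    tibble(seq_id = v$seq_id, pos = v$pos, ref = v$ref, alt = v$alt,
           type = v$type, ecotype_id = v$carriers),
    "ecotype_id")
  kind_of <- setNames(panel$sequences$kind, panel$sequences$id)
  seq_of <- setNames(panel$sequences$sequence, panel$sequences$id)
  long %>%
    group_by(.data$seq_id, .data$ecotype_id) %>%
    summarise(status = if (any(.data$type == "indel")) "discarded" else "mutant",
              sequence = if (any(.data$type == "indel")) NA_character_ else
                apply_snps(seq_of[[.data$seq_id[1]]], .data$pos, .data$ref,
                           .data$alt, kind_of[[.data$seq_id[1]]]),
              .groups = "drop")
}
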