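#' Population-level regulation fate profiles from an ecotype panel
#'
#' End-to-end driver for the three-step population pipeline: (1) singleton
#' variants are removed and every (sequence, ecotype) combination is
#' materialized as wild type, mutant type, or discarded (indel-bearing);
#' (2) target sites are predicted with both scoring schemes in the reference
#' genome and in every ecotype pseudo-genome, rescanning only pairs touched
#' by a mutant sequence; (3) per-ecotype fates and general fates are
#' assembled into regulation fate profiles.
#'
#' @param panel An [ecotype_panel()].
#' @param scheme_1,scheme_2 The two [scoring_scheme()]s whose pair-level
#'   intersection defines tool agreement.
#' @param drop_singletons Remove singleton variants first (default `TRUE`).
#' @return A `fate_profiles` object (see [build_fate_profiles()]).
#' @export
population_fate_profiles <- function(panel, scheme_1 = scheme_a(),
                                     scheme_2 = scheme_b(),
                                     drop_singletons = TRUE) {
  variants <- if (drop_singletons) filter_singletons(panel$variants)
  else panel$variants
  work <- panel
  work$variants <- variants
  mat <- materialize_all(work)
  mirnas <- dplyr::filter(panel$sequences, .data$kind == "mirna")
  transcripts <- dplyr::filter(panel$sequences, .data$kind == "transcript")
  ref_1 <- predict_all(mirnas[c("id", "sequence")],
                       transcripts[c("id", "sequence")], scheme_1)
  ref_2 <- predict_all(mirnas[c("id", "sequence")],
                       transcripts[c("id", "sequence")], scheme_2)
  by_eco <- if (nrow(mat)) split(mat, mat$ecotype_id) else list()
  eco_preds <- purrr::map(setNames(panel$ecotypes, panel$ecotypes),
                          function(eco) {
    rows <- by_eco[[eco]]
    if (is.null(rows)) {
      return(list(a = ref_1, b = ref_2, discarded = character()))
    }
    discarded <- rows$seq_id[rows$status == "discarded"]
    mut <- rows[rows$status == "mutant", , drop = FALSE]
    m_eco <- substitute_sequences(mirnas, mut, discarded)
    t_eco <- substitute_sequences(transcripts, mut, discarded)
    list(a = predict_all(m_eco, t_eco, scheme_1, genome_label = eco,
                         reference = ref_1, mutant_ids = mut$seq_id),
         b = predict_all(m_eco, t_eco, scheme_2, genome_label = eco,
                         reference = ref_2, mutant_ids = mut$seq_id),
         discarded = discarded)
  })
  build_fate_profiles(ref_1, ref_2, eco_preds)
}

substitute_sequences <- function(sequences, mutants, discarded) {
  out <- sequences[!sequences$id %in% discarded, c("id", "sequence")]
  idx <- match(out$id, mutants$seq_id)
  hit <- !is.na(idx)
  out$sequence[hit] <- mutants$sequence[idx[hit]]
  out
}
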