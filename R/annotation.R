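#' Evolutionary lineage ladder
#'
#' The default 11 age groups, ordered oldest to youngest, used to date genes
#' and miRNAs by the oldest lineage represented in their ortholog group or
#' homolog hit set.
#'
#' @return Character vector of ordered age labels.
#' @export
lineage_ladder <- function() {
  c("Cellular organisms", "Eukaryota", "Green plants", "Land plants",
    "Vascular plants", "Seed plants", "Flowering plants", "Eudicots",
    "Rosids", "Brassicaceae", "A. thaliana")
}

check_lineages <- function(x, ladder) {
  bad <- setdiff(unique(x), ladder)
  if (length(bad)) {
    abort(paste0("unknown lineage label(s): ", paste(bad, collapse = ", ")))
  }
}

#' Assign evolutionary ages to ortholog groups
#'
#' Each group's age is the oldest lineage among its members (the earliest
#' common ancestor); a group is conserved when it has at least one member
#' outside *A. thaliana* (the youngest rung of the ladder).
#'
#' @param groups Tibble with columns `group_id`, `gene_id`, `lineage`.
#' @param ladder Ordered lineage labels, oldest first.
#' @return Tibble: `group_id`, `age`, `conserved`.
#' @export
assign_gene_age <- function(groups, ladder = lineage_ladder()) {
  groups <- as_tibble(groups)
  if (nrow(groups) == 0L) abort("empty ortholog group table")
  check_lineages(groups$lineage, ladder)
  youngest <- ladder[length(ladder)]
  groups %>%
    group_by(.data$group_id) %>%
    summarise(age = ladder[min(match(.data$lineage, ladder))],
              conserved = any(.data$lineage != youngest),
              .groups = "drop")
}

#' Filter cross-species miRNA hits and date conserved miRNAs
#'
#' A miRNA is conserved when it has at least one homolog hit with E-value
#' <= 0.01, at least 90% of both the query and the subject sequence covered,
#' and at most 2 mismatches. Its age is the oldest passing subject lineage,
#' floored at Land plants (older assignments are clamped with a message,
#' since no plant miRNA predates land plants in this framework).
#'
#' @param hits Tibble with columns `query_mirna`, `subject_lineage`,
#'   `e_value`, `query_coverage`, `subject_coverage`, `mismatches`.
#' @param mirnas Character vector of all miRNA ids; ids without a passing hit
#'   are reported as non-conserved.
#' @param ladder Ordered lineage labels, oldest first.
#' @return Tibble: `mirna_id`, `conserved`, `age` (`NA` for non-conserved).
#' @export
filter_mirna_hits <- function(hits, mirnas = NULL, ladder = lineage_ladder()) {
  hits <- as_tibble(hits)
  check_lineages(hits$subject_lineage, ladder)
  pass <- hits$e_value <= 0.01 &
    hits$query_coverage >= 0.9 & hits$subject_coverage >= 0.9 &
    hits$mismatches <= 2
  passed <- hits[pass, , drop = FALSE]
  floor_idx <- match("Land plants", ladder)
  aged <- passed %>%
    group_by(mirna_id = .data$query_mirna) %>%
    summarise(age_idx = min(match(.data$subject_lineage, ladder)),
              .groups = "drop")
  clamped <- aged$age_idx < floor_idx
  if (any(clamped)) {
    inform(paste0("age of ", sum(clamped),
                  " conserved miRNA(s) clamped to Land plants"))
    aged$age_idx[clamped] <- floor_idx
  }
  aged$age <- ladder[aged$age_idx]
  aged$conserved <- TRUE
  mirnas <- mirnas %||% unique(hits$query_mirna)
  tibble(mirna_id = mirnas) %>%
    left_join(aged[c("mirna_id", "conserved", "age")], by = "mirna_id") %>%
    mutate(conserved = !is.na(.data$conserved))
}

#' Classify a miRNA family by member conservation
#'
#' A multi-member family is a conserved family when strictly more than half
#' of its members are conserved.
#'
#' @param members Character vector of the family's miRNA ids (>= 2 members).
#' @param conservation Named logical vector `mirna_id -> conserved`.
#' @return `"conserved_family"` or `"non_conserved_family"`.
#' @export
classify_family <- function(members, conservation) {
  if (length(members) < 2L) {
    abort("single-member families are excluded from family analyses")
  }
  cons <- conservation[members]
  if (anyNA(cons)) abort("conservation label missing for some members")
  if (sum(cons) * 2L > length(members)) "conserved_family"
  else "non_conserved_family"
}

#' Intra- or inter-family relation of a miRNA pair
#'
#' @param mirna_i,mirna_j Distinct miRNA ids.
#' @param family_map Named character vector `mirna_id -> family_id`.
#' @return `"intra"` or `"inter"`. Pairs with an unassigned member are
#'   labeled `"inter"` with a warning.
#' @export
pair_family_relation <- function(mirna_i, mirna_j, family_map) {
  if (mirna_i == mirna_j) abort("self-pairs are not allowed")
  fi <- family_map[mirna_i]; fj <- family_map[mirna_j]
  if (is.na(fi) || is.na(fj)) {
    warn(paste0("miRNA without family assignment: ",
                paste(c(mirna_i, mirna_j)[is.na(c(fi, fj))], collapse = ", ")))
    return("inter")
  }
  if (unname(fi) == unname(fj)) "intra" else "inter"
}
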