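#' Shared targets of two miRNAs
#'
#' @param profiles A `fate_profiles` object.
#' @param mirna_i,mirna_j Distinct miRNA identifiers.
#' @return Character vector of transcript ids with a fate profile for both
#'   miRNAs.
#' @export
shared_targets <- function(profiles, mirna_i, mirna_j) {
  if (mirna_i == mirna_j) abort("mirna_i and mirna_j must differ")
  regs <- profiles$regulations
  intersect(regs$transcript_id[regs$mirna_id == mirna_i],
            regs$transcript_id[regs$mirna_id == mirna_j])
}

#' Co-regulation (coreg) score of two regulations toward one target
#'
#' The coreg score is the fraction of ecotypes in the shared ecotype universe
#' (ecotypes where the two miRNAs and the target are all wild or mutant type,
#' none discarded) in which the two regulations present the same fate:
#' both kept (`EcoK`), both lost (`EcoL`), or both gained (`EcoG`). Two
#' guards apply: when both general fates are `KL`, the score is forced to 0
#' unless the two regulations are lost together in at least one ecotype
#' (`EcoL` nonempty).
#'
#' Two numerator conventions are available. Mode `"extended"` (default)
#' additionally counts ecotypes in which both regulations are absent (`n`)
#' as agreement and, symmetrically to the `KL` rule, forces a `G`/`G` motif
#' to 0 unless the regulations are gained together at least once (`EcoG`
#' nonempty); this keeps a pair of regulations gained in the same small
#' ecotype group at score 1 while rejecting disjoint-gain coincidences.
#' Mode `"literal"` counts only `EcoK`, `EcoL` and `EcoG` and applies only
#' the `KL` guard. Joint `o` (single-scheme ambiguity) never counts as
#' agreement in either mode. Motifs whose general fates can never present
#' equal per-ecotype fates (`K`/`G`, `KL`/`G`, or any `L`) score 0.
#'
#' @param profile_i,profile_j [fate_profile()]s toward the same target.
#' @param mode `"extended"` or `"literal"`.
#' @return The coreg score in `[0, 1]`, or `NA` (with a warning) when the
#'   shared ecotype universe is empty.
#' @export
coreg_score <- function(profile_i, profile_j, mode = c("extended", "literal")) {
  mode <- match.arg(mode)
  if (!identical(profile_i$transcript_id, profile_j$transcript_id)) {
    abort("both profiles must reference the same target")
  }
  eco <- intersect(names(profile_i$fates), names(profile_j$fates))
  coreg_from_fates(profile_i$fates[eco], profile_j$fates[eco],
                   profile_i$general_fate, profile_j$general_fate, mode)
}

coreg_from_fates <- function(fi, fj, gi, gj, mode) {
  avail <- fi != "." & fj != "."
  fi <- fi[avail]; fj <- fj[avail]
  if (!length(fi)) {
    warn("empty shared ecotype universe; coreg undefined")
    return(NA_real_)
  }
  type <- coreg_type_symbols(gi, gj)
  if (type == "excluded") return(0)
  n_k <- sum(fi == "k" & fj == "k")
  n_l <- sum(fi == "l" & fj == "l")
  n_g <- sum(fi == "g" & fj == "g")
  if (gi == "KL" && gj == "KL" && n_l == 0L) return(0)
  if (mode == "extended") {
    if (gi == "G" && gj == "G" && n_g == 0L) return(0)
    n_n <- sum(fi == "n" & fj == "n")
    (n_k + n_l + n_g + n_n) / length(fi)
  } else {
    (n_k + n_l + n_g) / length(fi)
  }
}

#' Co-regulation type of a motif
#'
#' Motif-level label from the two regulations' general fates: `ss`
#' (static-static, both `K`), `sd` (static-dynamic, `K` with `KL`), `dd`
#' (dynamic-dynamic, both `KL` or both `G`). Mixed combinations whose
#' per-ecotype fates can never agree (`K`/`G`, `KL`/`G`) and any combination
#' involving `L` are `excluded`.
#'
#' @param general_fate_i,general_fate_j General fates in `{K, KL, G, L}`.
#' @return `"ss"`, `"sd"`, `"dd"` or `"excluded"`.
#' @export
motif_coreg_type <- function(general_fate_i, general_fate_j) {
  coreg_type_symbols(general_fate_i, general_fate_j)
}

coreg_type_symbols <- function(gi, gj) {
  pair <- sort(c(gi, gj))
  if (any(pair == "L")) return("excluded")
  if (pair[1] == "K" && pair[2] == "K") "ss"
  else if (pair[1] == "K" && pair[2] == "KL") "sd"
  else if ((pair[1] == "KL" && pair[2] == "KL") ||
           (pair[1] == "G" && pair[2] == "G")) "dd"
  else "excluded"
}

#' Enumerate co-regulation motifs
#'
#' One motif per (miRNA pair, shared target) with its coreg score and
#' co-regulation type. Motifs with an empty shared ecotype universe are
#' dropped with a warning.
#'
#' @param profiles A `fate_profiles` object.
#' @param mode Coreg mode, see [coreg_score()].
#' @return Tibble: `mirna_i`, `mirna_j` (canonical order), `target`,
#'   `coreg`, `coreg_type`, `n_eco` (universe size).
#' @export
coreg_motifs <- function(profiles, mode = c("extended", "literal")) {
  mode <- match.arg(mode)
  regs <- profiles$regulations
  out <- list()
  for (t in unique(regs$transcript_id)) {
    idx <- which(regs$transcript_id == t)
    if (length(idx) < 2L) next
    prs <- combn(idx, 2L)
    for (c in seq_len(ncol(prs))) {
      i <- prs[1, c]; j <- prs[2, c]
      fi <- profiles$fates[i, ]; fj <- profiles$fates[j, ]
      avail <- sum(fi != "." & fj != ".")
      if (avail == 0L) {
        warn(paste0("motif (", regs$mirna_id[i], ", ", regs$mirna_id[j], ", ",
                    t, ") has empty ecotype universe; dropped"))
        next
      }
      m <- sort(c(regs$mirna_id[i], regs$mirna_id[j]))
      out[[length(out) + 1L]] <- tibble(
        mirna_i = m[1], mirna_j = m[2], target = t,
        coreg = coreg_from_fates(fi, fj, regs$general_fate[i],
                                 regs$general_fate[j], mode),
        coreg_type = coreg_type_symbols(regs$general_fate[i],
                                        regs$general_fate[j]),
        n_eco = avail)
    }
  }
  if (!length(out)) {
    return(tibble(mirna_i = character(), mirna_j = character(),
                  target = character(), coreg = numeric(),
                  coreg_type = character(), n_eco = integer()))
  }
  bind_rows(out)
}

#' Build the miRNA-miRNA crosstalk network
#'
#' Scores every co-regulation motif, removes motifs whose coreg score is
#' strictly smaller than the threshold, and connects two miRNAs when at
#' least one shared target survives. Each edge receives a crosstalk type
#' from the strict majority of its surviving motifs' co-regulation types.
#' The "unfiltered" pair set (all miRNA pairs sharing a target) and the
#' "deleted" pair set (pairs whose targets were all removed) are retained
#' for quality evaluation.
#'
#' @param profiles A `fate_profiles` object.
#' @param threshold Coreg threshold in `[0, 1]`; motifs with
#'   `coreg < threshold` are removed (ties at the threshold survive).
#' @param mode Coreg mode, see [coreg_score()].
#' @return A `crosstalk_network`: list with `nodes`, `edges`, `motifs`,
#'   `unfiltered_pairs`, `deleted_pairs`, `threshold`, `mode`.
#' @export
build_network <- function(profiles, threshold = 0.85,
                          mode = c("extended", "literal")) {
  mode <- match.arg(mode)
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0, 1]")
  motifs <- coreg_motifs(profiles, mode)
  motifs$surviving <- motifs$coreg >= threshold
  unfiltered <- distinct(motifs[c("mirna_i", "mirna_j")])
  surv <- motifs[motifs$surviving, , drop = FALSE]
  edges <- surv %>%
    group_by(.data$mirna_i, .data$mirna_j) %>%
    summarise(n_targets = dplyr::n(),
              crosstalk_type = majority_type(.data$coreg_type),
              .groups = "drop")
  deleted <- anti_join(unfiltered, edges, by = c("mirna_i", "mirna_j"))
  nodes <- tibble(mirna_id = sort(unique(c(edges$mirna_i, edges$mirna_j))))
  structure(list(nodes = nodes, edges = edges, motifs = motifs,
                 unfiltered_pairs = unfiltered, deleted_pairs = deleted,
                 threshold = threshold, mode = mode),
            class = "crosstalk_network")
}

majority_type <- function(types) {
  tab <- table(types[types %in% c("ss", "sd", "dd")])
  if (!length(tab)) return("unclassified")
  top <- names(tab)[which.max(tab)]
  if (max(tab) * 2L > length(types)) toupper(top) else "unclassified"
}

#' Crosstalk type of one edge
#'
#' The co-regulation type held by strictly more than half of the edge's
#' surviving motifs, capitalized; `"unclassified"` when no strict majority
#' exists.
#'
#' @param edge A one-row edge tibble or a character vector of surviving
#'   motif co-regulation types.
#' @return `"SS"`, `"SD"`, `"DD"` or `"unclassified"`.
#' @export
crosstalk_type <- function(edge) {
  types <- if (is.character(edge)) edge else edge$coreg_type
  if (!length(types)) abort("edge must have at least one surviving motif")
  majority_type(types)
}

#' @export
print.crosstalk_network <- function(x, ...) {
  cat("<crosstalk_network> ", nrow(x$nodes), " miRNAs, ", nrow(x$edges),
      " edges (threshold ", x$threshold, ", mode ", x$mode, ")\n", sep = "")
  if (nrow(x$edges)) print(count(x$edges, .data$crosstalk_type))
  invisible(x)
}

#' Tidy and summarise a crosstalk network
#'
#' @param x A `crosstalk_network`.
#' @param ... Unused.
#' @return `tidy()` returns the edge tibble; `glance()` a one-row summary
#'   with node/edge counts and per-crosstalk-type counts.
#' @export
tidy.crosstalk_network <- function(x, ...) x$edges

#' @rdname tidy.crosstalk_network
#' @export
glance.crosstalk_network <- function(x, ...) {
  ct <- x$edges$crosstalk_type
  tibble(n_mirnas = nrow(x$nodes), n_edges = nrow(x$edges),
         n_targets = length(unique(x$motifs$target[x$motifs$surviving])),
         n_SS = sum(ct == "SS"), n_SD = sum(ct == "SD"),
         n_DD = sum(ct == "DD"), n_unclassified = sum(ct == "unclassified"),
         threshold = x$threshold)
}

#' Convert a crosstalk network to igraph
#'
#' @param x A `crosstalk_network`.
#' @return An undirected simple [igraph::graph] with edge attribute
#'   `crosstalk_type`.
#' @export
as_igraph <- function(x) {
  igraph::graph_from_data_frame(
    x$edges[c("mirna_i", "mirna_j", "crosstalk_type")],
    directed = FALSE,
    vertices = x$nodes$mirna_id)
}

#' Write network tables to TSV
#'
#' @param x A `crosstalk_network`.
#' @param dir Output directory.
#' @return Paths of the edge and motif TSVs, invisibly.
#' @export
write_network <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edge_path <- file.path(dir, "edges.tsv")
  motif_path <- file.path(dir, "motifs.tsv")
  utils::write.table(x$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$motifs, motif_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges = edge_path, motifs = motif_path))
}

#' Plot a crosstalk network
#'
#' Force-directed layout with edges colored by crosstalk type.
#'
#' @param object A `crosstalk_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crosstalk_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(mirna_id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  ed <- object$edges %>%
    left_join(nodes, by = c(mirna_i = "mirna_id")) %>%
    rename(x0 = "x", y0 = "y") %>%
    left_join(nodes, by = c(mirna_j = "mirna_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y,
                                       colour = .data$crosstalk_type)) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 2) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "crosstalk type")
}
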