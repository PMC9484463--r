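#' Read mature miRNA or transcript sequences from FASTA
#'
#' Sequences are canonicalized to uppercase, with the internal alphabet
#' `A,C,G,U` for miRNAs and `A,C,G,T` for transcripts (U and T are treated as
#' equivalent; the comparison layer of the duplex scorer handles the mapping).
#'
#' @param path Path to a FASTA file.
#' @param kind `"mirna"` or `"transcript"`.
#' @param gene_map Optional data frame with columns `id` and `gene_id` mapping
#'   transcript identifiers to gene identifiers.
#' @return A tibble with columns `id`, `kind`, `gene_id`, `sequence`.
#' @export
read_fasta <- function(path, kind = c("mirna", "transcript"), gene_map = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warn(paste0("empty FASTA file: ", path))
    return(tibble(id = character(), kind = character(),
                  gene_id = character(), sequence = character()))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- unname(canonicalize_seq(as.character(set), kind))
  bad <- grepl("[^ACGUT]", seqs)
  if (any(bad)) {
    abort(paste0("non-nucleotide characters in sequence(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  out <- tibble(id = ids, kind = kind, gene_id = NA_character_, sequence = seqs)
  if (kind == "mirna") {
    len <- nchar(out$sequence)
    if (any(len < 18L | len > 26L)) {
      abort(paste0("mature miRNA length outside 18-26 nt: ",
                   paste(out$id[len < 18L | len > 26L], collapse = ", ")))
    }
  }
  if (!is.null(gene_map) && kind == "transcript") {
    gene_map <- as_tibble(gene_map)
    out$gene_id <- gene_map$gene_id[match(out$id, gene_map$id)]
  }
  out
}

#' Write sequence records to FASTA
#'
#' @param sequences A tibble as returned by [read_fasta()] (columns `id`,
#'   `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(setNames(sequences$sequence, sequences$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# uppercase and map U/T to the kind's alphabet
canonicalize_seq <- function(x, kind) {
  x <- toupper(x)
  if (kind == "mirna") gsub("T", "U", x, fixed = TRUE)
  else gsub("U", "T", x, fixed = TRUE)
}

#' Read a sequence-local variant table (VCF dialect)
#'
#' The expected dialect is an ordinary VCF whose `CHROM` column holds the
#' sequence identifier (miRNA or transcript id) and whose `POS` is 1-based
#' within that sequence. Genotype columns name ecotypes; an ecotype is a
#' carrier of an allele when its genotype string contains that alternate
#' allele's index (heterozygous calls count as carriers). Multi-allelic rows
#' are split into biallelic records.
#'
#' @param path Path to a VCF file.
#' @param sequences Optional sequence tibble (from [read_fasta()], possibly
#'   row-bound across kinds) used to validate positions and reference alleles.
#' @return A tibble with columns `seq_id`, `pos`, `ref`, `alt`, `type`
#'   (`"snp"` or `"indel"`), and a list-column `carriers` of ecotype ids.
#' @export
read_variants <- function(path, sequences = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble(seq_id = character(), pos = integer(), ref = character(),
                  alt = character(), type = character(), carriers = list()))
  }
  gt <- v@gt
  samples <- if (!is.null(gt) && ncol(gt) > 1L) colnames(gt)[-1L] else character()
  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gts <- if (length(samples)) sub(":.*$", "", gt[i, -1L]) else character()
    purrr::map(seq_along(alts), function(a) {
      carriers <- if (length(samples)) {
        samples[grepl(as.character(a), gts, fixed = TRUE)]
      } else character()
      ref <- toupper(fix$REF[i]); alt <- toupper(alts[a])
      tibble(seq_id = fix$CHROM[i], pos = as.integer(fix$POS[i]),
             ref = ref, alt = alt,
             type = if (nchar(ref) == 1L && nchar(alt) == 1L) "snp" else "indel",
             carriers = list(unname(carriers)))
    })
  })
  out <- bind_rows(purrr::flatten(rows))
  if (!is.null(sequences)) validate_variants(out, sequences)
  out
}

validate_variants <- function(variants, sequences) {
  idx <- match(variants$seq_id, sequences$id)
  unknown <- is.na(idx)
  if (any(unknown)) {
    abort(paste0("variant seq_id not in sequence set: ",
                 paste(unique(variants$seq_id[unknown]), collapse = ", ")))
  }
  len <- nchar(sequences$sequence)[idx]
  bad_pos <- variants$pos < 1L | variants$pos + nchar(variants$ref) - 1L > len
  if (any(bad_pos)) {
    abort(paste0("variant position outside sequence for: ",
                 paste(unique(variants$seq_id[bad_pos]), collapse = ", ")))
  }
  # compare in the DNA alphabet; miRNA sequences are stored with U
  found <- toupper(substr(gsub("U", "T", sequences$sequence[idx], fixed = TRUE),
                          variants$pos, variants$pos + nchar(variants$ref) - 1L))
  stated <- gsub("U", "T", variants$ref, fixed = TRUE)
  bad_ref <- found != stated
  if (any(bad_ref)) {
    abort(paste0("REF allele disagrees with sequence at: ",
                 paste(paste0(variants$seq_id[bad_ref], ":",
                              variants$pos[bad_ref]), collapse = ", ")))
  }
  invisible(variants)
}

#' Remove singleton variants
#'
#' Biallelic variants whose alternate allele is carried by exactly one ecotype
#' are removed before any downstream analysis; all other records are retained.
#'
#' @param variants A variant tibble from [read_variants()].
#' @return The filtered variant tibble. The number of removed records is
#'   reported via a message.
#' @export
filter_singletons <- function(variants) {
  if (nrow(variants) == 0L) return(variants)
  keep <- lengths(variants$carriers) != 1L
  inform(paste0("filter_singletons: removed ", sum(!keep), " of ",
                length(keep), " variant records"))
  variants[keep, , drop = FALSE]
}

#' Variant density in variants per kilobase
#'
#' @param variants A variant tibble.
#' @param seq_id Optional sequence id to restrict to; `NULL` counts all records.
#' @param span_bp Length of the surveyed span in base pairs (must be positive).
#' @return Variants per kb as a single number.
#' @export
variant_density <- function(variants, seq_id = NULL, span_bp) {
  if (!is.numeric(span_bp) || span_bp <= 0) abort("span_bp must be > 0")
  n <- if (is.null(seq_id)) nrow(variants) else sum(variants$seq_id == seq_id)
  n * 1000 / span_bp
}

#' Assemble an ecotype panel
#'
#' Bundles the sequence universe, the variant table, and the ordered ecotype
#' list, and validates their mutual invariants (carriers are known ecotypes,
#' reference alleles match the sequences, identifiers are unique).
#'
#' @param sequences Tibble of sequence records (miRNAs and transcripts
#'   row-bound; see [read_fasta()]).
#' @param variants Variant tibble (see [read_variants()]).
#' @param ecotypes Character vector of ecotype identifiers; defaults to the
#'   sorted union of all carriers.
#' @return An object of class `ecotype_panel`.
#' @export
ecotype_panel <- function(sequences, variants, ecotypes = NULL) {
  sequences <- as_tibble(sequences)
  variants <- as_tibble(variants)
  if (anyDuplicated(paste(sequences$kind, sequences$id))) {
    abort("sequence ids must be unique within kind")
  }
  if (is.null(ecotypes)) ecotypes <- sort(unique(unlist(variants$carriers)))
  if (anyDuplicated(ecotypes)) abort("ecotype identifiers must be unique")
  stray <- setdiff(unique(unlist(variants$carriers)), ecotypes)
  if (length(stray)) {
    abort(paste0("carriers not in ecotype list: ", paste(stray, collapse = ", ")))
  }
  if (nrow(variants)) validate_variants(variants, sequences)
  structure(list(sequences = sequences, variants = variants,
                 ecotypes = ecotypes),
            class = "ecotype_panel")
}

#' @export
print.ecotype_panel <- function(x, ...) {
  cat("<ecotype_panel> ", sum(x$sequences$kind == "mirna"), " miRNAs, ",
      sum(x$sequences$kind == "transcript"), " transcripts, ",
      nrow(x$variants), " variant records, ",
      length(x$ecotypes), " ecotypes\n", sep = "")
  invisible(x)
}

#' Write an ecotype panel to disk
#'
#' Writes miRNA and transcript FASTA files and a sequence-local VCF holding
#' the variant table with one genotype column per ecotype.
#'
#' @param panel An [ecotype_panel()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mirna = file.path(dir, "mirnas.fa"),
             transcript = file.path(dir, "transcripts.fa"),
             vcf = file.path(dir, "variants.vcf"))
  write_fasta(dplyr::filter(panel$sequences, .data$kind == "mirna"), paths["mirna"])
  write_fasta(dplyr::filter(panel$sequences, .data$kind == "transcript"),
              paths["transcript"])
  write_panel_vcf(panel, paths["vcf"])
  invisible(paths)
}

write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  eco <- panel$ecotypes
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", eco), collapse = "\t"))
  body <- purrr::map_chr(seq_len(nrow(v)), function(i) {
    gt <- ifelse(eco %in% v$carriers[[i]], "1|1", "0|0")
    paste(c(v$seq_id[i], v$pos[i], ".",
            gsub("U", "T", v$ref[i], fixed = TRUE),
            gsub("U", "T", v$alt[i], fixed = TRUE),
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}
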