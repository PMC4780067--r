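#' Codon index of a CDS position
#'
#' CDS positions are transcript-relative and 1-based, matching "c." notation;
#' the codon index is `ceiling(cds_pos / 3)`, so c.601 falls in codon 201.
#'
#' @param cds_pos 1-based position(s) within the coding sequence.
#' @return Integer codon index (vectorised).
#' @examples
#' codon_of(601) # 201
#' @export
codon_of <- function(cds_pos) {
  if (any(cds_pos < 1)) stop("cds_pos must be >= 1")
  as.integer(ceiling(cds_pos / 3))
}

AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "*"
)

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract the coding sequence of one transcript
#'
#' @param gene_model Rows of a gene-model table for a single transcript:
#'   columns `gene`, `transcript`, `chrom`, `strand`, `seg_start`, `seg_end`
#'   (1-based inclusive genomic intervals in translation order).
#' @param genome A named [Biostrings::DNAStringSet] (or named character
#'   vector) of contig sequences.
#' @return Character scalar, the CDS on the coding strand.
#' @export
cds_sequence <- function(gene_model, genome) {
  gene_model <- as_tibble(gene_model)
  stopifnot(length(unique(gene_model$transcript)) == 1)
  contig <- as.character(genome[[gene_model$chrom[1]]])
  segs <- mapply(function(s, e) substr(contig, s, e),
                 gene_model$seg_start, gene_model$seg_end)
  cds <- paste(segs, collapse = "")
  if (gene_model$strand[1] == "-") cds <- revcomp(cds)
  cds
}

genomic_to_cds <- function(pos, gene_model) {
  # returns NA when pos is outside every CDS segment
  widths <- gene_model$seg_end - gene_model$seg_start + 1L
  offsets <- cumsum(c(0L, widths))[seq_along(widths)]
  for (i in seq_len(nrow(gene_model))) {
    if (pos >= gene_model$seg_start[i] && pos <= gene_model$seg_end[i]) {
      within <- if (gene_model$strand[1] == "+") {
        pos - gene_model$seg_start[i] + 1L
      } else {
        gene_model$seg_end[i] - pos + 1L
      }
      return(offsets[i] + within)
    }
  }
  NA_integer_
}

#' Coding consequence of a variant on one transcript
#'
#' Maps the variant onto the transcript's CDS, translates reference and
#' alternate codons with the standard genetic code (reverse-strand models
#' complement the alleles first) and classifies the change as synonymous,
#' missense, stop_gain, frameshift, inframe_indel or noncoding. Indels whose
#' length change is not a multiple of 3 within the CDS are frameshifts.
#' Variants that only partially overlap a CDS segment are flagged as
#' splice-region and left noncoding.
#'
#' Protein strings use a simplified HGVS dialect: three-letter codes,
#' `"*"` for a gained stop (`p.Arg201*`), `"fs"` without extension length
#' (`p.Glu343fs`), `"="` for synonymous.
#'
#' @param variant One-row data frame (or list) with `chrom`, `pos`, `ref`,
#'   `alt` (anchored indel representation).
#' @param gene_model Gene-model rows for one transcript (see
#'   [cds_sequence()]).
#' @param genome Named contig sequences.
#' @return A one-row tibble: `gene`, `transcript`, `cds_pos`, `codon_index`,
#'   `ref_aa`, `alt_aa`, `kind`, `splice_flag`, `hgvs_p`.
#' @export
annotate_consequence <- function(variant, gene_model, genome) {
  gene_model <- as_tibble(gene_model)
  strand <- gene_model$strand[1]
  res <- tibble(
    gene = gene_model$gene[1], transcript = gene_model$transcript[1],
    cds_pos = NA_integer_, codon_index = NA_integer_,
    ref_aa = NA_character_, alt_aa = NA_character_,
    kind = "noncoding", splice_flag = FALSE, hgvs_p = NA_character_
  )
  ref <- toupper(variant$ref)
  alt <- toupper(variant$alt)
  span <- seq(variant$pos, variant$pos + nchar(ref) - 1L)
  in_cds <- vapply(span, function(p) {
    any(p >= gene_model$seg_start & p <= gene_model$seg_end)
  }, logical(1))
  if (!any(in_cds)) return(res)
  if (!all(in_cds)) {
    res$splice_flag <- TRUE
    return(res)
  }
  cds <- cds_sequence(gene_model, genome)
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    cds_pos <- genomic_to_cds(variant$pos, gene_model)
    ci <- codon_of(cds_pos)
    pic <- (cds_pos - 1L) %% 3L + 1L
    codon <- substr(cds, 3L * ci - 2L, 3L * ci)
    if (nchar(codon) < 3) return(res) # trailing partial codon
    ref_t <- if (strand == "-") revcomp(ref) else ref
    alt_t <- if (strand == "-") revcomp(alt) else alt
    if (substr(codon, pic, pic) != ref_t) {
      stop("reference allele mismatch at ", variant$chrom, ":", variant$pos)
    }
    alt_codon <- codon
    substr(alt_codon, pic, pic) <- alt_t
    ref_aa <- translate_codon(codon)
    alt_aa <- translate_codon(alt_codon)
    kind <- if (identical(ref_aa, alt_aa)) "synonymous"
            else if (identical(alt_aa, "*")) "stop_gain"
            else "missense"
    hgvs <- if (kind == "synonymous") {
      paste0("p.", AA3[[ref_aa]], ci, "=")
    } else {
      paste0("p.", AA3[[ref_aa]], ci, AA3[[alt_aa]])
    }
    res$cds_pos <- cds_pos; res$codon_index <- ci
    res$ref_aa <- ref_aa; res$alt_aa <- alt_aa
    res$kind <- kind; res$hgvs_p <- hgvs
    return(res)
  }
  # anchored indel: first changed base is after the shared anchor prefix
  len_change <- nchar(alt) - nchar(ref)
  first_changed <- variant$pos + 1L # anchor convention: base after anchor
  cds_pos <- genomic_to_cds(min(first_changed, variant$pos + nchar(ref) - 1L),
                            gene_model)
  if (is.na(cds_pos)) cds_pos <- genomic_to_cds(variant$pos, gene_model)
  ci <- codon_of(cds_pos)
  codon <- substr(cds, 3L * ci - 2L, 3L * ci)
  ref_aa <- if (nchar(codon) == 3) translate_codon(codon) else NA_character_
  kind <- if (len_change %% 3L != 0L) "frameshift" else "inframe_indel"
  hgvs <- if (!is.na(ref_aa)) {
    paste0("p.", AA3[[ref_aa]], ci, if (kind == "frameshift") "fs" else "del")
  } else NA_character_
  res$cds_pos <- cds_pos; res$codon_index <- ci
  res$ref_aa <- ref_aa
  res$kind <- kind; res$hgvs_p <- hgvs
  res
}

#' Consequences for a table of variants
#'
#' Runs [annotate_consequence()] against every transcript whose gene model
#' contains the variant position; variants hitting no transcript are reported
#' once as `noncoding`.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param gene_models Gene-model table (possibly several transcripts per
#'   gene).
#' @param genome Named contig sequences.
#' @return Tibble: one row per variant x overlapping transcript.
#' @export
annotate_consequences <- function(variants, gene_models, genome) {
  variants <- as_tibble(variants)
  gene_models <- as_tibble(gene_models)
  out <- vector("list", nrow(variants))
  model_split <- split(gene_models, gene_models$transcript)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    hit <- FALSE
    rows <- list()
    for (gm in model_split) {
      if (gm$chrom[1] != v$chrom) next
      lo <- min(gm$seg_start); hi <- max(gm$seg_end)
      if (v$pos > hi || (v$pos + nchar(v$ref) - 1L) < lo) next
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        v[, c("chrom", "pos", "ref", "alt")],
        annotate_consequence(v, gm, genome)
      )
      hit <- TRUE
    }
    if (!hit) {
      rows[[1L]] <- dplyr::bind_cols(
        v[, c("chrom", "pos", "ref", "alt")],
        tibble(gene = NA_character_, transcript = NA_character_,
               cds_pos = NA_integer_, codon_index = NA_integer_,
               ref_aa = NA_character_, alt_aa = NA_character_,
               kind = "noncoding", splice_flag = FALSE,
               hgvs_p = NA_character_)
      )
    }
    out[[i]] <- bind_rows(rows)
  }
  bind_rows(out)
}

#' Transition or transversion
#'
#' @param ref,alt Single-base reference and alternate alleles (vectorised).
#' @return `"transition"` for A<->G and C<->T, `"transversion"` otherwise.
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(nchar(ref) != 1 | nchar(alt) != 1)) {
    stop("substitution_class() expects single-base alleles")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "transition", "transversion")
}

#' Insertion or deletion
#'
#' @param ref,alt Anchored allele strings of different lengths (vectorised).
#' @return `"insertion"` when the alternate is longer, `"deletion"` when
#'   shorter.
#' @export
indel_class <- function(ref, alt) {
  if (any(nchar(ref) == nchar(alt))) {
    stop("indel_class() expects length-changing alleles")
  }
  ifelse(nchar(alt) > nchar(ref), "insertion", "deletion")
}

#' Mutation-spectrum summary
#'
#' Counts transitions, transversions, insertions and deletions over a set of
#' variants. Transitions + transversions equals the number of SNVs and
#' insertions + deletions the number of indels.
#'
#' @param variants Tibble with `ref` and `alt` columns (anchored alleles).
#' @return Named integer vector `c(transitions, transversions, insertions,
#'   deletions)`.
#' @export
spectrum_summary <- function(variants) {
  variants <- as_tibble(variants)
  out <- c(transitions = 0L, transversions = 0L,
           insertions = 0L, deletions = 0L)
  if (nrow(variants) == 0) return(out)
  is_snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1
  if (any(is_snv)) {
    cls <- substitution_class(variants$ref[is_snv], variants$alt[is_snv])
    out["transitions"] <- sum(cls == "transition")
    out["transversions"] <- sum(cls == "transversion")
  }
  if (any(!is_snv)) {
    cls <- indel_class(variants$ref[!is_snv], variants$alt[!is_snv])
    out["insertions"] <- sum(cls == "insertion")
    out["deletions"] <- sum(cls == "deletion")
  }
  out
}
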