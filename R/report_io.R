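#' Somatic mutation rate per megabase
#'
#' @param n_somatic Number of somatic mutations.
#' @param callable_bp Size of the callable region in bp (> 0).
#' @return Rate per Mb, reported to 3 decimals.
#' @examples
#' mutation_rate(7, 48280000) # 0.145
#' mutation_rate(7, 62100000) # 0.113
#' @export
mutation_rate <- function(n_somatic, callable_bp) {
  if (callable_bp <= 0) stop("callable_bp must be > 0")
  round(n_somatic / (callable_bp / 1e6), 3)
}

#' Write single-sample calls as VCF v4.2
#'
#' One sample per file; FORMAT carries GT, AD (ref,alt depths of surviving
#' reads), DP (surviving depth) and AF (allele fraction in percent).
#' Coordinates are 1-based with anchored indel alleles, so records parse
#' with standard VCF readers.
#'
#' @param calls Call tibble ([call_pileup()] output).
#' @param path Output file.
#' @param sample_name Sample column header.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(calls, path, sample_name = "SAMPLE") {
  calls <- as_tibble(calls)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=exomecase",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Read depths for ref and alt alleles">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Filtered read depth">',
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Alternate allele fraction, percent">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- if (nrow(calls) > 0) {
    paste(
      calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS", ".",
      "GT:AD:DP:AF",
      paste0("0/1:", calls$depth_pass - calls$alt_count, ",",
             calls$alt_count, ":", calls$depth_pass, ":",
             formatC(calls$af, format = "f", digits = 1)),
      sep = "\t"
    )
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read segmental-duplication intervals from BED
#'
#' BED input is 0-based half-open; the returned intervals are 1-based
#' inclusive (the convention used internally and in all TSV output).
#'
#' @param path Path to a BED file.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_segdup_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr))
}

#' Write segmental-duplication intervals as BED
#'
#' @param segdups Tibble with 1-based inclusive `chrom`, `start`, `end`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segdup_bed <- function(segdups, path) {
  segdups <- as_tibble(segdups)
  lines <- paste(segdups$chrom, segdups$start - 1L, segdups$end, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a synthetic case bundle to a directory
#'
#' Writes the mini-genome (FASTA), gene models, the three pileup tables,
#' the annotation track, segmental duplications (BED, 0-based half-open),
#' the control panel matrix, the truth table (all TSV) and the generating
#' configuration (DCF key-value file). Output is deterministic: the same
#' bundle writes byte-identical files.
#'
#' @param bundle A `case_bundle` from [generate_case()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "case_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(bundle$genome, p("genome.fa"))
  readr::write_tsv(bundle$gene_models, p("gene_models.tsv"))
  readr::write_tsv(bundle$pileups$tumour_dna, p("pileup_tumour_dna.tsv"))
  readr::write_tsv(bundle$pileups$blood_dna, p("pileup_blood_dna.tsv"))
  readr::write_tsv(bundle$pileups$tumour_rna, p("pileup_tumour_rna.tsv"))
  readr::write_tsv(bundle$annotations, p("annotations.tsv"))
  write_segdup_bed(bundle$segdups, p("segdups.bed"))
  readr::write_tsv(bundle$panel, p("control_panel.tsv"))
  readr::write_tsv(bundle$truth, p("truth.tsv"))
  cfg <- bundle$config
  cfg$somatic_afs <- paste(cfg$somatic_afs, collapse = ",")
  cfg$expression_split <- paste(cfg$expression_split, collapse = ",")
  write.dcf(as.data.frame(unclass(cfg)), p("config.dcf"))
  invisible(dir)
}

#' Case-level summary
#'
#' Aggregates pipeline stage outputs into the headline numbers of a case
#' report: somatic count and rate per Mb, substitution/indel spectrum,
#' germline survivor and gene counts, RNA expression split and LOH calls.
#'
#' @param somatic_final,germline_final Survivor tibbles from
#'   [run_cascade()].
#' @param expression_germline Expression profile of germline survivors.
#' @param loh_calls LOH scan results ([scan_loh()]).
#' @param callable_bp Callable-region size in bp.
#' @return A `case_summary` list.
#' @export
case_summary <- function(somatic_final, germline_final,
                         expression_germline, loh_calls, callable_bp) {
  n_som <- nrow(somatic_final)
  structure(list(
    n_somatic = n_som,
    mutation_rate_per_mb = mutation_rate(n_som, callable_bp),
    spectrum = spectrum_summary(somatic_final),
    n_germline = nrow(germline_final),
    n_germline_genes = dplyr::n_distinct(germline_final$gene),
    expression_split = split_summary(expression_germline),
    loh_calls = sum(loh_calls$is_loh, na.rm = TRUE)
  ), class = "case_summary")
}

#' @export
print.case_summary <- function(x, ...) {
  cat("Single-case variant analysis summary\n")
  cat("  somatic mutations:        ", x$n_somatic, "\n")
  cat("  somatic rate per Mb:      ", x$mutation_rate_per_mb, "\n")
  cat("  transitions/transversions:", x$spectrum[["transitions"]], "/",
      x$spectrum[["transversions"]], "\n")
  cat("  deletions/insertions:     ", x$spectrum[["deletions"]], "/",
      x$spectrum[["insertions"]], "\n")
  cat("  germline survivors:       ", x$n_germline, "in",
      x$n_germline_genes, "genes\n")
  cat("  RNA split (var/ref/none): ",
      paste(x$expression_split, collapse = "/"), "\n")
  cat("  LOH calls:                ", x$loh_calls, "\n")
  invisible(x)
}

#' Run the whole pipeline on a synthetic case
#'
#' Executes the stages in order: generate (or accept) a case bundle, call
#' variants per sample (tumour preset for tumour DNA and — per the study
#' design — for tumour RNA; blood preset for blood), classify
#' somatic/germline against blood, annotate coding consequences, run the
#' damaging-selection and exclusion cascade, integrate RNA expression for
#' the survivors, scan germline survivors for LOH with purity estimation,
#' and assemble the case summary. Deterministic given the config seed.
#'
#' @param config A [case_config()]; ignored when `bundle` is supplied.
#' @param bundle Optionally a pre-generated `case_bundle`.
#' @param out_dir If non-`NULL`, stage outputs are serialized there
#'   (VCF + TSV calls, classification report, filter traces, attrition
#'   table, expression and LOH reports, summary).
#' @return List with `bundle`, `tumour_calls`, `blood_calls`, `rna_calls`,
#'   `classified`, `consequences`, `cascade`, `expression_somatic`,
#'   `expression_germline`, `loh`, `summary`.
#' @export
run_pipeline <- function(config = case_config(), bundle = NULL,
                         out_dir = NULL) {
  if (is.null(bundle)) bundle <- generate_case(config)
  cfg <- bundle$config
  tumour_calls <- call_pileup(bundle$pileups$tumour_dna, tumour_preset())
  blood_calls <- call_pileup(bundle$pileups$blood_dna, blood_preset())
  rna_calls <- call_pileup(bundle$pileups$tumour_rna, tumour_preset())
  blood_depths <- pileup_depth(bundle$pileups$blood_dna)
  classified <- classify_variants(tumour_calls, blood_calls, blood_depths)
  consequences <- annotate_consequences(
    classified %>% distinct(chrom, pos, ref, alt),
    bundle$gene_models, bundle$genome
  )
  annotations <- bundle$annotations
  annotations$in_segdup <- mark_segdup(annotations, bundle$segdups)
  cascade <- run_cascade(classified, annotations, bundle$panel, consequences)
  expr_som <- expression_profile(cascade$somatic_final,
                                 bundle$pileups$tumour_rna)
  expr_germ <- expression_profile(cascade$germline_final,
                                  bundle$pileups$tumour_rna)
  loh <- scan_loh(cascade$germline_final, model = cfg$loh_model)
  summary <- case_summary(cascade$somatic_final, cascade$germline_final,
                          expr_germ, loh, cfg$callable_bp)
  res <- list(
    bundle = bundle, tumour_calls = tumour_calls,
    blood_calls = blood_calls, rna_calls = rna_calls,
    classified = classified, consequences = consequences,
    cascade = cascade, expression_somatic = expr_som,
    expression_germline = expr_germ, loh = loh, summary = summary
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_variants_vcf(res$tumour_calls, p("tumour_dna.vcf"), "TUMOUR_DNA")
  write_variants_vcf(res$blood_calls, p("blood_dna.vcf"), "BLOOD_DNA")
  write_variants_vcf(res$rna_calls, p("tumour_rna.vcf"), "TUMOUR_RNA")
  readr::write_tsv(res$classified, p("classified.tsv"))
  readr::write_tsv(res$cascade$traces, p("filter_traces.tsv"))
  readr::write_tsv(filter_attrition(res$cascade$traces), p("attrition.tsv"))
  readr::write_tsv(format_case_report(res$cascade$somatic_final,
                                      res$expression_somatic),
                   p("somatic_report.tsv"))
  readr::write_tsv(format_case_report(res$cascade$germline_final,
                                      res$expression_germline),
                   p("germline_report.tsv"))
  readr::write_tsv(res$loh, p("loh_report.tsv"))
  s <- res$summary
  readr::write_tsv(tibble(
    n_somatic = s$n_somatic,
    mutation_rate_per_mb = s$mutation_rate_per_mb,
    transitions = s$spectrum[["transitions"]],
    transversions = s$spectrum[["transversions"]],
    insertions = s$spectrum[["insertions"]],
    deletions = s$spectrum[["deletions"]],
    n_germline = s$n_germline,
    n_germline_genes = s$n_germline_genes,
    rna_variant_expressed = s$expression_split[["variant_expressed"]],
    rna_ref_only = s$expression_split[["ref_only"]],
    rna_not_expressed = s$expression_split[["not_expressed"]],
    loh_calls = s$loh_calls
  ), p("case_summary.tsv"))
  invisible(out_dir)
}

#' Case report table in the style of a somatic/germline mutation table
#'
#' Merges survivor records with RNA expression status into a per-variant
#' report: coordinates, gene, protein change, allele fraction (one
#' decimal), whether the mutation is expressed and the reference-allele
#' base coverage.
#'
#' @param survivors Survivor tibble from [run_cascade()].
#' @param expression Matching rows from [expression_profile()].
#' @return Report tibble.
#' @export
format_case_report <- function(survivors, expression) {
  survivors <- as_tibble(survivors)
  if (nrow(survivors) == 0) {
    return(tibble(coordinates = character(), gene = character(),
                  protein = character(), allele_frequency = character(),
                  mutation_expressed = character(),
                  ref_allele_expressed = character()))
  }
  survivors %>%
    left_join(as_tibble(expression), by = c("chrom", "pos", "ref", "alt")) %>%
    mutate(
      coordinates = paste0(chrom, ": ", pos, ifelse(
        nchar(ref) == nchar(alt), paste0(ref, ">", alt),
        ifelse(nchar(ref) > nchar(alt),
               paste0("del", substr(ref, 2, nchar(ref))),
               paste0("ins", substr(alt, 2, nchar(alt))))
      )),
      protein = hgvs_p,
      allele_frequency = formatC(af, format = "f", digits = 1),
      mutation_expressed = ifelse(state == "variant_expressed", "Yes", "no"),
      ref_allele_expressed = ifelse(rna_ref_count > 0,
                                    paste0("Yes (", rna_ref_count, ")"),
                                    "No (0)")
    ) %>%
    select(coordinates, gene, protein, allele_frequency,
           mutation_expressed, ref_allele_expressed)
}

#' Load the bundled somatic point-mutation table
#'
#' A packaged TSV of the somatic point mutations reported for a single
#' rhabdoid-tumour case (coordinates with allele notation, gene, protein
#' change, allele frequency in percent, RNA expression columns), with the
#' coordinate column parsed into `ref`/`alt` anchored alleles so spectrum
#' summaries can be computed directly.
#'
#' @return Tibble with one row per mutation.
#' @export
somatic_mutation_table <- function() {
  path <- system.file("extdata", "somatic_mutations.tsv",
                      package = "exomecase")
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  parse_coordinate_notation(tab)
}

#' Load the bundled candidate germline-variant table
#'
#' Same format as [somatic_mutation_table()] for the case's candidate
#' cancer-gene germline variants (including the two-hit nonsense site with
#' its blood-to-tumour allele-fraction shift).
#'
#' @return Tibble with one row per variant.
#' @export
candidate_germline_table <- function() {
  path <- system.file("extdata", "candidate_germline.tsv",
                      package = "exomecase")
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  parse_coordinate_notation(tab)
}

# parses "chr22: 42390734delG" / "chrX: 103294635C>T" / "chr3: 12insA"
# into chrom, pos, ref, alt (anchored; the true anchor base is unknown from
# the notation, so a placeholder anchor N is used for indels)
parse_coordinate_notation <- function(tab) {
  cc <- tab$coordinates
  chrom <- sub("^\\s*([Cc]hr[^:]+):.*$", "\\1", cc)
  rest <- sub("^\\s*[Cc]hr[^:]+:\\s*", "", cc)
  pos <- as.integer(sub("^([0-9]+).*$", "\\1", rest))
  op <- sub("^[0-9]+", "", rest)
  ref <- character(length(op)); alt <- character(length(op))
  for (i in seq_along(op)) {
    if (grepl("^[ACGT]>[ACGT]$", op[i])) {
      ref[i] <- substr(op[i], 1, 1)
      alt[i] <- substr(op[i], 3, 3)
    } else if (grepl("^del", op[i])) {
      deleted <- sub("^del", "", op[i])
      ref[i] <- paste0("N", deleted)
      alt[i] <- "N"
    } else if (grepl("^ins", op[i])) {
      inserted <- sub("^ins", "", op[i])
      ref[i] <- "N"
      alt[i] <- paste0("N", inserted)
    } else {
      stop("unrecognised coordinate notation: ", cc[i])
    }
  }
  dplyr::bind_cols(tibble(chrom = chrom, pos = pos, ref = ref, alt = alt),
                   tab)
}
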