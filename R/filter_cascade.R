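#' Genes excluded as systematic false-positive hosts
#'
#' Exact match to `TTN`, any mucin-family symbol (`MUC` prefix) and any
#' olfactory-receptor-style symbol (`OR` followed by a digit, so `OR4F5`
#' matches but `ORC1` does not). These gene families are prone to artefact
#' calls because of their size and/or paralogous sequence similarity.
#'
#' @param gene Character vector of gene symbols.
#' @return Logical vector.
#' @export
is_blacklisted_gene <- function(gene) {
  !is.na(gene) &
    (gene == "TTN" | startsWith(gene, "MUC") | grepl("^OR[0-9]", gene))
}

#' Damaging-variant selection rule
#'
#' A variant is retained as potentially functional if ANY of the following
#' holds: it is a reported clinical SNP; it is present in the somatic cancer
#' mutation catalogue; its damage prediction is `probably_damaging`
#' (PolyPhen-style) or `damaging` (SIFT-style); it overlaps a splice site;
#' its coding consequence is a gained stop codon; or it is an indel that
#' alters the protein (frameshift or in-frame). Missing (`NA`) predictions
#' count as non-damaging; `possibly_damaging` does not qualify.
#'
#' @param consequence_kind One of `synonymous`, `missense`, `stop_gain`,
#'   `frameshift`, `inframe_indel`, `noncoding` (vectorised).
#' @param annotation Data frame with logical `clinical_snp`, `in_cosmic`,
#'   `splice_site_overlap` and character `polyphen`, `sift` columns, aligned
#'   with `consequence_kind`.
#' @param splice_flag Optional logical vector from consequence annotation
#'   (variants spanning a CDS boundary); OR-ed with the annotation's
#'   splice-site flag.
#' @return Logical vector: `TRUE` if selected.
#' @export
select_damaging <- function(consequence_kind, annotation,
                            splice_flag = FALSE) {
  annotation <- as_tibble(annotation)
  isTRUEv <- function(x) !is.na(x) & x
  isTRUEv(annotation$clinical_snp) |
    isTRUEv(annotation$in_cosmic) |
    (!is.na(annotation$polyphen) & annotation$polyphen == "probably_damaging") |
    (!is.na(annotation$sift) & annotation$sift == "damaging") |
    isTRUEv(annotation$splice_site_overlap) |
    isTRUEv(splice_flag) |
    consequence_kind == "stop_gain" |
    consequence_kind %in% c("frameshift", "inframe_indel")
}

variant_id <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Exclusion filters with per-filter provenance
#'
#' Evaluates every exclusion filter for every variant and records each
#' outcome, so a variant's rejection is auditable filter by filter:
#' * `control_panel` — fails if the variant is present in at least one of
#'   the control exomes in the panel;
#' * `dbsnp_common` — fails if the catalogued population frequency is
#'   strictly greater than `max_pop_freq` (default 0.01; a frequency of
#'   exactly 1% passes);
#' * `segdup` — fails if the variant lies within a segmental duplication;
#' * `blacklist` — fails if the host gene matches [is_blacklisted_gene()].
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param annotations Annotation track with `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `dbsnp_pop_freq`, `in_segdup`.
#' @param panel Control panel: tibble with `chrom`, `pos`, `ref`, `alt` and
#'   one 0/1 column per control sample.
#' @param max_pop_freq Population-frequency cut-off (strict inequality).
#' @return Long tibble of traces: `variant_id`, `filter_name`, `outcome`
#'   (`"pass"`/`"fail"`), plus a `final` logical per variant (all pass).
#' @export
exclusion_filters <- function(variants, annotations, panel,
                              max_pop_freq = 0.01) {
  variants <- as_tibble(variants)
  annotations <- as_tibble(annotations)
  ids <- variant_id(variants)
  ann <- variants %>%
    left_join(annotations, by = c("chrom", "pos", "ref", "alt"))
  panel_hits <- panel_carrier_counts(panel)
  in_panel <- ids %in% panel_hits$variant_id[panel_hits$n_carriers > 0]
  freq <- ann$dbsnp_pop_freq
  common <- !is.na(freq) & freq > max_pop_freq
  segdup <- !is.na(ann$in_segdup) & ann$in_segdup
  blk <- is_blacklisted_gene(ann$gene)
  trace <- bind_rows(
    tibble(variant_id = ids, filter_name = "control_panel", fail = in_panel),
    tibble(variant_id = ids, filter_name = "dbsnp_common", fail = common),
    tibble(variant_id = ids, filter_name = "segdup", fail = segdup),
    tibble(variant_id = ids, filter_name = "blacklist", fail = blk)
  ) %>%
    mutate(outcome = ifelse(fail, "fail", "pass")) %>%
    select(variant_id, filter_name, outcome)
  finals <- trace %>%
    group_by(variant_id) %>%
    summarise(final = all(outcome == "pass"), .groups = "drop")
  left_join(trace, finals, by = "variant_id")
}

#' Carrier counts from a control-exome panel
#'
#' @param panel Tibble with `chrom`, `pos`, `ref`, `alt` and one 0/1 column
#'   per control sample.
#' @return Tibble with `variant_id` and `n_carriers`.
#' @export
panel_carrier_counts <- function(panel) {
  panel <- as_tibble(panel)
  sample_cols <- setdiff(names(panel), c("chrom", "pos", "ref", "alt"))
  n <- if (length(sample_cols) == 0 || nrow(panel) == 0) {
    integer(nrow(panel))
  } else {
    as.integer(rowSums(panel[, sample_cols, drop = FALSE]))
  }
  tibble(variant_id = variant_id(panel), n_carriers = n)
}

#' Mark variants overlapping segmental duplications
#'
#' Interval overlap against 1-based inclusive segmental-duplication ranges
#' (use [read_segdup_bed()] to convert from 0-based half-open BED).
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`.
#' @param segdups Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @return Logical vector `in_segdup` aligned with `variants`.
#' @export
mark_segdup <- function(variants, segdups) {
  variants <- as_tibble(variants)
  segdups <- as_tibble(segdups)
  if (nrow(variants) == 0) return(logical(0))
  if (nrow(segdups) == 0) return(rep(FALSE, nrow(variants)))
  v <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(variants$pos, variants$pos + nchar(variants$ref) - 1L)
  )
  s <- GenomicRanges::GRanges(
    segdups$chrom, IRanges::IRanges(segdups$start, segdups$end)
  )
  IRanges::overlapsAny(v, s)
}

#' Run the full selection and exclusion cascade
#'
#' For every classified variant the cascade records the damaging-selection
#' outcome and every exclusion-filter outcome. A somatic survivor is a
#' somatic-classified variant that is selected as damaging and passes every
#' exclusion filter; germline survivors are defined analogously. The
#' survivor set is independent of filter evaluation order because every
#' filter is evaluated for every variant.
#'
#' Variants lacking an annotation record are excluded with an
#' `unannotated` trace entry and a warning.
#'
#' @param classified Output of [classify_variants()].
#' @param annotations Annotation track (see [exclusion_filters()]); its
#'   `in_segdup` column may be pre-computed with [mark_segdup()].
#' @param panel Control panel table.
#' @param consequences Output of [annotate_consequences()] (one row per
#'   variant x transcript); a variant is damaging if any transcript's
#'   consequence qualifies.
#' @param max_pop_freq Population-frequency cut-off.
#' @return List with `somatic_final`, `germline_final` (tibbles of surviving
#'   variants with consequence columns), and `traces` (long per-filter
#'   tibble including the `damaging_selection` pseudo-filter).
#' @export
run_cascade <- function(classified, annotations, panel, consequences,
                        max_pop_freq = 0.01) {
  classified <- as_tibble(classified)
  if (nrow(classified) == 0) {
    empty <- classified
    return(list(somatic_final = empty, germline_final = empty,
                traces = tibble(variant_id = character(),
                                filter_name = character(),
                                outcome = character(), final = logical())))
  }
  ids <- variant_id(classified)
  annotations <- as_tibble(annotations)
  ann <- classified %>%
    left_join(annotations, by = c("chrom", "pos", "ref", "alt"))
  unann <- is.na(ann$gene) & !(variant_id(classified) %in% variant_id(annotations))
  if (any(unann)) {
    warning(sum(unann), " variant(s) had no annotation record; excluded")
  }
  # best (most severe) consequence per variant across transcripts
  csq <- as_tibble(consequences) %>%
    mutate(variant_id = paste(chrom, pos, ref, alt, sep = ":")) %>%
    group_by(variant_id) %>%
    summarise(
      kind = kind[order(match(kind, c("stop_gain", "frameshift",
                                      "inframe_indel", "missense",
                                      "synonymous", "noncoding")))][1],
      splice_flag = any(splice_flag),
      hgvs_p = hgvs_p[!is.na(hgvs_p)][1],
      csq_gene = gene[!is.na(gene)][1],
      .groups = "drop"
    )
  merged <- classified %>%
    mutate(variant_id = ids) %>%
    left_join(csq, by = "variant_id") %>%
    mutate(kind = ifelse(is.na(kind), "noncoding", kind),
           splice_flag = ifelse(is.na(splice_flag), FALSE, splice_flag))
  damaging <- select_damaging(merged$kind, ann, merged$splice_flag) & !unann
  sel_trace <- tibble(
    variant_id = ids, filter_name = "damaging_selection",
    outcome = ifelse(damaging, "pass", "fail")
  )
  excl <- exclusion_filters(classified, annotations, panel, max_pop_freq)
  unann_trace <- tibble(
    variant_id = ids[unann], filter_name = "unannotated", outcome = "fail"
  )
  traces <- bind_rows(sel_trace, select(excl, -final), unann_trace)
  finals <- traces %>%
    group_by(variant_id) %>%
    summarise(final = all(outcome == "pass"), .groups = "drop")
  traces <- left_join(traces, finals, by = "variant_id")
  surviving <- merged$variant_id %in% finals$variant_id[finals$final]
  out <- merged %>%
    mutate(gene = ann$gene, surviving = surviving)
  list(
    somatic_final = filter(out, status == "somatic", surviving),
    germline_final = filter(out, status == "germline", surviving),
    traces = traces
  )
}

#' Per-filter attrition table
#'
#' @param traces Trace tibble from [run_cascade()].
#' @return Tibble with one row per filter: variants failing it, and how many
#'   of those failed only that filter.
#' @export
filter_attrition <- function(traces) {
  traces <- as_tibble(traces)
  fails_per_variant <- traces %>%
    filter(outcome == "fail") %>%
    count(variant_id, name = "n_failed")
  traces %>%
    filter(outcome == "fail") %>%
    left_join(fails_per_variant, by = "variant_id") %>%
    group_by(filter_name) %>%
    summarise(n_fail = n(), n_exclusive = sum(n_failed == 1),
              .groups = "drop")
}
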