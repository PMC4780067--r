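#' Expression status of a DNA variant in tumour RNA
#'
#' An allele is "detected" in RNA when at least `min_reads` observations of
#' it reach base quality `min_quality`. The state is
#' `variant_expressed` when the variant allele is detected (regardless of
#' the reference allele), `ref_only` when only the reference allele is
#' detected, and `not_expressed` when neither is. Raw counts are reported
#' even when below threshold so reports can render "No (0)" versus
#' "Yes (35)" style cells.
#'
#' @param variant One-row data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param rna_pileup Long-format RNA pileup (may lack the site entirely).
#' @param min_reads Minimum detected-read count (default 1).
#' @param min_quality Minimum base quality for an RNA read to count
#'   (default 20).
#' @return One-row tibble: `chrom`, `pos`, `ref`, `alt`, `state`,
#'   `rna_alt_count`, `rna_ref_count`, `rna_af` (percent, `NA` when no
#'   allele-informative coverage).
#' @export
expression_status <- function(variant, rna_pileup, min_reads = 1L,
                              min_quality = 20) {
  rna_pileup <- as_tibble(rna_pileup)
  col <- rna_pileup %>%
    filter(chrom == variant$chrom, pos == variant$pos,
           ref == variant$ref, baseq >= min_quality)
  alt_n <- sum(col$allele == variant$alt)
  ref_n <- sum(col$allele == variant$ref)
  state <- if (alt_n >= min_reads) "variant_expressed"
           else if (ref_n >= min_reads) "ref_only"
           else "not_expressed"
  af <- if (alt_n + ref_n > 0) 100 * alt_n / (alt_n + ref_n) else NA_real_
  tibble(
    chrom = variant$chrom, pos = variant$pos, ref = variant$ref,
    alt = variant$alt, state = state,
    rna_alt_count = as.integer(alt_n), rna_ref_count = as.integer(ref_n),
    rna_af = af
  )
}

#' Expression status for a table of variants
#'
#' Vectorised [expression_status()] over every row of `variants`.
#'
#' @inheritParams expression_status
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @return Tibble with one row per variant.
#' @export
expression_profile <- function(variants, rna_pileup, min_reads = 1L,
                               min_quality = 20) {
  variants <- as_tibble(variants)
  rna_pileup <- as_tibble(rna_pileup)
  if (nrow(variants) == 0) {
    return(expression_status(
      list(chrom = "x", pos = 0L, ref = "N", alt = "N"), rna_pileup
    )[0, ])
  }
  good <- rna_pileup %>% filter(baseq >= min_quality)
  counts <- good %>% count(chrom, pos, ref, allele, name = "n_obs")
  out <- variants %>%
    select(chrom, pos, ref, alt) %>%
    left_join(counts %>% rename(alt = allele, rna_alt_count = n_obs),
              by = c("chrom", "pos", "ref", "alt")) %>%
    left_join(
      counts %>%
        filter(allele == ref) %>%
        select(chrom, pos, ref, rna_ref_count = n_obs),
      by = c("chrom", "pos", "ref")
    ) %>%
    mutate(
      rna_alt_count = ifelse(is.na(rna_alt_count), 0L, rna_alt_count),
      rna_ref_count = ifelse(is.na(rna_ref_count), 0L, rna_ref_count),
      state = dplyr::case_when(
        rna_alt_count >= min_reads ~ "variant_expressed",
        rna_ref_count >= min_reads ~ "ref_only",
        TRUE ~ "not_expressed"
      ),
      rna_af = ifelse(rna_alt_count + rna_ref_count > 0,
                      100 * rna_alt_count / (rna_alt_count + rna_ref_count),
                      NA_real_)
    ) %>%
    select(chrom, pos, ref, alt, state, rna_alt_count, rna_ref_count, rna_af)
  out
}

#' Three-way expression split
#'
#' @param statuses Output of [expression_profile()].
#' @return Named integer vector `c(variant_expressed, ref_only,
#'   not_expressed)` summing to the input size.
#' @export
split_summary <- function(statuses) {
  statuses <- as_tibble(statuses)
  states <- c("variant_expressed", "ref_only", "not_expressed")
  counts <- table(factor(statuses$state, levels = states))
  setNames(as.integer(counts), states)
}
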