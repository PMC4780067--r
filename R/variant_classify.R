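#' Classify tumour variants as somatic, germline or unclassifiable
#'
#' Cross-sample rules applied to each tumour call:
#' * **somatic** — no qualifying call at the site in the blood sample (zero
#'   alternate reads under the permissive blood preset) *and* raw blood
#'   coverage of at least `min_blood_depth` (default 8), so that absence of
#'   the allele in blood is informative.
#' * **germline** — the same allele is called in blood with blood allele
#'   fraction of at least `min_germline_af` percent (default 20) and blood
#'   alternate read count of at least `min_germline_count` (default 4). The
#'   constitutive-tissue thresholds are applied to the blood sample.
#' * **unclassifiable** — everything else: sites with insufficient blood
#'   coverage and no blood call, or low-level blood evidence (1-3 alternate
#'   reads, or fraction under the germline threshold) that is neither
#'   confidently somatic nor confidently germline.
#'
#' @param tumour_calls Calls from the tumour sample ([call_pileup()] output).
#' @param blood_calls Calls from the blood sample under the blood preset.
#' @param blood_depths Raw per-site blood depth ([pileup_depth()] output);
#'   must cover every tumour-call site.
#' @param min_blood_depth Minimum raw blood coverage for a somatic call.
#' @param min_germline_af Minimum blood allele fraction (percent) for a
#'   germline call.
#' @param min_germline_count Minimum blood alternate read count for a
#'   germline call.
#' @return Tumour calls with added columns `blood_af`, `blood_alt_count`,
#'   `blood_depth` and `status`; every tumour call receives exactly one
#'   status.
#' @export
classify_variants <- function(tumour_calls, blood_calls, blood_depths,
                              min_blood_depth = 8L,
                              min_germline_af = 20,
                              min_germline_count = 4L) {
  tumour_calls <- as_tibble(tumour_calls)
  blood_calls <- as_tibble(blood_calls)
  blood_depths <- as_tibble(blood_depths)
  if (nrow(tumour_calls) == 0) {
    return(mutate(tumour_calls, blood_af = numeric(), blood_alt_count = integer(),
                  blood_depth_pass = integer(), blood_depth = integer(),
                  status = character()))
  }
  merged <- tumour_calls %>%
    left_join(
      blood_calls %>%
        select(chrom, pos, ref, alt,
               blood_af = af, blood_alt_count = alt_count,
               blood_depth_pass = depth_pass),
      by = c("chrom", "pos", "ref", "alt")
    ) %>%
    left_join(
      blood_depths %>% select(chrom, pos, blood_depth = depth),
      by = c("chrom", "pos")
    )
  if (any(is.na(merged$blood_depth))) {
    bad <- merged[is.na(merged$blood_depth), ]
    stop("missing blood depth at tumour-call site(s): ",
         paste(bad$chrom, bad$pos, sep = ":", collapse = ", "))
  }
  # a blood call at the same site for a *different* allele does not make the
  # tumour allele germline; the join is allele-specific
  in_blood <- !is.na(merged$blood_alt_count)
  merged %>%
    mutate(
      status = dplyr::case_when(
        !in_blood & blood_depth >= min_blood_depth ~ "somatic",
        in_blood & blood_af >= min_germline_af &
          blood_alt_count >= min_germline_count ~ "germline",
        TRUE ~ "unclassifiable"
      )
    )
}
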