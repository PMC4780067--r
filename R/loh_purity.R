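#' Test a germline heterozygous site for loss of heterozygosity
#'
#' Compares blood and tumour allele counts at one site with a two-sided
#' exact test on the 2x2 table (alt/ref reads by sample). The site is called
#' LOH when the allele-fraction shift `af_tumour - af_blood` is at least
#' `min_delta` percentage points *and* the exact-test p-value is at most
#' `alpha`. For LOH calls with tumour allele fraction above 50% a tumour
#' purity is estimated under the requested copy model (see
#' [estimate_purity()]).
#'
#' @param blood_obs,tumour_obs One-row call records with `alt_count` and
#'   `depth_pass` (and optionally `chrom`, `pos`, `ref`, `alt`).
#' @param min_delta Minimum allele-fraction increase, percentage points
#'   (default 20).
#' @param alpha Significance level for the exact test (default 0.01).
#' @param model Copy model for purity estimation:
#'   `"single_copy_deletion"` (default) or `"copy_neutral"`.
#' @return One-row tibble: `af_blood`, `af_tumour`, `delta_af`, `p_value`,
#'   `is_loh`, `model`, `purity_estimate` (plus the variant key columns when
#'   present). All-`NA` call when either sample has zero depth.
#' @export
test_loh <- function(blood_obs, tumour_obs, min_delta = 20, alpha = 0.01,
                     model = c("single_copy_deletion", "copy_neutral")) {
  model <- match.arg(model)
  key <- if (all(c("chrom", "pos", "ref", "alt") %in% names(tumour_obs))) {
    tibble(chrom = tumour_obs$chrom, pos = tumour_obs$pos,
           ref = tumour_obs$ref, alt = tumour_obs$alt)
  } else tibble(.rows = 1)
  b_alt <- blood_obs$alt_count; b_dp <- blood_obs$depth_pass
  t_alt <- tumour_obs$alt_count; t_dp <- tumour_obs$depth_pass
  if (is.na(b_dp) || is.na(t_dp) || b_dp == 0 || t_dp == 0) {
    return(dplyr::bind_cols(key, tibble(
      af_blood = NA_real_, af_tumour = NA_real_, delta_af = NA_real_,
      p_value = NA_real_, is_loh = NA, model = model,
      purity_estimate = NA_real_
    )))
  }
  af_b <- 100 * b_alt / b_dp
  af_t <- 100 * t_alt / t_dp
  delta <- af_t - af_b
  tab <- matrix(c(b_alt, b_dp - b_alt, t_alt, t_dp - t_alt), nrow = 2)
  p <- fisher.test(tab)$p.value
  is_loh <- delta >= min_delta && p <= alpha
  purity <- if (isTRUE(is_loh) && af_t / 100 > 0.5) {
    estimate_purity(af_t / 100, model)
  } else NA_real_
  dplyr::bind_cols(key, tibble(
    af_blood = af_b, af_tumour = af_t, delta_af = delta, p_value = p,
    is_loh = is_loh, model = model, purity_estimate = purity
  ))
}

#' Scan germline variants for LOH
#'
#' Runs [test_loh()] on every germline-classified variant, using the blood
#' and tumour counts carried on the classification record.
#'
#' @param classified Output of [classify_variants()] (only rows with
#'   `status == "germline"` are tested); must carry `blood_alt_count` and
#'   `blood_depth`.
#' @inheritParams test_loh
#' @return Tibble of LOH calls, one row per germline variant.
#' @export
scan_loh <- function(classified, min_delta = 20, alpha = 0.01,
                     model = "single_copy_deletion") {
  classified <- as_tibble(classified) %>% filter(status == "germline")
  out <- vector("list", nrow(classified))
  for (i in seq_len(nrow(classified))) {
    row <- classified[i, ]
    out[[i]] <- test_loh(
      list(alt_count = row$blood_alt_count, depth_pass = row$blood_depth_pass),
      row, min_delta = min_delta, alpha = alpha, model = model
    )
  }
  bind_rows(out)
}

#' Tumour purity from the allele fraction at an LOH site
#'
#' For a germline heterozygous site where tumour cells have lost the
#' wild-type allele, the expected tumour allele fraction at purity `p` is
#' `1 / (2 - p)` when the lost copy is deleted (tumour cells contribute one
#' variant copy, normal cells two balanced copies) and `(1 + p) / 2` under
#' copy-neutral LOH (tumour cells contribute two variant copies). Inverting:
#' `purity = 2 - 1/af` (deletion) or `purity = 2*af - 1` (copy-neutral).
#' An allele fraction at or below 50% carries no LOH signal and returns
#' `NA`.
#'
#' @param af_tumour Tumour allele fraction on the 0-1 scale, in (0.5, 1].
#' @param model `"single_copy_deletion"` or `"copy_neutral"`.
#' @return Purity estimate in `[0, 1]` (vectorised), `NA` when
#'   `af_tumour <= 0.5`.
#' @examples
#' estimate_purity(0.875, "single_copy_deletion") # 6/7
#' estimate_purity(0.875, "copy_neutral")         # 0.75
#' @export
estimate_purity <- function(af_tumour,
                            model = c("single_copy_deletion",
                                      "copy_neutral")) {
  model <- match.arg(model)
  stopifnot(all(af_tumour > 0 & af_tumour <= 1, na.rm = TRUE))
  p <- switch(model,
    single_copy_deletion = 2 - 1 / af_tumour,
    copy_neutral = 2 * af_tumour - 1
  )
  ifelse(af_tumour <= 0.5, NA_real_, p)
}

#' Expected tumour allele fraction at an LOH site (forward model)
#'
#' Inverse companion of [estimate_purity()]: the allele fraction implied by
#' purity `p` under each copy model.
#'
#' @param purity Tumour purity in (0, 1].
#' @param model Copy model.
#' @return Expected allele fraction (0-1 scale).
#' @export
expected_af_loh <- function(purity,
                            model = c("single_copy_deletion",
                                      "copy_neutral")) {
  model <- match.arg(model)
  stopifnot(all(purity > 0 & purity <= 1))
  switch(model,
    single_copy_deletion = 1 / (2 - purity),
    copy_neutral = (1 + purity) / 2
  )
}

#' RNA allele-fraction consistency at an LOH site
#'
#' Under equal per-cell expression, if a fraction `f` of transcripts at the
#' site originates from tumour cells that express only the variant allele
#' while normal transcripts are balanced heterozygous, the expected RNA
#' allele fraction is `(1 + f) / 2`. The tumour *transcript* fraction is an
#' independent parameter from the DNA cellular purity: expression
#' contamination need not equal cellular contamination.
#'
#' @param af_rna Observed RNA allele fraction (0-1 scale).
#' @param rna_tumour_fraction Fraction of transcripts from tumour cells.
#' @return Tibble with `expected_af`, `observed_af`, `deviation`
#'   (observed - expected).
#' @examples
#' rna_consistency(0.75, 0.5) # expected 0.75, deviation 0
#' @export
rna_consistency <- function(af_rna, rna_tumour_fraction) {
  stopifnot(rna_tumour_fraction >= 0, rna_tumour_fraction <= 1)
  expected <- (1 + rna_tumour_fraction) / 2
  tibble(expected_af = expected, observed_af = af_rna,
         deviation = af_rna - expected)
}
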