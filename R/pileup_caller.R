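#' Variant-caller parameter set
#'
#' Read-level and allele-level thresholds applied when calling variants from
#' a pileup column. A read observation is counted only if its base quality is
#' at least `min_base_quality` and it carries at most `max_gapmm_in_window`
#' gaps/mismatches within the `window_bp` window centred on the site. A
#' non-reference allele is emitted only if its surviving read count is at
#' least `min_read_count` and its fraction of the surviving depth is at least
#' `min_allele_fraction`.
#'
#' @param max_gapmm_in_window Maximum gaps/mismatches tolerated per read
#'   within the window.
#' @param window_bp Window width in bp (odd, positive; default 21).
#' @param min_base_quality Minimum phred base quality for a read to count.
#' @param min_read_count Minimum alternate-allele read count.
#' @param min_allele_fraction Minimum alternate allele fraction (0-1 scale)
#'   of the surviving depth.
#' @return A `caller_params` list.
#' @seealso [tumour_preset()], [blood_preset()], [call_variants()]
#' @export
caller_params <- function(max_gapmm_in_window, window_bp = 21L,
                          min_base_quality, min_read_count,
                          min_allele_fraction) {
  stopifnot(
    window_bp > 0, window_bp %% 2 == 1,
    min_allele_fraction >= 0, min_allele_fraction <= 1,
    max_gapmm_in_window >= 0, min_read_count >= 0, min_base_quality >= 0
  )
  structure(
    list(
      max_gapmm_in_window = as.integer(max_gapmm_in_window),
      window_bp = as.integer(window_bp),
      min_base_quality = as.numeric(min_base_quality),
      min_read_count = as.integer(min_read_count),
      min_allele_fraction = as.numeric(min_allele_fraction)
    ),
    class = "caller_params"
  )
}

#' Tumour-DNA calling preset
#'
#' At most 2 gaps/mismatches within a 21 bp window, minimum base quality 30,
#' minimum read count 4 and minimum allele fraction 5%. The same preset is
#' applied to tumour RNA pileups.
#'
#' @return A `caller_params` list.
#' @export
tumour_preset <- function() {
  caller_params(2L, 21L, 30, 4L, 0.05)
}

#' Blood-DNA calling preset
#'
#' At most 3 gaps/mismatches within a 21 bp window, minimum base quality 25,
#' minimum read count 1 and minimum allele fraction 2%. Deliberately more
#' permissive than the tumour preset so that low-level constitutive evidence
#' is not missed when deciding somatic status.
#'
#' @return A `caller_params` list.
#' @export
blood_preset <- function() {
  caller_params(3L, 21L, 25, 1L, 0.02)
}

#' Call variants from one pileup column
#'
#' A pileup column holds the read observations at one site: each row carries
#' the observed allele string, its phred base quality and the number of
#' gaps/mismatches that read shows within the window around the site. Indel
#' observations are anchored: a deletion at ref `"TG"` is observed as `"T"`,
#' an insertion at ref `"T"` as `"TA"`, and the quality is that of the anchor
#' base.
#'
#' Reads failing the base-quality or gap/mismatch criteria are removed first;
#' the surviving count is the denominator `depth_pass`. Every non-reference
#' allele whose surviving count meets the read-count and allele-fraction
#' thresholds is emitted, ordered by descending count then allele string.
#'
#' @param column A data frame with columns `chrom`, `pos`, `ref`, `allele`,
#'   `baseq`, `gapmm`; all rows must share one (`chrom`, `pos`, `ref`).
#' @param params A [caller_params()] object.
#' @return A tibble of calls with columns `chrom`, `pos`, `ref`, `alt`,
#'   `alt_count`, `depth_pass`, `af` (percent). Zero rows if nothing
#'   qualifies.
#' @examples
#' col <- tibble::tibble(
#'   chrom = "ctg01", pos = 100L, ref = "C",
#'   allele = c(rep("C", 76), rep("T", 4)), baseq = 35, gapmm = 0L
#' )
#' call_variants(col, tumour_preset())
#' @export
call_variants <- function(column, params) {
  stopifnot(inherits(params, "caller_params"))
  column <- as_tibble(column)
  req <- c("chrom", "pos", "ref", "allele", "baseq", "gapmm")
  if (!all(req %in% names(column))) {
    stop("pileup column must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(column) == 0) return(empty_calls())
  if (any(column$baseq < 0)) stop("malformed pileup: negative base quality")
  if (length(unique(column$pos)) != 1 || length(unique(column$chrom)) != 1) {
    stop("call_variants() expects a single-site column; see call_pileup()")
  }
  keep <- column$baseq >= params$min_base_quality &
    column$gapmm <= params$max_gapmm_in_window
  surv <- column[keep, , drop = FALSE]
  dp <- nrow(surv)
  if (dp == 0) return(empty_calls())
  ref_allele <- surv$ref[1]
  tab <- table(surv$allele)
  alts <- setdiff(names(tab), ref_allele)
  if (length(alts) == 0) return(empty_calls())
  cnt <- as.integer(tab[alts])
  ok <- cnt >= params$min_read_count & cnt / dp >= params$min_allele_fraction
  if (!any(ok)) return(empty_calls())
  out <- tibble(
    chrom = surv$chrom[1], pos = surv$pos[1], ref = ref_allele,
    alt = alts[ok], alt_count = cnt[ok], depth_pass = dp,
    af = 100 * cnt[ok] / dp
  )
  arrange(out, desc(alt_count), alt)
}

empty_calls <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), alt_count = integer(), depth_pass = integer(),
    af = numeric()
  )
}

#' Call variants across a whole pileup table
#'
#' Applies [call_variants()] to every (`chrom`, `pos`, `ref`) column of a
#' long-format pileup table (one row per read observation).
#'
#' @param pileup Data frame with columns `chrom`, `pos`, `ref`, `allele`,
#'   `baseq`, `gapmm`.
#' @param params A [caller_params()] object.
#' @return Tibble of calls, sorted by `chrom` then `pos`.
#' @export
call_pileup <- function(pileup, params) {
  stopifnot(inherits(params, "caller_params"))
  pileup <- as_tibble(pileup)
  if (nrow(pileup) == 0) return(empty_calls())
  if (any(pileup$baseq < 0)) stop("malformed pileup: negative base quality")
  keep <- pileup$baseq >= params$min_base_quality &
    pileup$gapmm <= params$max_gapmm_in_window
  surv <- pileup[keep, , drop = FALSE]
  if (nrow(surv) == 0) return(empty_calls())
  counts <- surv %>%
    count(chrom, pos, ref, allele, name = "n_allele") %>%
    group_by(chrom, pos, ref) %>%
    mutate(depth_pass = sum(n_allele)) %>%
    ungroup() %>%
    filter(allele != ref,
           n_allele >= params$min_read_count,
           n_allele / depth_pass >= params$min_allele_fraction)
  if (nrow(counts) == 0) return(empty_calls())
  counts %>%
    rename(alt = allele, alt_count = n_allele) %>%
    mutate(alt_count = as.integer(alt_count),
           depth_pass = as.integer(depth_pass),
           af = 100 * alt_count / depth_pass) %>%
    arrange(chrom, pos, desc(alt_count), alt) %>%
    select(chrom, pos, ref, alt, alt_count, depth_pass, af)
}

#' Raw per-site depth of a pileup table
#'
#' Depth here is the unfiltered observation count at each site (used for the
#' blood-coverage requirement of somatic classification, which is a property
#' of raw coverage rather than of filtered reads).
#'
#' @param pileup Long-format pileup table.
#' @return Tibble with `chrom`, `pos`, `depth`.
#' @export
pileup_depth <- function(pileup) {
  as_tibble(pileup) %>% count(chrom, pos, name = "depth")
}
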