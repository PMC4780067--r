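make_site <- function(n_ref, n_alt, ref = "C", alt = "T", alt_q = 35,
                      alt_gapmm = 0L, ref_q = 35, ref_gapmm = 0L) {
  tibble::tibble(
    chrom = "ctg01", pos = 100L, ref = ref,
    allele = c(rep(alt, n_alt), rep(ref, n_ref)),
    baseq = c(rep(alt_q, length.out = n_alt), rep(ref_q, n_ref)),
    gapmm = c(rep(alt_gapmm, length.out = n_alt), rep(ref_gapmm, n_ref))
  )
}

test_that("presets carry the tumour and blood calling criteria", {
  tp <- tumour_preset()
  expect_equal(tp$max_gapmm_in_window, 2L)
  expect_equal(tp$window_bp, 21L)
  expect_equal(tp$min_base_quality, 30)
  expect_equal(tp$min_read_count, 4L)
  expect_equal(tp$min_allele_fraction, 0.05)
  bp <- blood_preset()
  expect_equal(bp$max_gapmm_in_window, 3L)
  expect_equal(bp$window_bp, 21L)
  expect_equal(bp$min_base_quality, 25)
  expect_equal(bp$min_read_count, 1L)
  expect_equal(bp$min_allele_fraction, 0.02)
})

test_that("allele-fraction and read-count thresholds are inclusive at the boundary", {
  # 4 alt / 80 reads is exactly 5% and exactly count 4 -> called
  calls <- call_variants(make_site(76, 4), tumour_preset())
  expect_equal(nrow(calls), 1)
  expect_equal(calls$alt_count, 4L)
  expect_equal(calls$af, 5)
  # 3 alt reads fails the count threshold even at sufficient fraction
  expect_equal(nrow(call_variants(make_site(77, 3), tumour_preset())), 0)
  # blood preset calls a single read
  expect_equal(nrow(call_variants(make_site(40, 1), blood_preset())), 1)
})

test_that("reads failing the gap/mismatch window leave the denominator too", {
  col <- make_site(31, 5, alt_gapmm = c(3L, 0L, 0L, 0L, 0L))
  calls <- call_variants(col, tumour_preset())
  expect_equal(calls$alt_count, 4L)
  expect_equal(calls$depth_pass, 35L)
  expect_equal(calls$af, 100 * 4 / 35)
})

test_that("low-quality reads are removed before counting", {
  col <- make_site(30, 6, alt_q = 12)
  expect_equal(nrow(call_variants(col, tumour_preset())), 0)
  # the permissive blood quality floor (25) still rejects Q12
  expect_equal(nrow(call_variants(col, blood_preset())), 0)
})

test_that("multi-allelic sites emit one record per qualifying alternate, ordered", {
  col <- tibble::tibble(
    chrom = "ctg01", pos = 9L, ref = "G",
    allele = c(rep("A", 10), rep("T", 6), rep("G", 20)),
    baseq = 35, gapmm = 0L
  )
  calls <- call_variants(col, tumour_preset())
  expect_equal(calls$alt, c("A", "T"))
  expect_equal(calls$alt_count, c(10L, 6L))
  expect_equal(calls$depth_pass, c(36L, 36L))
})

test_that("anchored indel alleles are called like any other allele string", {
  col <- tibble::tibble(
    chrom = "ctg01", pos = 50L, ref = "TG",
    allele = c(rep("T", 12), rep("TG", 48)),
    baseq = 35, gapmm = 0L
  )
  calls <- call_variants(col, tumour_preset())
  expect_equal(calls$ref, "TG")
  expect_equal(calls$alt, "T")
  expect_equal(calls$af, 20)
})

test_that("malformed input is rejected and empty input yields no call", {
  col <- make_site(5, 5)
  col$baseq[1] <- -1
  expect_error(call_variants(col, tumour_preset()), "negative base quality")
  expect_equal(nrow(call_variants(col[0, ], tumour_preset())), 0)
})

test_that("calling is idempotent and matches the brute-force oracle on small columns", {
  withr::with_seed(404, {
    for (i in 1:300) {
      col <- random_column(sample(1:10, 1))
      params <- if (i %% 2 == 0) tumour_preset() else blood_preset()
      got <- call_variants(col, params)
      again <- call_variants(col, params)
      expect_identical(got, again)
      want <- oracle_call(col, params)
      expect_equal(nrow(got), length(want))
      for (j in seq_along(want)) {
        expect_equal(got$alt[j] %in% vapply(want, `[[`, "", "alt"), TRUE)
        w <- want[[which(vapply(want, `[[`, "", "alt") == got$alt[j])]]
        expect_equal(got$alt_count[j], w$alt_count)
        expect_equal(got$depth_pass[j], w$depth_pass)
        expect_equal(got$af[j], w$af)
      }
    }
  })
})

test_that("relaxing any threshold never removes a previously called variant", {
  relaxations <- list(
    function(p) caller_params(p$max_gapmm_in_window + 1L, p$window_bp,
                              p$min_base_quality, p$min_read_count,
                              p$min_allele_fraction),
    function(p) caller_params(p$max_gapmm_in_window, p$window_bp,
                              p$min_base_quality - 5, p$min_read_count,
                              p$min_allele_fraction),
    function(p) caller_params(p$max_gapmm_in_window, p$window_bp,
                              p$min_base_quality,
                              max(p$min_read_count - 1L, 0L),
                              p$min_allele_fraction),
    function(p) caller_params(p$max_gapmm_in_window, p$window_bp,
                              p$min_base_quality, p$min_read_count,
                              p$min_allele_fraction / 2)
  )
  withr::with_seed(405, {
    for (i in 1:60) {
      col <- random_column(sample(5:40, 1))
      base <- call_variants(col, tumour_preset())
      for (relax in relaxations) {
        relaxed <- call_variants(col, relax(tumour_preset()))
        expect_true(all(base$alt %in% relaxed$alt))
      }
    }
  })
})

test_that("call_pileup agrees with per-column calling across sites", {
  withr::with_seed(406, {
    cols <- lapply(1:25, function(i) {
      col <- random_column(sample(5:30, 1))
      col$pos <- 100L + i
      col
    })
    pileup <- dplyr::bind_rows(cols)
    whole <- call_pileup(pileup, tumour_preset())
    each <- dplyr::bind_rows(lapply(cols, call_variants, tumour_preset()))
    each <- dplyr::arrange(each, chrom, pos, dplyr::desc(alt_count), alt)
    expect_equal(as.data.frame(whole), as.data.frame(each))
  })
})
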