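ann_row <- function(clinical_snp = FALSE, in_cosmic = FALSE,
                    polyphen = NA_character_, sift = NA_character_,
                    splice_site_overlap = FALSE, dbsnp_pop_freq = NA_real_,
                    gene = "GENE1", in_segdup = FALSE,
                    chrom = "ctg01", pos = 100L, ref = "C", alt = "T") {
  tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
    clinical_snp = clinical_snp, in_cosmic = in_cosmic, polyphen = polyphen,
    sift = sift, splice_site_overlap = splice_site_overlap,
    dbsnp_pop_freq = dbsnp_pop_freq, in_segdup = in_segdup
  )
}

empty_panel <- tibble::tibble(chrom = character(), pos = integer(),
                              ref = character(), alt = character())

test_that("the damaging selection is an OR over the stated criteria", {
  # stop gain with no database flags is retained
  expect_true(select_damaging("stop_gain", ann_row()))
  # synonymous with nothing else is not
  expect_false(select_damaging("synonymous", ann_row()))
  # frameshift indel with NA predictions is retained
  expect_true(select_damaging("frameshift", ann_row()))
  expect_true(select_damaging("inframe_indel", ann_row()))
  # each single criterion suffices
  expect_true(select_damaging("missense", ann_row(clinical_snp = TRUE)))
  expect_true(select_damaging("missense", ann_row(in_cosmic = TRUE)))
  expect_true(select_damaging("missense",
                              ann_row(polyphen = "probably_damaging")))
  expect_true(select_damaging("missense", ann_row(sift = "damaging")))
  expect_true(select_damaging("synonymous",
                              ann_row(splice_site_overlap = TRUE)))
  expect_true(select_damaging("noncoding", ann_row(), splice_flag = TRUE))
  # the intermediate prediction grades do not qualify
  expect_false(select_damaging("missense",
                               ann_row(polyphen = "possibly_damaging")))
  expect_false(select_damaging("missense", ann_row(sift = "tolerated")))
})

test_that("gene blacklist matches families, not lookalike symbols", {
  hits <- c("TTN", "MUC16", "MUC4", "OR4F5", "OR2T1", "OR51E2")
  misses <- c("ORC1", "ORAI1", "TTN2", "SMARCB1", "KDM5C", "ORMDL3", "MYCL1")
  expect_true(all(is_blacklisted_gene(hits)))
  expect_false(any(is_blacklisted_gene(misses)))
  expect_false(is_blacklisted_gene(NA_character_))
})

test_that("exclusion filters fire on panel presence, frequency, segdup and blacklist", {
  v <- tibble::tibble(chrom = "ctg01", pos = 100L, ref = "C", alt = "T")
  panel1 <- dplyr::bind_cols(
    v, tibble::as_tibble(matrix(c(1L, rep(0L, 96)), nrow = 1,
                                dimnames = list(NULL, sprintf("s%02d", 1:97))))
  )
  tr <- exclusion_filters(v, ann_row(), panel1)
  expect_equal(tr$outcome[tr$filter_name == "control_panel"], "fail")
  expect_false(tr$final[1])
  # a population frequency of exactly 1% passes (rule is strictly greater)
  tr2 <- exclusion_filters(v, ann_row(dbsnp_pop_freq = 0.01), empty_panel)
  expect_equal(tr2$outcome[tr2$filter_name == "dbsnp_common"], "pass")
  tr3 <- exclusion_filters(v, ann_row(dbsnp_pop_freq = 0.0100001),
                           empty_panel)
  expect_equal(tr3$outcome[tr3$filter_name == "dbsnp_common"], "fail")
  tr4 <- exclusion_filters(v, ann_row(in_segdup = TRUE), empty_panel)
  expect_equal(tr4$outcome[tr4$filter_name == "segdup"], "fail")
  tr5 <- exclusion_filters(v, ann_row(gene = "OR4F5"), empty_panel)
  expect_equal(tr5$outcome[tr5$filter_name == "blacklist"], "fail")
  tr6 <- exclusion_filters(v, ann_row(gene = "ORC1"), empty_panel)
  expect_true(tr6$final[1])
  # every filter outcome is recorded even after a failure
  expect_equal(nrow(tr), 4)
})

test_that("segdup marking converts and overlaps intervals correctly", {
  segdups <- tibble::tibble(chrom = "ctg01", start = 150L, end = 200L)
  v <- tibble::tibble(chrom = c("ctg01", "ctg01", "ctg01", "ctg02"),
                      pos = c(149L, 150L, 200L, 150L),
                      ref = c("A", "A", "A", "A"))
  expect_equal(mark_segdup(v, segdups), c(FALSE, TRUE, TRUE, FALSE))
  # a deletion reaching into the interval overlaps
  v2 <- tibble::tibble(chrom = "ctg01", pos = 148L, ref = "AAA")
  expect_true(mark_segdup(v2, segdups))
})

test_that("every classified variant is traced and survivors are exactly the all-pass ones", {
  bundle <- generate_case(small_case_config(seed = 31))
  res <- run_pipeline(bundle = bundle)
  cls <- res$classified
  cls_ids <- paste(cls$chrom, cls$pos, cls$ref, cls$alt, sep = ":")
  per_variant <- res$cascade$traces %>%
    dplyr::group_by(variant_id) %>%
    dplyr::summarise(ok = all(outcome == "pass"), .groups = "drop")
  # traces cover every classified variant, surviving or not
  expect_setequal(per_variant$variant_id, cls_ids)
  surv <- dplyr::bind_rows(res$cascade$somatic_final,
                           res$cascade$germline_final)
  surv_ids <- paste(surv$chrom, surv$pos, surv$ref, surv$alt, sep = ":")
  expect_setequal(surv_ids,
                  intersect(per_variant$variant_id[per_variant$ok],
                            cls_ids[cls$status != "unclassifiable"]))
})

test_that("each planted decoy fails exactly its named filter", {
  bundle <- generate_case(small_case_config(seed = 32))
  res <- run_pipeline(bundle = bundle)
  truth <- bundle$truth
  key <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = ":")
  tr <- res$cascade$traces
  call_keys <- paste(res$tumour_calls$chrom, res$tumour_calls$pos,
                     res$tumour_calls$ref, res$tumour_calls$alt, sep = ":")
  cls_keys <- paste(res$classified$chrom, res$classified$pos,
                    res$classified$ref, res$classified$alt, sep = ":")
  for (i in which(startsWith(truth$planted_class, "decoy:"))) {
    kind <- sub("^decoy:", "", truth$planted_class[i])
    if (kind %in% c("low_af", "low_basequal", "gap_context")) {
      expect_false(key[i] %in% call_keys, label = kind)
    } else if (kind == "blood_evidence") {
      expect_equal(res$classified$status[cls_keys == key[i]],
                   "unclassifiable")
    } else {
      kind <- if (kind == "not_damaging") "damaging_selection" else kind
      fails <- tr[tr$variant_id == key[i] & tr$outcome == "fail", ]
      expect_equal(fails$filter_name, kind)
    }
  }
})

test_that("variants without an annotation record are excluded with a warning", {
  cls <- tibble::tibble(
    chrom = "ctg01", pos = c(100L, 200L), ref = "C", alt = "T",
    alt_count = 10L, depth_pass = 40L, af = 25,
    blood_af = NA_real_, blood_alt_count = NA_integer_,
    blood_depth_pass = NA_integer_, blood_depth = 50L, status = "somatic"
  )
  ann <- ann_row(sift = "damaging")
  csq <- tibble::tibble(
    chrom = "ctg01", pos = c(100L, 200L), ref = "C", alt = "T",
    gene = "GENE1", transcript = "t1", cds_pos = 10L, codon_index = 4L,
    ref_aa = "A", alt_aa = "T", kind = "missense", splice_flag = FALSE,
    hgvs_p = "p.Ala4Thr"
  )
  expect_warning(
    res <- run_cascade(cls, ann, empty_panel, csq),
    "no annotation record"
  )
  expect_equal(nrow(res$somatic_final), 1)
  expect_equal(res$somatic_final$pos, 100L)
  expect_true("unannotated" %in% res$traces$filter_name)
})

test_that("an empty classification table yields empty cascade output", {
  cls0 <- classify_variants(
    tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), alt_count = integer(),
                   depth_pass = integer(), af = numeric()),
    tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), alt_count = integer(),
                   depth_pass = integer(), af = numeric()),
    tibble::tibble(chrom = character(), pos = integer(), depth = integer())
  )
  res <- run_cascade(cls0, ann_row()[0, ], empty_panel,
                     tibble::tibble(chrom = character(), pos = integer(),
                                    ref = character(), alt = character(),
                                    gene = character(),
                                    transcript = character(),
                                    cds_pos = integer(),
                                    codon_index = integer(),
                                    ref_aa = character(),
                                    alt_aa = character(), kind = character(),
                                    splice_flag = logical(),
                                    hgvs_p = character()))
  expect_equal(nrow(res$somatic_final), 0)
  expect_equal(nrow(res$germline_final), 0)
  expect_equal(nrow(res$traces), 0)
})
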