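test_that("codon arithmetic maps CDS positions to codon indices", {
  expect_equal(codon_of(601), 201L)
  expect_equal(codon_of(3), 1L)
  expect_equal(codon_of(604), 202L) # brute force: 201 complete triplets + 1
  expect_error(codon_of(0), ">= 1")
  # non-decreasing, incrementing exactly at positions = 1 (mod 3)
  idx <- codon_of(1:300)
  expect_true(all(diff(idx) >= 0))
  bumps <- which(diff(idx) == 1) + 1
  expect_true(all(bumps %% 3 == 1))
})

test_that("a C>T in a CGA codon is a stop gain with simplified HGVS", {
  # codons: ATG CGA AAA -> variant at codon 2 position 1
  toy <- toy_gene("ATGCGAAAA")
  v <- list(chrom = "toy", pos = toy$start + 3L, ref = "C", alt = "T")
  got <- annotate_consequence(v, toy$model, toy$genome)
  expect_equal(got$kind, "stop_gain")
  expect_equal(got$cds_pos, 4L)
  expect_equal(got$codon_index, 2L)
  expect_equal(got$ref_aa, "R")
  expect_equal(got$alt_aa, "*")
  expect_equal(got$hgvs_p, "p.Arg2*")
})

test_that("synonymous and missense substitutions are classified via the genetic code", {
  toy <- toy_gene("ATGCTGACG")
  # CTG -> CTA, both Leu
  syn <- annotate_consequence(
    list(chrom = "toy", pos = toy$start + 5L, ref = "G", alt = "A"),
    toy$model, toy$genome
  )
  expect_equal(syn$kind, "synonymous")
  expect_equal(syn$hgvs_p, "p.Leu2=")
  # ACG -> ATG, Thr -> Met
  mis <- annotate_consequence(
    list(chrom = "toy", pos = toy$start + 7L, ref = "C", alt = "T"),
    toy$model, toy$genome
  )
  expect_equal(mis$kind, "missense")
  expect_equal(mis$hgvs_p, "p.Thr3Met")
})

test_that("indels inside the CDS frameshift unless a multiple of three", {
  toy <- toy_gene("ATGGAGCAGTTT")
  del <- annotate_consequence(
    list(chrom = "toy", pos = toy$start + 3L, ref = "GA", alt = "G"),
    toy$model, toy$genome
  )
  expect_equal(del$kind, "frameshift")
  expect_match(del$hgvs_p, "fs$")
  ins <- annotate_consequence(
    list(chrom = "toy", pos = toy$start + 4L, ref = "A", alt = "AT"),
    toy$model, toy$genome
  )
  expect_equal(ins$kind, "frameshift")
  inframe <- annotate_consequence(
    list(chrom = "toy", pos = toy$start + 3L, ref = "GAGC", alt = "G"),
    toy$model, toy$genome
  )
  expect_equal(inframe$kind, "inframe_indel")
})

test_that("reverse-strand annotation of a palindromic CDS mirrors the forward result", {
  # ATGCGACACGTGTCGCAT is its own reverse complement
  cds <- "ATGCGACACGTGTCGCAT"
  expect_equal(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds))),
    cds
  )
  fwd <- toy_gene(cds)
  rev <- toy_gene(cds)
  rev$model$strand <- "-"
  # forward variant at codon 2 pos 1 (C>T); its mirror on the minus strand
  # sits at the complementary genomic position with complemented alleles
  p_f <- fwd$start + 3L
  p_r <- rev$start + nchar(cds) - 1L - 3L
  got_f <- annotate_consequence(
    list(chrom = "toy", pos = p_f, ref = "C", alt = "T"), fwd$model,
    fwd$genome
  )
  got_r <- annotate_consequence(
    list(chrom = "toy", pos = p_r, ref = "G", alt = "A"), rev$model,
    rev$genome
  )
  expect_equal(got_r$kind, got_f$kind)
  expect_equal(got_r$cds_pos, got_f$cds_pos)
  expect_equal(got_r$hgvs_p, got_f$hgvs_p)
})

test_that("variants outside or spanning the CDS boundary are flagged", {
  toy <- toy_gene("ATGAAACCC")
  out <- annotate_consequence(
    list(chrom = "toy", pos = 5L, ref = "T", alt = "A"),
    toy$model, toy$genome
  )
  expect_equal(out$kind, "noncoding")
  expect_false(out$splice_flag)
  spanning <- annotate_consequence(
    list(chrom = "toy", pos = toy$start - 1L, ref = "TA", alt = "T"),
    toy$model, toy$genome
  )
  expect_equal(spanning$kind, "noncoding")
  expect_true(spanning$splice_flag)
})

test_that("multi-segment and multi-transcript models are annotated per transcript", {
  # two transcripts over one gene: one with a single CDS segment, one with
  # the same CDS split across two segments separated by an intron
  seq <- paste0(strrep("T", 10), "ATGCGA", strrep("A", 7), "CACTAA",
                strrep("T", 10))
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "toy"
  models <- tibble::tibble(
    gene = "TOY", transcript = c("t1", "t2", "t2"), chrom = "toy",
    strand = "+",
    seg_start = c(11L, 11L, 24L), seg_end = c(16L, 16L, 29L)
  )
  v <- list(chrom = "toy", pos = 14L, ref = "C", alt = "T")
  got <- annotate_consequences(
    tibble::tibble(chrom = "toy", pos = 14L, ref = "C", alt = "T"),
    models, genome
  )
  expect_equal(nrow(got), 2)
  expect_setequal(got$transcript, c("t1", "t2"))
  expect_setequal(got$kind, "stop_gain")
  # the split transcript maps the downstream segment correctly too
  v2 <- annotate_consequence(
    list(chrom = "toy", pos = 25L, ref = "A", alt = "T"),
    models[models$transcript == "t2", ], genome
  )
  expect_equal(v2$cds_pos, 8L)
})

test_that("substitution and indel classes follow purine/pyrimidine chemistry", {
  expect_equal(substitution_class("C", "T"), "transition")
  expect_equal(substitution_class("G", "A"), "transition")
  expect_equal(substitution_class(c("G", "A", "A"), c("T", "T", "C")),
               rep("transversion", 3))
  expect_error(substitution_class("TG", "T"), "single-base")
  expect_error(substitution_class("A", "A"), "differ")
  expect_equal(indel_class("NG", "N"), "deletion")
  expect_equal(indel_class("N", "NA"), "insertion")
  expect_error(indel_class("A", "C"), "length-changing")
})

test_that("spectrum summary partitions SNVs and indels", {
  tab <- somatic_mutation_table()
  got <- spectrum_summary(tab)
  expect_equal(unname(got), c(2L, 3L, 1L, 1L))
  expect_equal(sum(got[c("transitions", "transversions")]),
               sum(nchar(tab$ref) == 1 & nchar(tab$alt) == 1))
  expect_equal(unname(spectrum_summary(tab[0, ])), c(0L, 0L, 0L, 0L))
  homog <- tibble::tibble(ref = rep("C", 10), alt = rep("T", 10))
  expect_equal(unname(spectrum_summary(homog)), c(10L, 0L, 0L, 0L))
})
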