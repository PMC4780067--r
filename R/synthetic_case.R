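#' Configuration of a synthetic tumour/blood/RNA case
#'
#' Defines the study conditions the generator plants: the number and allele
#' fractions of subclonal somatic variants, the size and gene count of the
#' rare-and-damaging germline set with its three-way RNA expression split,
#' one germline-nonsense site with somatic loss of the wild-type allele in
#' an impure tumour, per-filter decoy variants, and sequencing depths.
#'
#' Defaults emulate the reported case: 7 somatic variants at subclonal
#' fractions 13.8/6.7/7.4/9/14.6/17/5.7 percent, 205 damaging germline
#' variants over 200 genes split 81 variant-expressed / 29 reference-only /
#' 95 not expressed, tumour purity 6/7 under a single-copy-deletion LOH
#' model (tumour DNA allele fraction 87.5%), tumour transcript fraction 0.5
#' at the LOH site (RNA allele fraction 75%), and a callable region of
#' 48.28 Mb.
#'
#' @param seed Integer RNG seed; the same seed yields a bit-identical
#'   bundle.
#' @param n_somatic Number of somatic pass variants.
#' @param somatic_afs True tumour allele fractions (0-1) of the somatic
#'   variants; all must be at least the tumour caller's minimum allele
#'   fraction.
#' @param n_germline_pass Number of germline variants that survive the
#'   cascade.
#' @param n_genes_germline Number of distinct genes carrying them (must not
#'   exceed `n_germline_pass`).
#' @param expression_split Integer triple (variant_expressed, ref_only,
#'   not_expressed) summing to `n_germline_pass`.
#' @param depth_dna_tumour,depth_dna_blood,depth_rna Mean read depths
#'   (Poisson) per sample.
#' @param purity Tumour cell fraction in (0, 1].
#' @param loh_model `"single_copy_deletion"` or `"copy_neutral"`.
#' @param rna_tumour_fraction Fraction of transcripts at the LOH site that
#'   originate from tumour cells.
#' @param n_decoys_per_filter Decoy variants planted per violated
#'   filter/stage (9 stages, see [generate_case()]).
#' @param n_background Reference-only background pileup sites.
#' @param callable_bp Callable-region size used for the mutation rate
#'   (fixture convention; the default reproduces a rate of 0.145/Mb for 7
#'   somatic mutations).
#' @return A validated `case_config` list.
#' @export
case_config <- function(seed = 1L,
                        n_somatic = 7L,
                        somatic_afs = c(0.138, 0.067, 0.074, 0.09,
                                        0.146, 0.17, 0.057),
                        n_germline_pass = 205L,
                        n_genes_germline = 200L,
                        expression_split = c(variant_expressed = 81L,
                                             ref_only = 29L,
                                             not_expressed = 95L),
                        depth_dna_tumour = 200,
                        depth_dna_blood = 100,
                        depth_rna = 50,
                        purity = 6 / 7,
                        loh_model = c("single_copy_deletion",
                                      "copy_neutral"),
                        rna_tumour_fraction = 0.5,
                        n_decoys_per_filter = 6L,
                        n_background = 100L,
                        callable_bp = 48280000) {
  loh_model <- match.arg(loh_model)
  cfg <- list(
    seed = as.integer(seed), n_somatic = as.integer(n_somatic),
    somatic_afs = somatic_afs,
    n_germline_pass = as.integer(n_germline_pass),
    n_genes_germline = as.integer(n_genes_germline),
    expression_split = as.integer(expression_split),
    depth_dna_tumour = depth_dna_tumour,
    depth_dna_blood = depth_dna_blood, depth_rna = depth_rna,
    purity = purity, loh_model = loh_model,
    rna_tumour_fraction = rna_tumour_fraction,
    n_decoys_per_filter = as.integer(n_decoys_per_filter),
    n_background = as.integer(n_background),
    callable_bp = callable_bp
  )
  names(cfg$expression_split) <- c("variant_expressed", "ref_only",
                                   "not_expressed")
  tp <- tumour_preset()
  if (length(cfg$somatic_afs) != cfg$n_somatic) {
    stop("somatic_afs must have length n_somatic")
  }
  if (cfg$n_somatic > 0 && any(cfg$somatic_afs < tp$min_allele_fraction)) {
    stop("all somatic_afs must be >= the tumour caller minimum allele ",
         "fraction (", tp$min_allele_fraction, ")")
  }
  if (sum(cfg$expression_split) != cfg$n_germline_pass) {
    stop("expression_split must sum to n_germline_pass")
  }
  if (cfg$n_genes_germline > cfg$n_germline_pass && cfg$n_germline_pass > 0) {
    stop("n_genes_germline must not exceed n_germline_pass")
  }
  if (cfg$n_germline_pass > 0 &&
      cfg$n_germline_pass - cfg$n_genes_germline > cfg$n_genes_germline - 1L) {
    stop("at most one extra variant per germline gene is supported")
  }
  if (cfg$purity <= 0 || cfg$purity > 1) stop("purity must be in (0, 1]")
  if (cfg$rna_tumour_fraction < 0 || cfg$rna_tumour_fraction > 1) {
    stop("rna_tumour_fraction must be in [0, 1]")
  }
  if (cfg$n_somatic > 0 &&
      min(cfg$somatic_afs) * cfg$depth_dna_tumour < tp$min_read_count) {
    stop("under-powered fixture: requested allele fraction cannot be ",
         "represented with >= ", tp$min_read_count,
         " reads at the configured tumour depth")
  }
  if (cfg$n_germline_pass > 0 && 0.5 * cfg$depth_dna_blood < 4) {
    stop("under-powered fixture: blood depth too low for germline ",
         "heterozygous calls")
  }
  structure(cfg, class = "case_config")
}

# planted variant shapes: codon planted at the variant's codon index, the
# substituted/anchored position within it, and the alternate allele
VKINDS <- list(
  mis_CT  = list(codon = "ACG", pic = 2L, alt = "T"), # Thr>Met, transition
  mis_GA  = list(codon = "GCT", pic = 1L, alt = "A"), # Ala>Thr, transition
  mis_GT  = list(codon = "GCA", pic = 1L, alt = "T"), # Ala>Ser, transversion
  mis_AT  = list(codon = "GAG", pic = 2L, alt = "T"), # Glu>Val, transversion
  mis_AC  = list(codon = "TAC", pic = 2L, alt = "C"), # Tyr>Ser, transversion
  stop_CT = list(codon = "CGA", pic = 1L, alt = "T"), # Arg>*, nonsense
  syn     = list(codon = "CTG", pic = 3L, alt = "A"), # Leu>Leu, synonymous
  del1    = list(codon = "CAG", pic = 2L, indel = "del"), # AG>A frameshift
  ins1    = list(codon = "TCA", pic = 1L, indel = "ins")  # T>TA frameshift
)

DECOY_KINDS <- c("low_af", "low_basequal", "gap_context", "blood_evidence",
                 "not_damaging", "control_panel", "dbsnp_common", "segdup",
                 "blacklist")

SOMATIC_GENES <- c("SEPT03", "H2BFM", "ZIC4", "HIST2H2AB", "ZIK1",
                   "KRTAP6-3", "IFNA8")
SOMATIC_VKINDS <- c("del1", "mis_CT", "ins1", "mis_GT", "mis_AT",
                    "mis_AC", "mis_GA")
BLACKLIST_GENES <- c("TTN", "MUC16", "OR4F5")

NONSTOP_CODONS <- setdiff(
  names(Biostrings::GENETIC_CODE),
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]
)

random_cds <- function(n_codons) {
  paste(c("ATG", sample(NONSTOP_CODONS, n_codons - 1, replace = TRUE)),
        collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- read-level simulation ------------------------------------------------

sim_qualities <- function(n, p_minor = 0.1) {
  sample(c(35, 12), n, replace = TRUE, prob = c(1 - p_minor, p_minor))
}

sim_gapmm <- function(n) {
  rbinom(n, 2L, 0.03)
}

make_column <- function(chrom, pos, ref, alt, depth_mean, af,
                        exact_alt = NULL, force_alt_q = NULL,
                        force_alt_gapmm = NULL, predicate = NULL,
                        max_tries = 200L) {
  if (depth_mean <= 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  allele = character(), baseq = numeric(), gapmm = integer()))
  }
  for (i in seq_len(max_tries)) {
    depth <- max(rpois(1L, depth_mean), 1L)
    n_alt <- if (!is.null(exact_alt)) {
      min(exact_alt, depth)
    } else if (is.null(alt) || af <= 0) 0L else rbinom(1L, depth, af)
    alleles <- c(rep(if (is.null(alt)) ref else alt, n_alt),
                 rep(ref, depth - n_alt))
    baseq <- sim_qualities(depth)
    gapmm <- sim_gapmm(depth)
    if (n_alt > 0) {
      if (!is.null(force_alt_q)) baseq[seq_len(n_alt)] <- force_alt_q
      if (!is.null(force_alt_gapmm)) gapmm[seq_len(n_alt)] <- force_alt_gapmm
    }
    col <- tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                  allele = alleles, baseq = baseq, gapmm = as.integer(gapmm))
    if (is.null(predicate) || isTRUE(predicate(col))) return(col)
  }
  stop("under-powered fixture: could not realise allele fraction ", af,
       " at mean depth ", depth_mean, " for ", chrom, ":", pos,
       " within ", max_tries, " draws")
}

pred_called <- function(params, alt) {
  force(params); force(alt)
  function(col) {
    calls <- call_variants(col, params)
    any(calls$alt == alt)
  }
}

pred_not_called <- function(params, alt) {
  p <- pred_called(params, alt)
  function(col) !p(col)
}

pred_germline_blood <- function(params, alt, min_af = 20, min_count = 4L) {
  force(params); force(alt)
  function(col) {
    calls <- call_variants(col, params)
    hit <- calls[calls$alt == alt, ]
    nrow(hit) == 1 && hit$af >= min_af && hit$alt_count >= min_count
  }
}

pred_rna_state <- function(variant, want, min_reads = 1L, min_quality = 20) {
  force(variant); force(want)
  function(col) {
    expression_status(variant, col, min_reads, min_quality)$state == want
  }
}

# ---- plan construction ----------------------------------------------------

build_plan <- function(cfg) {
  rows <- list()
  if (cfg$n_somatic > 0) {
    genes <- if (cfg$n_somatic <= length(SOMATIC_GENES)) {
      SOMATIC_GENES[seq_len(cfg$n_somatic)]
    } else {
      c(SOMATIC_GENES,
        sprintf("SOM%03d", seq_len(cfg$n_somatic - length(SOMATIC_GENES))))
    }
    states <- rep(c("ref_only", "not_expressed"),
                  length.out = cfg$n_somatic)
    if (cfg$n_somatic >= 7) states[7] <- "not_expressed"
    rows$somatic <- tibble(
      planted_class = "somatic_pass", gene = genes,
      vkind = rep(SOMATIC_VKINDS, length.out = cfg$n_somatic),
      true_af_tumour = cfg$somatic_afs, true_af_blood = 0,
      true_af_rna = ifelse(states == "ref_only", 0, NA_real_),
      expression_state = states, loh = FALSE,
      polyphen = NA_character_,
      sift = ifelse(rep(SOMATIC_VKINDS, length.out = cfg$n_somatic) %in%
                      c("del1", "ins1"), NA_character_, "damaging"),
      clinical_snp = FALSE, in_cosmic = FALSE,
      dbsnp_pop_freq = NA_real_
    )
  }
  if (cfg$n_germline_pass > 0) {
    n <- cfg$n_germline_pass
    gene_names <- c("SMARCB1",
                    sprintf("GML%04d", seq_len(cfg$n_genes_germline - 1L)))
    extra <- n - cfg$n_genes_germline
    gene_assign <- c(gene_names,
                     if (extra > 0) gene_names[1L + seq_len(extra)])
    split <- cfg$expression_split
    states <- rep(c("variant_expressed", "ref_only", "not_expressed"),
                  times = split)
    af_loh <- expected_af_loh(cfg$purity, cfg$loh_model)
    # the two-hit site occupies the first slot; its RNA fraction follows the
    # tumour-transcript mixture when that slot is variant-expressed
    af_rna_loh <- switch(states[1],
      variant_expressed = (1 + cfg$rna_tumour_fraction) / 2,
      ref_only = 0,
      not_expressed = NA_real_
    )
    ann_cycle <- rep(c("polyphen", "sift", "cosmic", "clinical"),
                     length.out = n - 1L)
    rows$germline <- tibble(
      planted_class = "germline_pass", gene = gene_assign,
      vkind = c("stop_CT",
                rep(c("mis_CT", "mis_GA", "mis_GT", "mis_AT", "mis_AC"),
                    length.out = n - 1L)),
      true_af_tumour = c(af_loh, rep(0.5, n - 1L)),
      true_af_blood = 0.5,
      true_af_rna = c(af_rna_loh, ifelse(
        states[-1] == "variant_expressed", 0.5,
        ifelse(states[-1] == "ref_only", 0, NA_real_)
      )),
      expression_state = states, loh = c(TRUE, rep(FALSE, n - 1L)),
      polyphen = c(NA_character_,
                   ifelse(ann_cycle == "polyphen", "probably_damaging",
                          "benign")),
      sift = c(NA_character_,
               ifelse(ann_cycle == "sift", "damaging", "tolerated")),
      clinical_snp = c(FALSE, ann_cycle == "clinical"),
      in_cosmic = c(FALSE, ann_cycle == "cosmic"),
      dbsnp_pop_freq = rep(c(NA_real_, 0.002, 0.01), length.out = n)
    )
  }
  if (cfg$n_decoys_per_filter > 0) {
    k <- cfg$n_decoys_per_filter
    kinds <- rep(DECOY_KINDS, each = k)
    idx <- rep(seq_len(k), times = length(DECOY_KINDS))
    gene <- ifelse(
      kinds == "blacklist",
      rep_len(BLACKLIST_GENES, length(kinds))[seq_along(kinds)],
      ifelse(kinds == "segdup",
             sprintf("SEGD%03d", idx),
             sprintf("DCY%s%03d", toupper(gsub("_", "", kinds)), idx))
    )
    # blacklist decoys cycle the three blacklisted host genes
    gene[kinds == "blacklist"] <- rep_len(BLACKLIST_GENES,
                                          sum(kinds == "blacklist"))
    rows$decoys <- tibble(
      planted_class = paste0("decoy:", kinds), gene = gene,
      vkind = ifelse(kinds == "not_damaging", "syn", "mis_GA"),
      true_af_tumour = dplyr::case_when(
        kinds == "low_af" ~ 0.02,
        kinds %in% c("low_basequal", "gap_context") ~ 0.15,
        TRUE ~ 0.25
      ),
      true_af_blood = ifelse(kinds == "blood_evidence", 0.03, 0),
      true_af_rna = 0,
      expression_state = "ref_only", loh = FALSE,
      polyphen = ifelse(kinds == "not_damaging", "benign",
                        "probably_damaging"),
      sift = ifelse(kinds == "not_damaging", "tolerated", "damaging"),
      clinical_snp = FALSE, in_cosmic = FALSE,
      dbsnp_pop_freq = ifelse(kinds == "dbsnp_common", 0.05, NA_real_)
    )
  }
  plan <- bind_rows(rows)
  if (nrow(plan) == 0) {
    return(tibble(
      planted_class = character(), gene = character(), vkind = character(),
      true_af_tumour = numeric(), true_af_blood = numeric(),
      true_af_rna = numeric(), expression_state = character(),
      loh = logical(), polyphen = character(), sift = character(),
      clinical_snp = logical(), in_cosmic = logical(),
      dbsnp_pop_freq = numeric(), codon_index = integer()
    ))
  }
  # unique gene symbols may carry up to two variants; assign codon indices
  plan %>%
    group_by(gene) %>%
    mutate(codon_index = 30L + (row_number() - 1L) * 40L) %>%
    ungroup() %>%
    mutate(codon_index = ifelse(planted_class == "germline_pass" & loh,
                                201L, codon_index))
}

#' Generate a synthetic tumour/blood/RNA case bundle
#'
#' Builds a mini-genome (contigs of 10 kb holding single-CDS gene models),
#' plants every truth variant inside a coding sequence so its consequence is
#' computable, simulates per-site read pileups for tumour DNA, blood DNA and
#' tumour RNA (binomial allele counts at the planted fraction and Poisson
#' depth; base qualities drawn from a Q35/Q12 two-point mixture so quality
#' filters have bite; per-read gap/mismatch context generated directly as
#' counts), and emits the matching annotation track, segmental-duplication
#' intervals, 97-sample control panel and truth table.
#'
#' Pass-class truth records are drawn from a binomial conditioned on
#' callability (redrawn until the planted variant passes its per-sample
#' thresholds), so recovery of the planted counts is guaranteed for any
#' seed; decoy records are constructed to fail exactly their named filter:
#' `low_af`, `low_basequal`, `gap_context` (caller stage),
#' `blood_evidence` (classification stage: 3 alternate blood reads, neither
#' confidently somatic nor germline), `not_damaging` (selection stage), and
#' `control_panel`, `dbsnp_common`, `segdup`, `blacklist` (exclusion
#' stage).
#'
#' @param config A [case_config()] object.
#' @return A `case_bundle` list: `config`, `genome`
#'   ([Biostrings::DNAStringSet]), `gene_models`, `pileups` (list
#'   `tumour_dna`, `blood_dna`, `tumour_rna`), `annotations`, `segdups`
#'   (1-based inclusive), `panel`, `truth`.
#' @examples
#' bundle <- generate_case(case_config(seed = 42, n_germline_pass = 10,
#'   n_genes_germline = 9, expression_split = c(4, 3, 3),
#'   n_decoys_per_filter = 1, n_background = 10))
#' bundle$truth
#' @export
generate_case <- function(config) {
  stopifnot(inherits(config, "case_config"))
  withr::with_seed(config$seed, generate_case_impl(config))
}

generate_case_impl <- function(cfg) {
  plan <- build_plan(cfg)
  genes <- unique(plan$gene)
  n_genes <- length(genes)
  genes_per_contig <- 10L
  cds_len <- 720L # 240 codons
  n_contigs <- max(1L, ceiling(n_genes / genes_per_contig))
  contigs <- sprintf("ctg%02d", seq_len(n_contigs))
  contig_len <- 10000L

  gene_models <- if (n_genes > 0) {
    tibble(
      gene = genes,
      transcript = paste0(genes, "-t1"),
      chrom = contigs[ceiling(seq_len(n_genes) / genes_per_contig)],
      strand = "+",
      seg_start = 200L + ((seq_len(n_genes) - 1L) %% genes_per_contig) * 950L,
      seg_end = 200L + ((seq_len(n_genes) - 1L) %% genes_per_contig) * 950L +
        cds_len - 1L
    )
  } else {
    tibble(gene = character(), transcript = character(), chrom = character(),
           strand = character(), seg_start = integer(), seg_end = integer())
  }

  # contig sequences with designed CDSs and planted variant codons
  seqs <- vapply(contigs, function(x) random_dna(contig_len), character(1))
  for (i in seq_len(n_genes)) {
    gm <- gene_models[i, ]
    cds <- random_cds(cds_len / 3L)
    for (j in which(plan$gene == gm$gene)) {
      ci <- plan$codon_index[j]
      spec <- VKINDS[[plan$vkind[j]]]
      substr(cds, 3L * ci - 2L, 3L * ci) <- spec$codon
    }
    substr(seqs[gm$chrom], gm$seg_start, gm$seg_end) <- cds
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- contigs

  # genomic coordinates and allele strings for each planted variant
  if (nrow(plan) > 0) {
    coords <- lapply(seq_len(nrow(plan)), function(j) {
      gm <- gene_models[gene_models$gene == plan$gene[j], ]
      ci <- plan$codon_index[j]
      spec <- VKINDS[[plan$vkind[j]]]
      base0 <- gm$seg_start + (ci - 1L) * 3L
      if (is.null(spec$indel)) {
        pos <- base0 + spec$pic - 1L
        ref <- substr(spec$codon, spec$pic, spec$pic)
        alt <- spec$alt
      } else if (spec$indel == "del") {
        pos <- base0 + spec$pic - 1L
        ref <- substr(spec$codon, spec$pic, spec$pic + 1L)
        alt <- substr(spec$codon, spec$pic, spec$pic)
      } else {
        pos <- base0 + spec$pic - 1L
        ref <- substr(spec$codon, spec$pic, spec$pic)
        alt <- paste0(ref, "A")
      }
      tibble(chrom = gm$chrom, pos = as.integer(pos), ref = ref, alt = alt)
    })
    plan <- dplyr::bind_cols(bind_rows(coords), plan)
  } else {
    plan <- tibble(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), planted_class = character(),
                   gene = character(), vkind = character(),
                   true_af_tumour = numeric(), true_af_blood = numeric(),
                   true_af_rna = numeric(), expression_state = character(),
                   loh = logical(), polyphen = character(),
                   sift = character(), clinical_snp = logical(),
                   in_cosmic = logical(), dbsnp_pop_freq = numeric(),
                   codon_index = integer())
  }

  # segmental-duplication intervals over the segdup-decoy genes
  segd_genes <- plan$gene[plan$planted_class == "decoy:segdup"]
  segdups <- if (length(segd_genes) > 0) {
    gene_models %>%
      filter(gene %in% segd_genes) %>%
      mutate(start = pmax(seg_start - 50L, 1L), end = seg_end + 50L) %>%
      select(chrom, start, end)
  } else {
    tibble(chrom = character(), start = integer(), end = integer())
  }

  # control-exome panel: the control_panel decoys carried by 3/97 controls,
  # plus panel-only variants absent from the case
  n_ctrl <- 97L
  panel_rows <- plan %>%
    filter(planted_class == "decoy:control_panel") %>%
    select(chrom, pos, ref, alt)
  extra_n <- 10L
  if (n_contigs >= 1) {
    epos <- as.integer(seq(20L, by = 12L, length.out = extra_n))
    eref <- substring(as.character(genome[[contigs[1]]]), epos, epos)
    ealt <- vapply(eref, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                   character(1))
    panel_rows <- bind_rows(panel_rows,
                            tibble(chrom = contigs[1], pos = epos,
                                   ref = unname(eref), alt = unname(ealt)))
  }
  carriers <- matrix(0L, nrow = nrow(panel_rows), ncol = n_ctrl,
                     dimnames = list(NULL, sprintf("s%02d", seq_len(n_ctrl))))
  for (r in seq_len(nrow(panel_rows))) {
    carriers[r, sample(n_ctrl, 3L)] <- 1L
  }
  panel <- dplyr::bind_cols(panel_rows, as_tibble(carriers))

  annotations <- plan %>%
    mutate(splice_site_overlap = FALSE,
           in_segdup = mark_segdup(plan, segdups)) %>%
    select(chrom, pos, ref, alt, gene, clinical_snp, in_cosmic, polyphen,
           sift, splice_site_overlap, dbsnp_pop_freq, in_segdup)

  # background reference-only sites in intergenic space
  bg <- if (cfg$n_background > 0) {
    bpos <- as.integer(20L + (seq_len(cfg$n_background) - 1L) %% 12L * 15L)
    bchrom <- contigs[1L + (seq_len(cfg$n_background) - 1L) %/% 12L %% n_contigs]
    bref <- vapply(seq_len(cfg$n_background), function(i) {
      substring(as.character(genome[[bchrom[i]]]), bpos[i], bpos[i])
    }, character(1))
    tibble(chrom = bchrom, pos = bpos, ref = bref)
  } else {
    tibble(chrom = character(), pos = integer(), ref = character())
  }

  tum_cols <- list(); bld_cols <- list(); rna_cols <- list()
  tp <- tumour_preset(); bp <- blood_preset()
  for (j in seq_len(nrow(plan))) {
    v <- plan[j, ]
    klass <- v$planted_class
    kind <- sub("^decoy:", "", klass)
    # tumour DNA
    if (klass %in% c("somatic_pass", "germline_pass") ||
        kind %in% c("blood_evidence", "not_damaging", "control_panel",
                    "dbsnp_common", "segdup", "blacklist")) {
      tum_cols[[j]] <- make_column(v$chrom, v$pos, v$ref, v$alt,
                                   cfg$depth_dna_tumour, v$true_af_tumour,
                                   predicate = pred_called(tp, v$alt))
    } else if (kind == "low_af") {
      tum_cols[[j]] <- make_column(v$chrom, v$pos, v$ref, v$alt,
                                   cfg$depth_dna_tumour, v$true_af_tumour,
                                   predicate = pred_not_called(tp, v$alt))
    } else if (kind == "low_basequal") {
      tum_cols[[j]] <- make_column(
        v$chrom, v$pos, v$ref, v$alt, cfg$depth_dna_tumour, 0,
        exact_alt = max(4L, round(v$true_af_tumour * cfg$depth_dna_tumour)),
        force_alt_q = 12
      )
    } else if (kind == "gap_context") {
      tum_cols[[j]] <- make_column(
        v$chrom, v$pos, v$ref, v$alt, cfg$depth_dna_tumour, 0,
        exact_alt = max(4L, round(v$true_af_tumour * cfg$depth_dna_tumour)),
        force_alt_gapmm = 4L
      )
    }
    # blood DNA
    if (klass == "germline_pass") {
      bld_cols[[j]] <- make_column(v$chrom, v$pos, v$ref, v$alt,
                                   cfg$depth_dna_blood, v$true_af_blood,
                                   predicate = pred_germline_blood(bp, v$alt))
    } else if (kind == "blood_evidence") {
      bld_cols[[j]] <- make_column(v$chrom, v$pos, v$ref, v$alt,
                                   cfg$depth_dna_blood, 0,
                                   exact_alt = 3L, force_alt_q = 35,
                                   force_alt_gapmm = 0L)
    } else {
      bld_cols[[j]] <- make_column(v$chrom, v$pos, v$ref, NULL,
                                   cfg$depth_dna_blood, 0)
    }
    # tumour RNA
    key <- list(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt)
    if (v$expression_state == "variant_expressed") {
      rna_cols[[j]] <- make_column(
        v$chrom, v$pos, v$ref, v$alt, cfg$depth_rna, v$true_af_rna,
        predicate = pred_rna_state(key, "variant_expressed")
      )
    } else if (v$expression_state == "ref_only") {
      rna_cols[[j]] <- make_column(
        v$chrom, v$pos, v$ref, NULL, cfg$depth_rna, 0,
        predicate = pred_rna_state(key, "ref_only")
      )
    } # not_expressed: no RNA rows at all
  }
  for (b in seq_len(nrow(bg))) {
    tum_cols[[length(tum_cols) + 1L]] <-
      make_column(bg$chrom[b], bg$pos[b], bg$ref[b], NULL,
                  cfg$depth_dna_tumour, 0)
    bld_cols[[length(bld_cols) + 1L]] <-
      make_column(bg$chrom[b], bg$pos[b], bg$ref[b], NULL,
                  cfg$depth_dna_blood, 0)
  }

  truth <- plan %>%
    select(chrom, pos, ref, alt, gene, planted_class, true_af_tumour,
           true_af_blood, true_af_rna, expression_state, loh)

  structure(list(
    config = cfg,
    genome = genome,
    gene_models = gene_models,
    pileups = list(
      tumour_dna = bind_rows(tum_cols),
      blood_dna = bind_rows(bld_cols),
      tumour_rna = bind_rows(rna_cols)
    ),
    annotations = annotations,
    segdups = segdups,
    panel = panel,
    truth = truth
  ), class = "case_bundle")
}

#' Simulate a single-site pileup at a known allele fraction
#'
#' A direct binomial draw at exact depth with uniform base quality: the
#' simplest model under which a called allele fraction should recover the
#' planted one to within binomial error. Used for allele-fraction recovery
#' experiments (subclonal somatic fractions, LOH DNA shift, LOH RNA
#' fraction).
#'
#' @param depth Exact number of reads.
#' @param af True allele fraction (0-1).
#' @param chrom,pos,ref,alt Variant key of the simulated site.
#' @param baseq Base quality assigned to every read.
#' @return A single-site pileup tibble suitable for [call_variants()].
#' @export
simulate_site_pileup <- function(depth, af, chrom = "site", pos = 1000L,
                                 ref = "C", alt = "T", baseq = 35) {
  n_alt <- rbinom(1L, depth, af)
  tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref,
    allele = c(rep(alt, n_alt), rep(ref, depth - n_alt)),
    baseq = baseq, gapmm = 0L
  )
}
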