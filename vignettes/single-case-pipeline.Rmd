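---
title: "Single-case tumour/blood/RNA variant analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-case tumour/blood/RNA variant analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomecase)
```

## The analysis problem

`exomecase` implements, as a tested and reusable pipeline, the variant
analysis of a single paediatric rhabdoid-tumour case sequenced in three
libraries: tumour exome, matched blood exome and tumour mRNA. Rhabdoid
tumours are defined by biallelic inactivation of the SWI/SNF subunit gene
*SMARCB1*, typically a germline point mutation combined with somatic loss
of the wild-type allele, and they carry remarkably few additional somatic
mutations. A faithful re-analysis therefore needs five things: a pileup
variant caller with explicit per-sample read-level criteria, a
somatic/germline classifier against the matched blood, a
damaging-variant selection and exclusion cascade with auditable
provenance, integration of DNA variants with RNA allele counts, and an
allele-fraction model for loss of heterozygosity (LOH) in an impure
tumour. A hypergeometric gene-set overlap module covers the downstream
pathway-level question.

Because the original read data are not deposited, the package ships a
synthetic case generator that plants the case's reported structure as
ground truth, so every stage can be validated end to end by recovery.

## Variant calling from pileups

The caller operates on pileup columns: per-site stacks of read
observations, each carrying the observed allele, its phred base quality
and the number of gaps/mismatches that read shows within a 21 bp window
around the site. Two presets encode the per-sample criteria:

| preset  | gaps/mismatches (21 bp) | min base quality | min read count | min allele fraction |
|---------|------------------------:|-----------------:|---------------:|--------------------:|
| tumour  | 2 | 30 | 4 | 5% |
| blood   | 3 | 25 | 1 | 2% |

Reads failing the quality or gap/mismatch criteria are removed first and
also leave the denominator: the reported allele fraction is
`alt_count / depth_pass` over the *surviving* reads, because the
thresholds are properties of countable read evidence, not of raw
coverage. All thresholds are inclusive (4 alternate reads in 80 is
exactly 5% and is called). The "minimum read count" is applied to the
alternate allele, not total depth — this is the reading consistent with
observing a reported call at 5.7% allele fraction. Indels use anchored,
VCF-compatible alleles (deletion `TG>T`, insertion `T>TA`) carrying the
anchor base's quality. Multi-allelic sites emit every qualifying
alternate, ordered by descending count then allele string. Tumour RNA is
called with the tumour preset, mirroring the study design of applying the
same settings to RNA as to tumour DNA.

## Somatic/germline classification

A tumour call is **somatic** when blood shows zero qualifying alternate
reads under the permissive blood preset *and* raw blood coverage is at
least 8, so that absence in blood is informative. It is **germline**
when the same allele is called in blood at ≥ 20% allele fraction with
≥ 4 supporting reads. Two points were genuinely open and are package
decisions: (i) the 20%/count-4 thresholds are applied to the blood
sample, the constitutive tissue; (ii) sites with 1–3 alternate blood
reads (possible low-level germline or artifact) are neither confidently
somatic nor germline and are reported as **unclassifiable** rather than
forced into either bin.

## Selection and exclusion cascade

A classified variant is *selected* as potentially functional if **any**
criterion holds: reported clinical SNP, present in the somatic cancer
catalogue, PolyPhen-style `probably_damaging` or SIFT-style `damaging`
(the intermediate `possibly_damaging` grade does not qualify and missing
predictions count as non-damaging), splice-site overlap, a gained stop
codon, or a protein-altering indel. Selected variants then face four
exclusion filters: presence in any of 97 control exomes, catalogued
population frequency strictly above 1% (exactly 1% passes), overlap with
a segmental duplication (BED input, 0-based half-open, converted at the
boundary), and a gene blacklist. The blacklist matches families rather
than literal symbols: exact `TTN`, prefix `MUC`, and `OR` followed by a
digit so that `OR4F5` is excluded but `ORC1` is not. Every filter is
evaluated for every variant and every outcome is recorded in a trace
table, which makes the survivor set independent of evaluation order and
every rejection auditable. Database semantics (what precisely counts as
a "clinical SNP" in a given release) are deliberately modelled as
booleans supplied by the annotation track: interpreting live databases
is version-bound and out of scope. The germline arm uses the identical
cascade.

## Coding consequences

Gene models are lists of 1-based inclusive CDS segments in translation
order; reverse-strand models complement alleles before translation with
the standard genetic code (via `Biostrings::GENETIC_CODE`). The codon
index of CDS position `p` is `ceiling(p / 3)` — position 601 is codon
201. Indels whose length change is not a multiple of three within the
CDS are frameshifts. Protein strings use a simplified HGVS dialect
(`p.Arg201*`, `p.Glu343fs`, `p.Leu2=`) without extension lengths; full
HGVS validation is out of scope. Variants partially overlapping a CDS
segment are flagged splice-region and handed to the cascade via the
splice criterion. Substitution spectra classify A↔G and C↔T as
transitions, everything else among SNVs as transversions.

## RNA integration

For each DNA variant the RNA pileup is reduced to counts of variant and
reference reads at quality ≥ 20. An allele is *detected* at ≥ 1 read by
default; the detection threshold is configurable because the original
analysis reports detection without stating one, and a single
well-anchored RNA read is the weakest evidence consistent with those
reports. The three states — variant expressed, reference only, not
expressed — partition every input, and raw counts are always reported so
that sub-threshold evidence remains visible (the "No (0)" versus
"Yes (35)" table style).

## LOH and tumour purity

At a germline heterozygous site, somatic loss of the wild-type allele
shifts the tumour allele fraction upward from ~50%. The original
analysis inferred LOH by inspection; a reusable pipeline needs a rule,
so the package calls LOH when the shift is at least 20 percentage points
*and* a two-sided exact test on the 2×2 allele-count table
(`stats::fisher.test`) gives p ≤ 0.01. Both defaults are deliberately
conservative for exome depths and are configurable.

Purity is estimated under two explicit copy models. With tumour purity
$p$, a deletion of the wild-type copy gives expected allele fraction
$\mathrm{af} = 1/(2-p)$ (tumour cells contribute one variant copy,
normal cells two balanced copies), inverted as $p = 2 - 1/\mathrm{af}$;
copy-neutral LOH gives $\mathrm{af} = (1+p)/2$, inverted as
$p = 2\,\mathrm{af} - 1$. An allele fraction of 87.5% yields purity
6/7 ≈ 0.857 under the deletion model and 0.75 under the copy-neutral
model; which copy model underlies a given case cannot be decided from a
single site, so both are reported. Allele fractions at or below 50%
carry no LOH signal and return `NA`. In RNA, if a fraction $f$ of
transcripts at the site comes from tumour cells expressing only the
variant allele while normal transcripts are balanced, the expected RNA
allele fraction is $(1+f)/2$ — 75% at $f = 0.5$. The DNA cellular purity
and the RNA tumour-transcript fraction are kept as independent
parameters because expression contamination need not equal cellular
contamination.

## Gene-set overlap

Up- and down-regulated query lists are tested separately against GMT
collections with the exact hypergeometric upper tail
$P(X \ge k)$ (`stats::phyper`) and Benjamini–Hochberg adjustment
(`stats::p.adjust`). The background universe is configurable and
defaults to the union of all supplied set members and the query, because
the original background is not recorded; results are sensitive to this
choice and the vignette recommends passing the full annotated gene list
of the platform when available. Differential-expression testing itself
is out of scope — the module consumes gene lists.

## The synthetic case generator

The generator emulates the *reported structure* of the case, not its
sequences. Defaults are the study conditions: 7 somatic variants at
subclonal allele fractions 13.8/6.7/7.4/9/14.6/17/5.7 percent, none
variant-expressed in RNA; 205 rare-and-damaging germline variants over
200 genes with an 81/29/95 expression split; one germline nonsense site
(stop codon at codon 201) with somatic LOH at purity 6/7 under the
single-copy-deletion model (DNA allele fraction 87.5%, RNA 75% at tumour
transcript fraction 0.5); and decoy variants violating each pipeline
stage: three caller-level decoys (fraction below 5%, alternate reads at
Q12, alternate reads with 4 gaps/mismatches), a classification decoy
with exactly 3 alternate blood reads, a selection decoy (synonymous,
flag-free), and one decoy per exclusion filter. Mean depths default to
200× tumour DNA, 100× blood and 50× RNA — higher than the original
exomes, because the fixture's purpose is reliable recovery of the
planted truth at desk scale, and two of the planted somatic fractions
sit within one binomial standard deviation of the 5% calling threshold
at shallower depths.

The mini-genome uses contigs of 10 kb holding single-segment CDS models
of 720 bp on the forward strand; every planted variant is embedded in a
designed codon so its consequence (missense, nonsense, frameshift,
synonymous) is computable from sequence rather than asserted.
Base qualities follow a two-point Q35/Q12 mixture (10% Q12) so quality
filters have bite; per-read gap/mismatch context is generated directly
as counts because alignment is out of scope. Depth is Poisson around the
configured mean; allele counts are binomial at the planted fraction.

One sampling decision matters and is worth stating plainly: pass-class
truth records are drawn from a binomial *conditioned on callability* —
the column is redrawn until the planted variant passes its per-sample
thresholds — and decoys are conversely conditioned to fail exactly their
stage. Without conditioning, a variant planted at 5.7% hovers at the 5%
cutoff and the planted counts (7/205/200/81/29) would only be recovered
for some seeds, which would make recovery tests meaningless. The
conditioning is a statement about the fixture ("the truth is callable by
construction"), not about the caller. Unconditioned sampling is retained
where calibration is the point: background and heterozygous-site
calibration checks, and the dedicated single-site simulator
(`simulate_site_pileup()`, exact depth, uniform quality) used for
allele-fraction recovery experiments.

What the generator does **not** emulate — and hence what passing
recovery tests do not show about real data: read-level alignment
artifacts (mismapping in segmental duplications is represented only by
the interval annotation), strand bias, sequencing-error substitution
spectra, transcript-isoform structure, inter-library coverage
heterogeneity beyond Poisson, and any correlation structure between
neighbouring sites.

The callable-region size is a fixture convention exposed as
`callable_bp` (default 48,280,000, under which 7 somatic mutations give
0.145/Mb to three decimals). The enrolled exome target of 62.1 Mb would
give 0.113/Mb; since the effective denominator behind the reported rate
is not stated, the parameter is configurable rather than asserted.

## Numerical and engineering choices

* Coordinates are 1-based inclusive everywhere except BED, converted at
  the I/O boundary (`read_segdup_bed()`, `write_segdup_bed()`).
* Allele fractions are percentages with one decimal in reports; internal
  computation is double precision throughout.
* Ties at multi-allelic sites break by descending count, then allele
  string.
* Every random draw in the generator flows from the single config seed
  via `withr::with_seed`; identical seeds give bit-identical serialized
  bundles (checked byte-for-byte in the tests).
* Degenerate inputs: an empty pileup column yields no call (not an
  error); negative base quality is a malformed-input error; zero depth
  on either side of the LOH test yields an `NA` call; a variant lacking
  an annotation record is excluded with an `unannotated` trace entry and
  a warning; configs whose planted fractions cannot be represented with
  at least the caller's minimum read count at the configured depth are
  rejected as under-powered.

Test problem sizes were chosen for desk-scale runs: the default case
(~270 planted variants plus backgrounds, three samples) generates and
analyses in seconds; the calibration property uses 1,000 heterozygous
sites; the LOH type-I property uses 10,000 null replicates at depth 100;
caller/oracle equivalence enumerates a few hundred random small columns.

## Worked example

```{r example, eval = FALSE}
library(exomecase)
res <- run_pipeline(case_config(seed = 1))
res$summary
#> Single-case variant analysis summary
#>   somatic mutations:         7
#>   somatic rate per Mb:       0.145
#>   transitions/transversions: 2 / 3
#>   deletions/insertions:      1 / 1
#>   germline survivors:        205 in 200 genes
#>   RNA split (var/ref/none):  81/29/95
#>   LOH calls:                 1
```

The planted two-hit site is recovered with its allele-fraction shift and
purity estimate:

```{r loh, eval = FALSE}
site <- res$bundle$truth[res$bundle$truth$loh, ]
dplyr::filter(res$loh, chrom == site$chrom, pos == site$pos)
```

Note that `loh_calls` can occasionally exceed the single planted site:
with ~204 null heterozygous survivors scanned at α = 0.01 together with
the 20-point shift requirement, an occasional chance call is expected
and is the statistically honest behaviour of the rule.

## Known limitations

* The generator validates recovery, not discovery performance on real
  reads; no claim is made about sensitivity/specificity on actual
  alignments.
* The exact test treats read counts as independent draws; duplicate
  reads or overlapping mates would violate this on real data.
* Purity estimation uses a single LOH site; genome-wide copy-number
  segmentation is explicitly out of scope.
* HGVS output is a simplified dialect intended for reports, not for
  databases round-trips.
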