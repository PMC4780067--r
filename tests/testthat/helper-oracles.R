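# Independent oracles, deliberately naive: plain loops and exhaustive
# enumeration, sharing no code with the implementation they check.

# literal read-by-read application of the calling rule
oracle_call <- function(column, params) {
  surviving <- list()
  for (i in seq_len(nrow(column))) {
    row <- column[i, ]
    if (row$baseq >= params$min_base_quality &&
        row$gapmm <= params$max_gapmm_in_window) {
      surviving[[length(surviving) + 1]] <- row$allele
    }
  }
  alleles <- unlist(surviving)
  dp <- length(alleles)
  out <- list()
  if (dp == 0) return(out)
  for (a in sort(unique(alleles))) {
    if (a == column$ref[1]) next
    cnt <- sum(alleles == a)
    if (cnt >= params$min_read_count && cnt / dp >= params$min_allele_fraction) {
      out[[length(out) + 1]] <- list(alt = a, alt_count = cnt,
                                     depth_pass = dp, af = 100 * cnt / dp)
    }
  }
  out
}

random_column <- function(n_obs, ref = "A", alleles = c("A", "C", "G")) {
  tibble::tibble(
    chrom = "ctg01", pos = 500L, ref = ref,
    allele = sample(alleles, n_obs, replace = TRUE),
    baseq = sample(c(35, 28, 12), n_obs, replace = TRUE),
    gapmm = sample(0:4, n_obs, replace = TRUE)
  )
}

# two-sided exact p for a 2x2 table by full hypergeometric enumeration
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  xs <- max(0, k - n_):min(k, m)
  probs <- vapply(xs, function(x) stats::dhyper(x, m, n_, k), numeric(1))
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# P(overlap >= k) by enumerating every possible draw of n from N
overlap_p_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# hand Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# mini-genome with a single CDS planted at a fixed offset
toy_gene <- function(cds, chrom = "toy", start = 21L, strand = "+",
                     flank = 20L) {
  stopifnot(nchar(cds) %% 3 == 0)
  seq <- paste0(strrep("T", flank), cds, strrep("T", flank))
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- chrom
  model <- tibble::tibble(
    gene = "TOY", transcript = "TOY-t1", chrom = chrom, strand = strand,
    seg_start = start, seg_end = start + nchar(cds) - 1L
  )
  list(genome = genome, model = model, start = start)
}

small_case_config <- function(seed = 11, ...) {
  case_config(
    seed = seed, n_germline_pass = 10L, n_genes_germline = 9L,
    expression_split = c(4L, 3L, 3L), n_decoys_per_filter = 2L,
    n_background = 10L, ...
  )
}
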