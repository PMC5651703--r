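# Shared fixtures and independent oracles, all built in code.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# Small screen used by several suites.
tiny_config <- function(seed = 1, ...) {
  sim_config(n_tag_snps = 10, linked_per_tag = 4, fragments_per_region = 100,
             pre_fraction = 0.1, nre_fraction = 0.1, regsnp_fraction = 0.05,
             seed = seed, ...)
}

# Independent exhaustive-enumeration oracle for the two-sided Fisher p:
# sum of hypergeometric-null probabilities of all tables (margins fixed)
# no more probable than the observed one. Relative epsilon guards float ties.
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive O(n*m) point-in-interval overlap oracle.
overlap_naive <- function(snps, peaks) {
  vapply(seq_len(nrow(snps)), function(i) {
    any(peaks$chrom == snps$chrom[i] &
          peaks$start <= snps$pos[i] - 1L & snps$pos[i] - 1L < peaks$end)
  }, logical(1))
}

# Hand-written SAM fixture: one proper 465-bp pair covering a panel SNP,
# one proper 700-bp pair (too long), one unpaired read.
sam_fixture_panel <- function() {
  tibble(chrom = "chr1", pos = c(1050L, 2050L), snp_id = c("rs1", "rs2"),
         ref = c("A", "A"), alt = c("G", "G"), maf = c(0.2, 0.2))
}

write_sam_fixture <- function(path, snp_base = "G", snp_qual = "I",
                              extra_lines = character()) {
  seq100 <- function(base_at = NULL, base = "A", fill = "A") {
    s <- strrep(fill, 100)
    if (!is.null(base_at)) substr(s, base_at, base_at) <- base
    s
  }
  q100 <- function(qual_at = NULL, qual = "I") {
    s <- strrep("I", 100)
    if (!is.null(qual_at)) substr(s, qual_at, qual_at) <- qual
    s
  }
  lines <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:100000",
    # pair p1: span 1000-1465 (465 bp), R1 covers SNP rs1 at pos 1050
    sprintf("p1\t99\tchr1\t1001\t60\t100M\t=\t1366\t465\t%s\t%s",
            seq100(50, snp_base), q100(50, snp_qual)),
    sprintf("p1\t147\tchr1\t1366\t60\t100M\t=\t1001\t-465\t%s\t%s",
            seq100(), q100()),
    # pair p2: span 2000-2700 (700 bp), covers rs2 but too long
    sprintf("p2\t99\tchr1\t2001\t60\t100M\t=\t2601\t700\t%s\t%s",
            seq100(50, "G"), q100()),
    sprintf("p2\t147\tchr1\t2601\t60\t100M\t=\t2001\t-700\t%s\t%s",
            seq100(), q100()),
    # unpaired read
    sprintf("u1\t0\tchr1\t3001\t60\t100M\t*\t0\t0\t%s\t%s", seq100(), q100()),
    extra_lines
  )
  writeLines(lines, path)
  path
}

# Design with genotype orthogonal to (1, C, M) in sample.
orthogonal_design <- function(n, seed) {
  set.seed(seed)
  C <- rnorm(n)
  M <- rnorm(n)
  g0 <- rbinom(n, 2, 0.4)
  G <- residuals(lm(g0 ~ C + M))  # orthogonal to (1, C, M) in sample
  tibble(C = C, M = M, G = G)
}

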