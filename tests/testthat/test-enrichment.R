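test_that("interval overlap agrees with the naive oracle on random fixtures", {
  set.seed(33)
  for (rep in 1:5) {
    snps <- tibble(snp_id = sprintf("s%d", 1:80),
                   chrom = sample(c("chr1", "chr2"), 80, replace = TRUE),
                   pos = sample.int(5000, 80))
    peaks <- tibble(chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                    start = sample.int(4900, 30))
    peaks$end <- peaks$start + sample.int(200, 30)
    expect_equal(snps_in_peaks(snps, peaks), overlap_naive(snps, peaks))
  }
  # boundary semantics of 0-based half-open peaks against 1-based positions
  snps <- tibble(snp_id = c("a", "b", "c"), chrom = "chr1",
                 pos = c(100L, 101L, 110L))
  peaks <- tibble(chrom = "chr1", start = 100L, end = 109L)
  expect_equal(snps_in_peaks(snps, peaks), c(FALSE, TRUE, FALSE))
})

test_that("overlap enrichment handles empty classes and zero margins", {
  snps <- tibble(snp_id = c("a", "b"), chrom = "chr1", pos = c(100L, 200L),
                 class = c("PRE", "inactive"))
  far <- tibble(chrom = "chr9", start = 1L, end = 50L)
  res <- overlap_enrichment(snps, far, "PRE", "inactive")
  expect_equal(res$p_value, 1)
  expect_true(is.na(res$odds_ratio))
  expect_error(overlap_enrichment(snps, far, "NRE", "inactive"), "test class")
})

test_that("planted peak enrichment is recovered by the overlap test", {
  set.seed(61)
  panel <- tibble(chrom = "chr1", pos = seq(1000L, by = 1000L, length.out = 2000),
                  snp_id = sprintf("s%04d", 1:2000), ref = "A", alt = "C",
                  maf = 0.2)
  truth <- tibble(snp_id = panel$snp_id,
                  class = c(rep("PRE", 200), rep("inactive", 1800)),
                  log2fc = 0, allelic_effect = 1)
  peaks <- simulate_annotations(panel, truth, target_or = 3,
                                baseline_rate = 0.04, seed = 10)
  snps <- mutate(panel[, c("snp_id", "chrom", "pos")], class = truth$class)
  res <- overlap_enrichment(snps, peaks, "PRE", "inactive")
  expect_true(res$ci_lower <= 3 && 3 <= res$ci_upper)
})

test_that("flat PWMs score zero and hand-computed deltas match", {
  flat <- new_pwm("flat", matrix(0.25, 4, 3), pseudocount = 0)
  panel <- tibble(chrom = "c", pos = 10L, snp_id = "s1", ref = "T", alt = "A",
                  maf = 0.1)
  genome <- Biostrings::DNAStringSet(c(c = strrep("C", 30)))
  res <- pwm_delta_scores(panel, genome, flat)
  expect_equal(res$ref_score, 0)
  expect_equal(res$alt_score, 0)
  expect_equal(res$delta, 0)

  # width-1 motif A:0.7 others 0.1, uniform background, no pseudocount,
  # forward strand: delta = log2(2.8) - log2(0.4) = log2(7)
  m1 <- new_pwm("m1", matrix(c(0.7, 0.1, 0.1, 0.1), 4, 1), pseudocount = 0)
  res1 <- pwm_delta_scores(panel, genome, m1, both_strands = FALSE)
  expect_equal(res1$delta, log2(7), tolerance = 1e-12)
  expect_equal(res1$ref_score, log2(0.4), tolerance = 1e-12)
  expect_equal(res1$alt_score, log2(2.8), tolerance = 1e-12)

  # antisymmetry under swapping ref and alt
  swapped <- mutate(panel, ref = "A", alt = "T")
  res2 <- pwm_delta_scores(swapped, genome, m1, both_strands = FALSE)
  expect_equal(res2$delta, -res1$delta)
})

test_that("strand handling scores a motif equally on its consensus and its reverse complement", {
  mat <- matrix(0.04, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  consensus <- c("A", "C", "G", "T")
  for (j in 1:4) mat[consensus[j], j] <- 0.88
  pwm <- new_pwm("cons", mat, pseudocount = 0.01)
  fwd <- paste(consensus, collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  mk_genome <- function(core) {
    Biostrings::DNAStringSet(c(g = paste0(strrep("A", 10), core, strrep("A", 10))))
  }
  panel <- tibble(chrom = "g", pos = 11L, snp_id = "s", ref = "A", alt = "A",
                  maf = 0.1)
  panel$alt <- "C"  # alt unused; ref base matches the planted consensus start
  s_fwd <- pwm_delta_scores(panel, mk_genome(fwd), pwm)$ref_score
  s_rc <- pwm_delta_scores(panel, mk_genome(rc), pwm)$ref_score
  # scoring the reverse complement on both strands recovers the same maximum
  expect_equal(s_fwd, s_rc, tolerance = 1e-9)
  # and the per-position sum recomputed independently matches
  p <- sweep(mat + 0.01, 2, colSums(mat + 0.01), "/")
  manual <- sum(log2(p[cbind(match(consensus, rownames(p)), 1:4)] / 0.25))
  expect_equal(s_fwd, manual, tolerance = 1e-9)
})

test_that("SNPs at contig edges are skipped with a warning", {
  m <- new_pwm("m", matrix(c(0.7, 0.1, 0.1, 0.1), 4, 2))
  panel <- tibble(chrom = "c", pos = 1L, snp_id = "edge", ref = "A", alt = "C",
                  maf = 0.1)
  genome <- Biostrings::DNAStringSet(c(c = "ACGTACGT"))
  expect_warning(res <- pwm_delta_scores(panel, genome, m), "bounds")
  expect_equal(nrow(res), 0L)
})

test_that("the delta >= 3 rule and class comparisons drive delta enrichment", {
  deltas <- tibble(snp_id = c("r1", "r2", "a1", "i1", "i2"),
                   motif_id = "m",
                   ref_score = 0, alt_score = 0,
                   delta = c(3.2, -3.5, 2.9, 0.2, 3.1))
  classes <- tibble(snp_id = c("r1", "r2", "a1", "i1", "i2"),
                    class = c("regulatory", "regulatory",
                              "active_nonregulatory", "inactive", "inactive"))
  res <- delta_enrichment(deltas, classes, threshold = 3)
  expect_equal(nrow(res), 2L)
  ra <- filter(res, reference_class == "active_nonregulatory")
  expect_equal(ra$test_in, 2)   # both regulatory SNPs pass |delta| >= 3
  expect_equal(ra$ref_in, 0)    # 2.9 does not
  ri <- filter(res, reference_class == "inactive")
  expect_equal(ri$ref_in, 1)    # 3.1 does
  # all-zero deltas: nothing disrupts, zero-margin handling gives p = 1
  none <- mutate(deltas, delta = 0)
  res0 <- delta_enrichment(none, classes, threshold = 3)
  expect_true(all(res0$p_value == 1))
  expect_error(delta_enrichment(deltas, mutate(classes, class = "inactive")),
               "regulatory")
})

test_that("planted motif disruption enrichment is recovered end to end", {
  set.seed(77)
  n_reg <- 150
  n_act <- 300
  n_inact <- 1500
  ids <- c(sprintf("r%03d", 1:n_reg), sprintf("a%03d", 1:n_act),
           sprintf("i%04d", 1:n_inact))
  cls <- c(rep("regulatory", n_reg), rep("active_nonregulatory", n_act),
           rep("inactive", n_inact))
  # plant disruption with 5x higher odds among regulatory SNPs
  p_in <- 0.08
  odds <- p_in / (1 - p_in) * 5
  p_reg <- odds / (1 + odds)
  disrupt <- runif(length(cls)) < ifelse(cls == "regulatory", p_reg, p_in)
  deltas <- tibble(snp_id = ids, motif_id = "m", ref_score = 0,
                   alt_score = 0, delta = ifelse(disrupt, 4, 1))
  res <- delta_enrichment(deltas, tibble(snp_id = ids, class = cls)) |>
    filter(reference_class == "inactive")
  expect_true(res$ci_lower <= 5 && 5 <= res$ci_upper)
})

test_that("MEME motif files round-trip through the reader", {
  pwms <- list(
    new_pwm("motifA", matrix(c(0.7, 0.1, 0.1, 0.1,
                               0.25, 0.25, 0.25, 0.25), 4, 2)),
    new_pwm("motifB", matrix(runif(12, 0.1, 1), 4, 3))
  )
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, path)
  back <- read_meme(path)
  expect_equal(names(back), c("motifA", "motifB"))
  expect_equal(back$motifA$mat, pwms[[1]]$mat, tolerance = 1e-5)
  expect_equal(back$motifB$mat, pwms[[2]]$mat, tolerance = 1e-5)
  expect_equal(back$motifA$bg, c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
})
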