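lib4 <- c("input_1", "input_2", "output_1", "output_2")
unit_sf <- tibble(library = lib4, size_factor = 1)

test_that("median-of-ratios size factors match hand computation", {
  two_col <- tibble(snp_id = c("a", "b", "c"),
                    input_1 = c(10, 100, 50), output_1 = c(20, 200, 100))
  sf <- size_factors_median_of_ratios(two_col)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- tibble(snp_id = c("a", "b"), input_1 = c(5, 9), output_1 = c(5, 9))
  expect_equal(size_factors_median_of_ratios(same)$size_factor, c(1, 1))

  # scale equivariance: multiplying one column by c multiplies its factor
  scaled <- two_col
  scaled$output_1 <- scaled$output_1 * 5
  sf2 <- size_factors_median_of_ratios(scaled)
  ratio <- sf2$size_factor / sf$size_factor
  # geometric means change too, so compare factor ratios up to common scale
  expect_equal(ratio[2] / ratio[1], 5, tolerance = 1e-12)

  allzero <- tibble(snp_id = "a", input_1 = 0, output_1 = 3)
  expect_error(size_factors_median_of_ratios(allzero), "all-positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  ds <- simulate_dataset(tiny_config(seed = 31), emit_fragments = FALSE)
  counts <- ds$counts
  counts$output_1 <- counts$output_1 * 3L  # force unequal depths
  mine <- size_factors_median_of_ratios(counts)$size_factor
  K <- as.matrix(counts[, lib4])
  ref <- DESeq2::estimateSizeFactorsForMatrix(K)
  expect_equal(mine, unname(ref), tolerance = 1e-10)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # hand step-up: sorted p scaled by m/rank, then running minimum from the top
  hand <- rev(cummin(rev(sort(p) * 10 / (1:10))))
  expect_equal(bh_adjust(p), pmin(1, hand)[rank(p)])
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(-0.1)), "0, 1")
})

test_that("identical input and output counts give a null fold change", {
  counts <- tibble(snp_id = sprintf("r%d", 1:3),
                   input_1 = c(500, 480, 520), input_2 = c(500, 480, 520),
                   output_1 = c(500, 480, 520), output_2 = c(500, 480, 520))
  res <- nb_wald_lfc(counts, unit_sf, dispersion = 0.01)
  expect_true(all(abs(res$log2FC) < 0.05))
  expect_true(all(res$pvalue > 0.5))
})

test_that("vanishing dispersion reproduces the Poisson GLM oracle", {
  set.seed(42)
  sf <- c(0.8, 1.1, 0.95, 1.3)
  counts <- tibble(snp_id = sprintf("r%d", 1:20),
                   input_1 = rpois(20, 200 * sf[1]),
                   input_2 = rpois(20, 200 * sf[2]),
                   output_1 = rpois(20, 380 * sf[3]),
                   output_2 = rpois(20, 380 * sf[4]))
  sft <- tibble(library = lib4, size_factor = sf)
  res <- nb_wald_lfc(counts, sft, dispersion = 1e-12)
  x <- c(0, 0, 1, 1)
  for (i in c(1, 7, 20)) {
    k <- as.numeric(counts[i, lib4])
    fit <- glm(k ~ x, family = poisson(), offset = log(sf))
    sm <- summary(fit)$coefficients
    expect_equal(res$log2FC[i], sm["x", "Estimate"] / log(2), tolerance = 1e-3)
    expect_equal(res$pvalue[i],
                 2 * pnorm(-abs(sm["x", "Estimate"] / sm["x", "Std. Error"])),
                 tolerance = 1e-3)
  }
})

test_that("the fold-change estimator is unbiased with oracle-consistent spread", {
  # Monte-Carlo oracle at lambda = 500, dispersion 0.01, 2+2 replicates.
  # The Fisher-information bound on the estimator sd is
  # sqrt((1/500 + 0.01)/2 + (1/1000 + 0.01)/2) / ln 2 ~= 0.155 log2 units,
  # so the estimate cannot concentrate more tightly than that.
  set.seed(1234)
  info_sd <- sqrt((1 / 500 + 0.01) / 2 + (1 / 1000 + 0.01) / 2) / log(2)
  ests <- replicate(200, {
    counts <- tibble(snp_id = "r1",
                     input_1 = rnbinom(1, mu = 500, size = 100),
                     input_2 = rnbinom(1, mu = 500, size = 100),
                     output_1 = rnbinom(1, mu = 1000, size = 100),
                     output_2 = rnbinom(1, mu = 1000, size = 100))
    nb_wald_lfc(counts, unit_sf, dispersion = 0.01)$log2FC
  })
  expect_lt(abs(mean(ests) - 1), 3 * sd(ests) / sqrt(200))
  expect_lt(abs(sd(ests) - info_sd), 0.25 * info_sd)
})

test_that("all-zero regions are reported missing and later filtered", {
  counts <- tibble(snp_id = c("dead", "live"),
                   input_1 = c(0, 300), input_2 = c(0, 310),
                   output_1 = c(0, 290), output_2 = c(0, 305))
  res <- nb_wald_lfc(counts, unit_sf, dispersion = 0.01)
  expect_true(is.na(res$log2FC[1]) && is.na(res$pvalue[1]))
  cls <- classify_elements(res)
  expect_equal(cls$class[1], "filtered")
})

test_that("classification follows the FDR and sign rules", {
  res <- tibble(snp_id = c("a", "b", "c", "d"),
                baseMean = c(100, 100, 100, 5),
                log2FC = c(1, -1, 0.5, 2),
                SE = 0.1, stat = 0,
                pvalue = c(0.0002, 0.0002, 0.9, 0.0001))
  out <- classify_elements(res, fdr_alpha = 0.01, min_base_mean = 10)
  expect_equal(out$class, c("PRE", "NRE", "inactive", "filtered"))
  # the filtered region is excluded from the BH burden (m = 3, not 4)
  expect_equal(out$padj[1], bh_adjust(c(0.0002, 0.0002, 0.9))[1])
  expect_true(is.na(out$padj[4]))
  expect_true(all(out$padj >= out$pvalue, na.rm = TRUE))
})

test_that("called fold changes track DESeq2 on a simulated screen", {
  cfg <- sim_config(n_tag_snps = 40, linked_per_tag = 4,
                    fragments_per_region = 300, pre_fraction = 0.1,
                    nre_fraction = 0.1, regsnp_fraction = 0, seed = 17)
  ds <- simulate_dataset(cfg, emit_fragments = FALSE)
  mine <- nb_wald_lfc(ds$counts)
  K <- as.matrix(ds$counts[, lib4])
  rownames(K) <- ds$counts$snp_id
  cd <- data.frame(condition = factor(c("input", "input", "output", "output"),
                                      levels = c("input", "output")))
  dds <- DESeq2::DESeqDataSetFromMatrix(K, cd, ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  expect_gt(cor(mine$log2FC, ref$log2FoldChange), 0.98)
  planted <- ds$truth$class != "inactive"
  expect_gt(cor(mine$log2FC[planted], ds$truth$log2fc[planted]), 0.9)
})
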