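# Design-stage coverage simulation: how many pooled individuals are needed
# for both alleles of each panel SNP to be represented in the captured DNA.

#' Simulated both-allele coverage curve
#'
#' For each pool size `i`, draws `i` individuals from the genotype pool
#' uniformly without replacement and counts the panel SNPs whose sampled
#' genotypes carry at least one reference and one alternative allele;
#' the covered fraction is that count over the panel size. Sampling is
#' repeated to report a mean and standard deviation per size.
#'
#' @param pool Genotype dosage matrix (individuals x SNPs, values 0/1/2).
#' @param sizes Integer vector of pool sizes `i`; each must be at most the
#'   number of individuals in `pool`.
#' @param repeats Random samplings per size.
#' @param seed Optional integer seed.
#' @param panel_size Denominator for the covered fraction; defaults to the
#'   number of pool columns (set it to the designed panel size when the pool
#'   covers only part of the panel).
#' @return A `starr_coverage` tibble: `i`, `mean_p`, `sd_p`, `repeats`.
#' @export
coverage_curve <- function(pool, sizes, repeats = 5L, seed = NULL,
                           panel_size = ncol(pool)) {
  validate_pool(pool)
  check_number(repeats, "repeats", lower = 1, integerish = TRUE)
  check_number(panel_size, "panel_size", lower = 1, integerish = TRUE)
  if (any(sizes < 1L) || any(sizes != round(sizes))) {
    abort("`sizes` must be positive whole numbers.")
  }
  if (max(sizes) > nrow(pool)) {
    abort(sprintf("pool has %d individuals; cannot sample %d without replacement.",
                  nrow(pool), max(sizes)))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- purrr::map_dfr(sizes, function(i) {
    p <- vapply(seq_len(repeats), function(r) {
      idx <- sample.int(nrow(pool), i)
      s <- colSums(pool[idx, , drop = FALSE])
      sum(s >= 1L & s <= 2L * i - 1L) / panel_size
    }, numeric(1))
    tibble(i = as.integer(i), mean_p = mean(p),
           sd_p = if (repeats > 1L) stats::sd(p) else 0,
           repeats = as.integer(repeats))
  })
  structure(res, class = c("starr_coverage", class(res)))
}

#' Closed-form both-allele coverage probability under HWE
#'
#' With alternative-allele frequency `f` and `i` diploid individuals drawn
#' with replacement from a Hardy-Weinberg population, the probability that
#' both alleles appear among the `2i` sampled chromosomes is
#' `1 - (1 - f)^(2i) - f^(2i)`. Used as the analytic check for
#' [coverage_curve()] on pools much larger than `i`.
#'
#' @param maf Allele frequency in `[0, 1]` (vectorized).
#' @param i Number of individuals (vectorized).
#' @return Coverage probabilities.
#' @export
analytic_coverage <- function(maf, i) {
  if (any(maf < 0 | maf > 1)) abort("`maf` must lie in [0, 1].")
  if (any(i < 1)) abort("`i` must be at least 1.")
  1 - (1 - maf)^(2 * i) - maf^(2 * i)
}
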