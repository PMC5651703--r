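# Allelic-imbalance analysis: normalize and pool per-SNP allele counts
# across replicates, compute the ratio-of-ratios effect size, and test each
# SNP's allele ratio shift with the two-sided Fisher exact test (conditional
# maximum-likelihood odds ratio), controlling FDR at 10%.

#' Normalize, pool and filter per-SNP allele counts
#'
#' Each replicate library's allele counts are rescaled by a per-library
#' normalization constant and summed across replicates within condition.
#' With `normalize = "depth"` (default) the constant equalizes total library
#' depth (counts scaled by mean depth / library depth), which preserves
#' within-SNP allele ratios and makes the pooled-count filter comparable
#' across libraries; `normalize = "snp"` instead equalizes each SNP's
#' coverage across libraries. SNPs with any pooled normalized ref or alt
#' count below `min_pooled` are dropped (reported in the
#' `"starr_pool_stats"` attribute).
#'
#' @param allele_counts Long allele count tibble (`snp_id`, `library`,
#'   `condition`, `replicate`, `ref_count`, `alt_count`).
#' @param library_depths Optional tibble (`library`, `depth`); defaults to
#'   each library's total ref + alt count. A zero depth is an error.
#' @param min_pooled Minimum pooled normalized count required for both
#'   alleles in both conditions.
#' @param normalize `"depth"` or `"snp"` (see above).
#' @return A tibble with `snp_id`, `in_ref`, `in_alt`, `out_ref`, `out_alt`
#'   (pooled normalized counts).
#' @export
pooled_allele_table <- function(allele_counts, library_depths = NULL,
                                min_pooled = 10, normalize = c("depth", "snp")) {
  check_columns(allele_counts,
                c("snp_id", "library", "condition", "ref_count", "alt_count"),
                "allele_counts")
  normalize <- match.arg(normalize)
  check_number(min_pooled, "min_pooled", lower = 0)
  ac <- as_tibble(allele_counts)

  if (normalize == "depth") {
    if (is.null(library_depths)) {
      library_depths <- ac |>
        dplyr::group_by(.data$library) |>
        dplyr::summarise(depth = sum(.data$ref_count + .data$alt_count),
                         .groups = "drop")
    }
    check_columns(library_depths, c("library", "depth"), "library_depths")
    if (any(library_depths$depth <= 0)) {
      abort("library depth must be positive for every library.")
    }
    scale <- mean(library_depths$depth) / library_depths$depth
    ac <- ac |>
      dplyr::mutate(scale = scale[match(.data$library, library_depths$library)])
    if (any(is.na(ac$scale))) abort("`library_depths` must cover every library.")
  } else {
    # per-SNP coverage rescaling: equalize each SNP's coverage across libraries
    cov <- ac |>
      dplyr::group_by(.data$snp_id) |>
      dplyr::mutate(snp_cov = .data$ref_count + .data$alt_count,
                    snp_mean = mean(.data$snp_cov)) |>
      dplyr::ungroup()
    ac <- cov |>
      dplyr::mutate(scale = ifelse(.data$snp_cov > 0,
                                   .data$snp_mean / .data$snp_cov, 0))
  }

  pooled <- ac |>
    dplyr::mutate(ref_n = .data$ref_count * .data$scale,
                  alt_n = .data$alt_count * .data$scale) |>
    dplyr::group_by(.data$snp_id, .data$condition) |>
    dplyr::summarise(ref = sum(.data$ref_n), alt = sum(.data$alt_n),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = c("ref", "alt"),
                       names_glue = "{condition}_{.value}") |>
    dplyr::select("snp_id", in_ref = "input_ref", in_alt = "input_alt",
                  out_ref = "output_ref", out_alt = "output_alt")

  keep <- pooled$in_ref >= min_pooled & pooled$in_alt >= min_pooled &
    pooled$out_ref >= min_pooled & pooled$out_alt >= min_pooled
  out <- pooled[keep, , drop = FALSE]
  attr(out, "starr_pool_stats") <- c(snps_in = nrow(pooled),
                                     excluded_low_count = sum(!keep),
                                     snps_kept = sum(keep))
  out
}

#' Two-sided Fisher exact test with conditional-MLE odds ratio
#'
#' For a 2x2 table of non-negative integers, the two-sided p value sums the
#' probabilities of all tables (under the hypergeometric null, margins
#' fixed) no more probable than the observed one, and the odds ratio is the
#' conditional maximum-likelihood estimate under the noncentral
#' hypergeometric likelihood, with a 95% confidence interval from
#' likelihood inversion. A table with a zero margin carries no information:
#' p is 1 and the odds ratio is reported missing.
#'
#' @param table A 2x2 matrix of non-negative integers, or a length-4 vector
#'   `(n11, n12, n21, n22)` filled by row.
#' @param conf_int Compute the 95% confidence interval (skipping it speeds
#'   up large batch runs).
#' @return A one-row tibble: `p_value`, `odds_ratio`, `ci_lower`, `ci_upper`.
#' @export
fisher_exact_cmle <- function(table, conf_int = TRUE) {
  if (is.vector(table) && length(table) == 4L) {
    table <- matrix(table, 2, 2, byrow = TRUE)
  }
  if (!is.matrix(table) || !all(dim(table) == c(2L, 2L))) {
    abort("`table` must be a 2x2 matrix or a length-4 vector.")
  }
  if (any(table < 0) || any(table != round(table))) {
    abort("`table` cells must be non-negative integers.")
  }
  storage.mode(table) <- "integer"
  if (any(rowSums(table) == 0L) || any(colSums(table) == 0L)) {
    return(tibble(p_value = 1, odds_ratio = NA_real_,
                  ci_lower = NA_real_, ci_upper = NA_real_))
  }
  ft <- fisher.test(table, conf.int = conf_int)
  tibble(
    # guard against p marginally above 1 from floating-point summation
    p_value = min(1, ft$p.value),
    odds_ratio = unname(ft$estimate),
    ci_lower = if (conf_int) ft$conf.int[1] else NA_real_,
    ci_upper = if (conf_int) ft$conf.int[2] else NA_real_
  )
}

#' Test SNPs for allelic imbalance between output and input libraries
#'
#' For each SNP in the pooled table, the effect size is the fold change of
#' allele ratios, `(out_alt / out_ref) / (in_alt / in_ref)`; significance
#' comes from [fisher_exact_cmle()] on the pooled counts (rounded
#' half-to-even, since the exact test needs integers) arranged as alleles x
#' condition. p values are BH-adjusted across all tested SNPs and the
#' regulatory flag is set at adjusted p below `fdr_alpha`. When an activity
#' result is supplied, each SNP is annotated with its host element class
#' (`PRE`, `NRE`, `inactive`, `filtered`, or `untested` if absent).
#'
#' @param pooled Pooled allele table from [pooled_allele_table()].
#' @param activity Optional `starr_activity` tibble for host-class
#'   annotation.
#' @param fdr_alpha FDR threshold for the regulatory flag.
#' @return A `starr_allelic` tibble: pooled counts, `effect_size` (and its
#'   reciprocal `effect_size_ref`), `p_value`, `padj`, `regulatory`,
#'   `host_class`.
#' @export
allelic_test <- function(pooled, activity = NULL, fdr_alpha = 0.1) {
  check_columns(pooled, c("snp_id", "in_ref", "in_alt", "out_ref", "out_alt"),
                "pooled")
  check_number(fdr_alpha, "fdr_alpha", lower = 0, upper = 1)
  pooled <- as_tibble(pooled)
  effect <- (pooled$out_alt / pooled$out_ref) / (pooled$in_alt / pooled$in_ref)
  p <- purrr::pmap_dbl(
    list(pooled$in_ref, pooled$in_alt, pooled$out_ref, pooled$out_alt),
    function(ir, ia, or_, oa) {
      tab <- matrix(round(c(ir, or_, ia, oa)), 2, 2, byrow = TRUE)
      fisher_exact_cmle(tab, conf_int = FALSE)$p_value
    }
  )
  padj <- bh_adjust(p)
  host <- rep("untested", nrow(pooled))
  if (!is.null(activity)) {
    check_columns(activity, c("snp_id", "class"), "activity")
    m <- match(pooled$snp_id, activity$snp_id)
    host[!is.na(m)] <- activity$class[m[!is.na(m)]]
  }
  out <- dplyr::mutate(
    pooled,
    effect_size = effect,
    effect_size_ref = 1 / effect,
    p_value = p,
    padj = padj,
    regulatory = !is.na(padj) & padj < fdr_alpha,
    host_class = host
  )
  structure(out, class = c("starr_allelic", class(out)), fdr_alpha = fdr_alpha)
}

#' @method glance starr_allelic
#' @export
glance.starr_allelic <- function(x, ...) {
  tibble(
    snps_tested = nrow(x),
    regulatory = sum(x$regulatory),
    regulatory_in_pre = sum(x$regulatory & x$host_class == "PRE"),
    regulatory_in_nre = sum(x$regulatory & x$host_class == "NRE"),
    fdr_alpha = attr(x, "fdr_alpha")
  )
}
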