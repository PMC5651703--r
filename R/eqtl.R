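# Two-step eQTL regression: residualize expression on somatic copy number
# and promoter methylation, then regress the residuals on genotype dosage.

#' Two-step residualizing eQTL fit
#'
#' Step 1 fits ordinary least squares `E ~ C + M` (with intercept) and takes
#' the residuals; step 2 regresses those residuals on the genotype dosage
#' `G` (with intercept). The genotype effect, its standard error, t
#' statistic and p value come from step 2. Rows with any missing value are
#' dropped (listwise deletion) and counted.
#'
#' @param data Tibble with per-sample columns `E` (expression), `C` (somatic
#'   copy number), `M` (promoter methylation) and `G` (genotype dosage,
#'   0/1/2 under the default additive coding).
#' @param tail `"two-sided"` (default), `"greater"` or `"less"` for the
#'   step-2 genotype test.
#' @param genotype_mode `"additive"` regresses on the dosage; `"group"`
#'   contrasts carriers (`G > 0`) against non-carriers, the group-mean mode.
#' @return A `starr_eqtl` object; see [tidy.starr_eqtl()] and
#'   [glance.starr_eqtl()].
#' @export
fit_two_step <- function(data, tail = c("two-sided", "greater", "less"),
                         genotype_mode = c("additive", "group")) {
  check_columns(data, c("E", "C", "M", "G"), "data")
  tail <- match.arg(tail)
  genotype_mode <- match.arg(genotype_mode)
  complete <- stats::complete.cases(data[, c("E", "C", "M", "G")])
  n_dropped <- sum(!complete)
  d <- as_tibble(data)[complete, ]
  if (nrow(d) < 4L) abort("At least 4 complete observations are required.")
  g <- if (genotype_mode == "group") as.numeric(d$G > 0) else as.numeric(d$G)
  if (length(unique(g)) < 2L) abort("no genotype variance: `G` is constant.")

  step1 <- lm(E ~ C + M, data = d)
  if (step1$rank < 3L) abort("step-1 design is rank deficient.")
  eps <- residuals(step1)
  step2 <- lm(eps ~ g)
  if (step2$rank < 2L) abort("step-2 design is rank deficient.")
  sm <- summary(step2)$coefficients
  est <- sm["g", "Estimate"]
  se <- sm["g", "Std. Error"]
  tval <- sm["g", "t value"]
  df <- step2$df.residual
  p <- switch(tail,
              "two-sided" = 2 * pt(-abs(tval), df),
              "greater" = pt(tval, df, lower.tail = FALSE),
              "less" = pt(tval, df))
  structure(list(
    step1 = step1, step2 = step2, residuals = eps,
    estimate = est, se = se, statistic = tval, df = df, p_value = p,
    tail = tail, genotype_mode = genotype_mode,
    n_used = nrow(d), n_dropped = n_dropped
  ), class = "starr_eqtl")
}

#' @export
print.starr_eqtl <- function(x, ...) {
  cat("Two-step eQTL fit\n")
  cat(sprintf("  n = %d (%d dropped), genotype coding: %s\n",
              x$n_used, x$n_dropped, x$genotype_mode))
  cat(sprintf("  genotype effect = %.4g (SE %.4g), t = %.3f, p = %.4g [%s]\n",
              x$estimate, x$se, x$statistic, x$p_value, x$tail))
  invisible(x)
}

#' Tidy a two-step eQTL fit
#'
#' One row per coefficient of both regression steps.
#'
#' @param x A `starr_eqtl` object.
#' @param ... Unused.
#' @return A tibble: `step`, `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy starr_eqtl
#' @export
tidy.starr_eqtl <- function(x, ...) {
  grab <- function(fit, step) {
    sm <- summary(fit)$coefficients
    tibble(step = step, term = rownames(sm), estimate = sm[, 1],
           std.error = sm[, 2], statistic = sm[, 3], p.value = sm[, 4])
  }
  dplyr::bind_rows(grab(x$step1, "covariates"), grab(x$step2, "genotype"))
}

#' Summarize a two-step eQTL fit in one row
#'
#' @param x A `starr_eqtl` object.
#' @param ... Unused.
#' @return A one-row tibble with the genotype effect, its test, sample
#'   counts and the two R-squared values.
#' @method glance starr_eqtl
#' @export
glance.starr_eqtl <- function(x, ...) {
  tibble(
    estimate = x$estimate, std.error = x$se, statistic = x$statistic,
    p.value = x$p_value, df = x$df,
    r.squared.step1 = summary(x$step1)$r.squared,
    r.squared.step2 = summary(x$step2)$r.squared,
    nobs = x$n_used, n_dropped = x$n_dropped, tail = x$tail
  )
}
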