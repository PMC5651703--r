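# Synthetic-screen generator: builds a complete reporter screen (panel,
# diploid genotype pool, fragments, input/output count libraries, annotation
# peaks) with recorded ground truth so every downstream stage can be tested
# for parameter recovery without any external data.

#' Configuration for a synthetic reporter screen
#'
#' Defaults emulate the design of a pooled-capture STARR-seq screen: ~465-bp
#' fragments captured around each target SNP from a pool of ten diploid
#' individuals, two replicate input and output libraries, region activities
#' inside a 0.5- to 16-fold range, and a small fraction of SNPs with a
#' planted allelic effect.
#'
#' @param n_tag_snps Number of tag SNPs.
#' @param linked_per_tag Linked SNPs simulated per tag SNP (the panel has
#'   `n_tag_snps * (1 + linked_per_tag)` SNPs, one region each).
#' @param n_individuals Diploid individuals in the genotype pool.
#' @param maf_range Uniform range for the panel minor-allele frequency.
#' @param fragments_per_region Mean fragment count per SNP region per library.
#' @param fragment_length_mean,fragment_length_sd Fragment length distribution
#'   (bp), truncated to `[400, 600]`.
#' @param pre_fraction,nre_fraction Fractions of regions planted as positive /
#'   negative regulatory elements; their sum must be at most 1.
#' @param activity_fold_range Fold-change interval spanned by planted
#'   activities (default `c(0.5, 16)`). PRE folds are drawn log-uniformly from
#'   `[max(1.25, lo), hi]`, NRE folds from `[lo, min(0.8, hi)]`; pass
#'   `pre_log2fc_range` / `nre_log2fc_range` to plant exact effects.
#' @param pre_log2fc_range,nre_log2fc_range Optional explicit log2 fold-change
#'   intervals overriding the derivation from `activity_fold_range`.
#' @param regsnp_fraction Fraction of panel SNPs given a planted allelic
#'   effect (assigned among SNPs polymorphic in the sampled pool).
#' @param allelic_effect_range Fold-change interval for the planted allelic
#'   effect on the alt/ref ratio (drawn log-uniformly; inverted with
#'   probability 1/2 so both directions occur).
#' @param nb_dispersion Negative-binomial dispersion of library counts
#'   (variance = mu + dispersion * mu^2); `0` gives Poisson counts.
#' @param replicates Replicate libraries per condition.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A validated `starr_sim_config` list.
#' @export
sim_config <- function(n_tag_snps = 20,
                       linked_per_tag = 9,
                       n_individuals = 10,
                       maf_range = c(0.05, 0.5),
                       fragments_per_region = 200,
                       fragment_length_mean = 465,
                       fragment_length_sd = 30,
                       pre_fraction = 0.075,
                       nre_fraction = 0.1,
                       activity_fold_range = c(0.5, 16),
                       pre_log2fc_range = NULL,
                       nre_log2fc_range = NULL,
                       regsnp_fraction = 0.01,
                       allelic_effect_range = c(1.5, 3),
                       nb_dispersion = 0.02,
                       replicates = 2,
                       seed = 1) {
  check_number(n_tag_snps, "n_tag_snps", lower = 1, integerish = TRUE)
  check_number(linked_per_tag, "linked_per_tag", lower = 0, integerish = TRUE)
  check_number(n_individuals, "n_individuals", lower = 1, integerish = TRUE)
  check_number(fragments_per_region, "fragments_per_region", lower = 1)
  check_number(fragment_length_mean, "fragment_length_mean", lower = 400, upper = 600)
  check_number(fragment_length_sd, "fragment_length_sd", lower = 0)
  check_number(pre_fraction, "pre_fraction", lower = 0, upper = 1)
  check_number(nre_fraction, "nre_fraction", lower = 0, upper = 1)
  check_number(regsnp_fraction, "regsnp_fraction", lower = 0, upper = 1)
  check_number(nb_dispersion, "nb_dispersion", lower = 0)
  check_number(replicates, "replicates", lower = 1, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  if (pre_fraction + nre_fraction > 1) {
    abort("pre_fraction + nre_fraction must be <= 1.")
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing interval within (0, 0.5].")
  }
  if (length(activity_fold_range) != 2L || any(activity_fold_range <= 0) ||
      activity_fold_range[1] > activity_fold_range[2]) {
    abort("`activity_fold_range` must be a positive increasing interval.")
  }
  if (length(allelic_effect_range) != 2L || any(allelic_effect_range <= 0) ||
      allelic_effect_range[1] > allelic_effect_range[2]) {
    abort("`allelic_effect_range` must be a positive increasing interval.")
  }
  lo <- activity_fold_range[1]
  hi <- activity_fold_range[2]
  if (is.null(pre_log2fc_range)) {
    pre_log2fc_range <- log2(c(max(1.25, lo), max(1.25, hi)))
  }
  if (is.null(nre_log2fc_range)) {
    nre_log2fc_range <- log2(c(min(0.8, lo), min(0.8, hi)))
  }
  structure(list(
    n_tag_snps = as.integer(n_tag_snps),
    linked_per_tag = as.integer(linked_per_tag),
    n_individuals = as.integer(n_individuals),
    maf_range = maf_range,
    fragments_per_region = fragments_per_region,
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    pre_fraction = pre_fraction,
    nre_fraction = nre_fraction,
    activity_fold_range = activity_fold_range,
    pre_log2fc_range = pre_log2fc_range,
    nre_log2fc_range = nre_log2fc_range,
    regsnp_fraction = regsnp_fraction,
    allelic_effect_range = allelic_effect_range,
    nb_dispersion = nb_dispersion,
    replicates = as.integer(replicates),
    seed = as.integer(seed)
  ), class = "starr_sim_config")
}

# Library noise: one gamma factor per region x library (mean 1, variance =
# dispersion) shared by both alleles, with Poisson counts around it. Each
# allele count is then marginally NB(mu, dispersion), while the allele split
# given the region total stays binomial -- the distribution implied by
# sampling each fragment's allele from a pool chromosome. Dispersion 0
# degenerates to plain Poisson.
rgamma_factor <- function(n, dispersion) {
  if (dispersion <= 0) return(rep(1, n))
  stats::rgamma(n, shape = 1 / dispersion, rate = 1 / dispersion)
}

snp_spacing <- 5000L

#' Simulate a complete reporter screen with known ground truth
#'
#' Generates, from one seed: a target-SNP panel (tag + linked SNPs), a
#' diploid genotype pool drawn under Hardy-Weinberg equilibrium, per-library
#' negative-binomial fragment counts at region x allele x replicate
#' resolution, optional per-fragment records consistent with those counts,
#' and a truth table of planted region activities and allelic effects.
#'
#' Output means follow input means times the region's activity fold change;
#' a planted allelic effect multiplies the output mean of alt-allele
#' fragments, matching the ratio-of-ratios effect-size definition used by
#' [allelic_test()]. Allelic effects are planted only at SNPs whose sampled
#' pool carries both alleles (an effect at a monomorphic SNP would be
#' unobservable ground truth).
#'
#' @param config A [sim_config()] object.
#' @param emit_fragments Generate per-fragment records (one per counted
#'   fragment, tiling each SNP's +/-250 bp region with the SNP covered).
#'   Disable for large screens where only the count tables are needed.
#' @param emit_genome Generate a synthetic genome sequence whose base at each
#'   panel position equals the panel reference allele (needed for PWM and SAM
#'   round-trips).
#' @return A `starr_dataset` list: `panel`, `pool`, `truth`, `counts` (wide
#'   region-by-library tibble), `allele_counts` (long per-SNP tibble),
#'   `fragments` (or `NULL`), `genome` (or `NULL`), `config`.
#' @export
simulate_dataset <- function(config = sim_config(), emit_fragments = TRUE,
                             emit_genome = FALSE) {
  if (!inherits(config, "starr_sim_config")) {
    abort("`config` must be created with sim_config().")
  }
  set.seed(config$seed)
  n_snps <- config$n_tag_snps * (1L + config$linked_per_tag)
  snp_id <- sprintf("snp%05d", seq_len(n_snps))
  tag_id <- sprintf("tag%04d", rep(seq_len(config$n_tag_snps),
                                   each = 1L + config$linked_per_tag))
  is_tag <- rep(c(TRUE, rep(FALSE, config$linked_per_tag)), config$n_tag_snps)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  panel <- tibble(
    chrom = "chrSim",
    pos = 2500L + (seq_len(n_snps) - 1L) * snp_spacing,
    snp_id = snp_id, ref = unname(ref), alt = unname(alt),
    maf = runif(n_snps, config$maf_range[1], config$maf_range[2]),
    tag_id = tag_id, is_tag = is_tag
  )

  # HWE diploid pool: dosage ~ Binomial(2, maf), SNPs independent (no LD).
  pool <- matrix(
    rbinom(config$n_individuals * n_snps, 2L, rep(panel$maf, each = config$n_individuals)),
    nrow = config$n_individuals, ncol = n_snps,
    dimnames = list(sprintf("ind%03d", seq_len(config$n_individuals)), snp_id)
  )
  h_alt <- colSums(pool) / (2 * config$n_individuals)

  # Region activity classes: exact counts forced by the configured fractions.
  n_pre <- round(config$pre_fraction * n_snps)
  n_nre <- round(config$nre_fraction * n_snps)
  classes <- rep("inactive", n_snps)
  active_idx <- sample.int(n_snps, n_pre + n_nre)
  classes[active_idx[seq_len(n_pre)]] <- "PRE"
  if (n_nre > 0) classes[active_idx[n_pre + seq_len(n_nre)]] <- "NRE"
  log2fc <- numeric(n_snps)
  log2fc[classes == "PRE"] <- runif(n_pre, config$pre_log2fc_range[1],
                                    config$pre_log2fc_range[2])
  log2fc[classes == "NRE"] <- runif(n_nre, config$nre_log2fc_range[1],
                                    config$nre_log2fc_range[2])

  # Allelic effects: planted among pool-polymorphic SNPs only.
  polymorphic <- h_alt > 0 & h_alt < 1
  n_reg <- min(round(config$regsnp_fraction * n_snps), sum(polymorphic))
  allelic_effect <- rep(1, n_snps)
  if (n_reg > 0) {
    reg_idx <- sample(which(polymorphic), n_reg)
    fold <- exp(runif(n_reg, log(config$allelic_effect_range[1]),
                      log(config$allelic_effect_range[2])))
    flip <- runif(n_reg) < 0.5
    fold[flip] <- 1 / fold[flip]
    allelic_effect[reg_idx] <- fold
  }
  truth <- tibble(snp_id = snp_id, class = classes, log2fc = log2fc,
                  allelic_effect = allelic_effect, pool_alt_freq = h_alt)

  # Counts at region x allele x replicate resolution.
  lam <- config$fragments_per_region
  act <- 2^log2fc
  libs <- c(paste0("input_", seq_len(config$replicates)),
            paste0("output_", seq_len(config$replicates)))
  allele_counts <- purrr::map_dfr(libs, function(lib) {
    is_out <- startsWith(lib, "output")
    mu_ref <- lam * (1 - h_alt) * (if (is_out) act else 1)
    mu_alt <- lam * h_alt * (if (is_out) act * allelic_effect else 1)
    u <- rgamma_factor(n_snps, config$nb_dispersion)
    tibble(
      snp_id = snp_id, library = lib,
      condition = lib_condition(lib), replicate = lib_replicate(lib),
      ref_count = stats::rpois(n_snps, u * mu_ref),
      alt_count = stats::rpois(n_snps, u * mu_alt),
      other_count = 0L, unknown_count = 0L
    )
  })
  counts <- allele_counts |>
    dplyr::mutate(total = .data$ref_count + .data$alt_count) |>
    dplyr::select("snp_id", "library", "total") |>
    tidyr::pivot_wider(names_from = "library", values_from = "total") |>
    dplyr::arrange(match(.data$snp_id, snp_id))

  fragments <- NULL
  if (emit_fragments) {
    long <- allele_counts |>
      tidyr::pivot_longer(c("ref_count", "alt_count"), names_to = "allele",
                          values_to = "n") |>
      dplyr::filter(.data$n > 0L) |>
      dplyr::mutate(allele = sub("_count$", "", .data$allele))
    idx <- rep(seq_len(nrow(long)), long$n)
    n_frag <- length(idx)
    pos <- panel$pos[match(long$snp_id[idx], panel$snp_id)]
    len <- pmin(600L, pmax(400L, as.integer(round(
      rnorm(n_frag, config$fragment_length_mean, config$fragment_length_sd)
    ))))
    # fragment must cover the SNP: 0-based start in [pos - len, pos - 1]
    start <- (pos - len) + as.integer(floor(runif(n_frag) * len))
    start <- pmax(start, 0L)
    base_tbl <- dplyr::select(panel, "snp_id", "ref", "alt")
    allele_base <- ifelse(long$allele[idx] == "ref",
                          base_tbl$ref[match(long$snp_id[idx], base_tbl$snp_id)],
                          base_tbl$alt[match(long$snp_id[idx], base_tbl$snp_id)])
    fragments <- tibble(
      fragment_id = sprintf("frag%08d", seq_len(n_frag)),
      library = long$library[idx],
      chrom = "chrSim",
      start = start, end = start + len, length = len,
      snp_id = long$snp_id[idx],
      base = allele_base, qual = 40L
    )
  }

  genome <- NULL
  if (emit_genome) {
    glen <- max(panel$pos) + 2500L
    seq_chars <- sample(bases, glen, replace = TRUE)
    seq_chars[panel$pos] <- panel$ref
    genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
    names(genome) <- "chrSim"
  }

  structure(list(panel = panel, pool = pool, truth = truth, counts = counts,
                 allele_counts = allele_counts, fragments = fragments,
                 genome = genome, config = config),
            class = "starr_dataset")
}

#' @export
print.starr_dataset <- function(x, ...) {
  cat("Synthetic reporter screen\n")
  cat(sprintf("  SNP regions: %d (%d PRE, %d NRE planted)\n",
              nrow(x$panel), sum(x$truth$class == "PRE"),
              sum(x$truth$class == "NRE")))
  cat(sprintf("  planted allelic effects: %d\n", sum(x$truth$allelic_effect != 1)))
  cat(sprintf("  pool: %d individuals; libraries: %s\n", nrow(x$pool),
              paste(setdiff(names(x$counts), "snp_id"), collapse = ", ")))
  cat(sprintf("  fragments: %s; genome: %s\n",
              if (is.null(x$fragments)) "not emitted" else
                format(dplyr::n_distinct(x$fragments$fragment_id)),
              if (is.null(x$genome)) "not emitted" else "emitted"))
  invisible(x)
}

#' Simulate annotation peaks with a planted enrichment
#'
#' Emits BED-style peaks such that SNPs in active regions (planted PRE or
#' NRE) fall inside a peak with `target_or` times the baseline odds of
#' inactive SNPs. Used to exercise [overlap_enrichment()] round-trips.
#'
#' @param panel Target-SNP panel tibble.
#' @param truth Truth table from [simulate_dataset()].
#' @param target_or Planted odds ratio (> 0); `1` plants no enrichment.
#' @param baseline_rate In-peak probability for inactive SNPs, in (0, 1).
#' @param seed Integer seed.
#' @param peak_width Peak width in bp.
#' @return A peaks tibble (`chrom`, `start`, `end`, `name`), 0-based
#'   half-open, each peak covering its SNP.
#' @export
simulate_annotations <- function(panel, truth, target_or, baseline_rate, seed,
                                 peak_width = 300L) {
  panel <- validate_panel(panel)
  check_number(target_or, "target_or", lower = .Machine$double.eps)
  check_number(baseline_rate, "baseline_rate")
  if (baseline_rate <= 0 || baseline_rate >= 1) {
    abort("`baseline_rate` must be strictly inside (0, 1).")
  }
  check_number(seed, "seed", integerish = TRUE)
  set.seed(seed)
  cls <- truth$class[match(panel$snp_id, truth$snp_id)]
  active <- cls %in% c("PRE", "NRE")
  base_odds <- baseline_rate / (1 - baseline_rate)
  p_active <- (target_or * base_odds) / (1 + target_or * base_odds)
  p <- ifelse(active, p_active, baseline_rate)
  in_peak <- runif(nrow(panel)) < p
  hits <- panel[in_peak, ]
  if (nrow(hits) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  offset <- as.integer(floor(runif(nrow(hits)) * peak_width))
  start <- pmax(0L, pos_to_zero(hits$pos) - offset)
  tibble(chrom = hits$chrom, start = start,
         end = start + as.integer(peak_width),
         name = paste0("peak_", hits$snp_id))
}
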