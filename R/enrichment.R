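# Annotation enrichment: SNP-in-peak overlap tests and PWM allele delta
# scoring with the >= 3 log-likelihood motif-disruption rule.

#' Which SNPs fall inside annotation peaks
#'
#' Point-in-interval overlap: a SNP overlaps a peak iff its (1-based)
#' position is covered by the (0-based half-open) peak interval.
#'
#' @param snps Tibble with `snp_id`, `chrom`, `pos` (1-based).
#' @param peaks Peaks tibble (`chrom`, `start`, `end`), 0-based half-open.
#' @return Logical vector along `snps` rows.
#' @export
snps_in_peaks <- function(snps, peaks) {
  check_columns(snps, c("snp_id", "chrom", "pos"), "snps")
  validate_peaks(peaks)
  if (nrow(peaks) == 0L) return(rep(FALSE, nrow(snps)))
  lvls <- union(unique(snps$chrom), unique(peaks$chrom))
  snp_gr <- GenomicRanges::GRanges(
    factor(snps$chrom, levels = lvls),
    IRanges::IRanges(start = snps$pos, width = 1L)
  )
  peak_gr <- GenomicRanges::GRanges(
    factor(peaks$chrom, levels = lvls),
    IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  GenomicRanges::countOverlaps(snp_gr, peak_gr) > 0L
}

#' Peak-overlap enrichment of one SNP class against another
#'
#' Builds the 2x2 table (in peak / not in peak) x (test class / reference
#' class) and tests it with [fisher_exact_cmle()]. The odds ratio is
#' oriented so values above 1 mean the test class overlaps peaks more often.
#'
#' @param snps Tibble with `snp_id`, `chrom`, `pos`, `class`.
#' @param peaks Peaks tibble, 0-based half-open.
#' @param test_class,reference_class Values of `snps$class` to compare; each
#'   may name several classes (their union is used). Empty classes are an
#'   error.
#' @return A one-row enrichment tibble: classes, the four counts
#'   (`test_in`, `test_out`, `ref_in`, `ref_out`), `odds_ratio`, CI and
#'   `p_value`.
#' @export
overlap_enrichment <- function(snps, peaks, test_class, reference_class) {
  check_columns(snps, c("snp_id", "chrom", "pos", "class"), "snps")
  in_peak <- snps_in_peaks(snps, peaks)
  test_i <- snps$class %in% test_class
  ref_i <- snps$class %in% reference_class
  if (!any(test_i)) abort(sprintf("No SNPs in test class '%s'.",
                                  paste(test_class, collapse = "+")))
  if (!any(ref_i)) abort(sprintf("No SNPs in reference class '%s'.",
                                 paste(reference_class, collapse = "+")))
  tab <- matrix(c(sum(test_i & in_peak), sum(test_i & !in_peak),
                  sum(ref_i & in_peak), sum(ref_i & !in_peak)),
                2, 2, byrow = TRUE)
  ft <- fisher_exact_cmle(tab)
  tibble(
    test_class = paste(test_class, collapse = "+"),
    reference_class = paste(reference_class, collapse = "+"),
    test_in = tab[1, 1], test_out = tab[1, 2],
    ref_in = tab[2, 1], ref_out = tab[2, 2],
    odds_ratio = ft$odds_ratio, ci_lower = ft$ci_lower,
    ci_upper = ft$ci_upper, p_value = ft$p_value
  )
}

# Log2 likelihood-ratio score of a sequence window under one PWM.
# seq_chars: character vector of bases; returns -Inf if any base is not ACGT.
pwm_window_score <- function(seq_chars, pwm) {
  w <- ncol(pwm$mat)
  p <- (pwm$mat + pwm$pseudocount)
  p <- sweep(p, 2, colSums(p), "/")
  idx <- match(seq_chars, rownames(p))
  if (anyNA(idx)) return(-Inf)
  sum(log2(p[cbind(idx, seq_len(w))] / pwm$bg[idx]))
}

revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

# Best score over all windows of width w covering position `center` (index
# into seq_chars), optionally on both strands.
pwm_best_score <- function(seq_chars, center, pwm, both_strands = TRUE) {
  w <- ncol(pwm$mat)
  starts <- seq(max(1L, center - w + 1L), min(center, length(seq_chars) - w + 1L))
  best <- -Inf
  for (s in starts) {
    win <- seq_chars[s:(s + w - 1L)]
    best <- max(best, pwm_window_score(win, pwm))
    if (both_strands) {
      best <- max(best, pwm_window_score(revcomp_chars(win), pwm))
    }
  }
  best
}

#' PWM binding-score differences between alleles
#'
#' For every SNP x motif pair, scores the reference and the alternative
#' allele as the maximum log2 likelihood-ratio score over all motif windows
#' covering the SNP position (both strands by default), and reports
#' `delta = alt_score - ref_score`. SNPs whose sequence context is
#' unavailable (too close to a contig end) are skipped with a warning.
#'
#' @param panel Target-SNP panel tibble.
#' @param genome A [Biostrings::DNAStringSet] (or FASTA path) containing the
#'   panel chromosomes.
#' @param pwms A list of motifs from [read_meme()] / [new_pwm()].
#' @param both_strands Score the reverse strand too.
#' @return A tibble: `snp_id`, `motif_id`, `ref_score`, `alt_score`,
#'   `delta`.
#' @export
pwm_delta_scores <- function(panel, genome, pwms, both_strands = TRUE) {
  panel <- validate_panel(panel)
  if (is.character(genome)) genome <- read_genome(genome)
  if (inherits(pwms, "starr_pwm")) pwms <- list(pwms)
  out <- list()
  for (pwm in pwms) {
    w <- ncol(pwm$mat)
    for (i in seq_len(nrow(panel))) {
      chrom <- panel$chrom[i]
      pos <- panel$pos[i]
      if (!chrom %in% names(genome)) {
        warn(sprintf("SNP %s: chromosome %s not in genome; skipped.",
                     panel$snp_id[i], chrom))
        next
      }
      from <- pos - w + 1L
      to <- pos + w - 1L
      if (from < 1L || to > Biostrings::width(genome)[match(chrom, names(genome))]) {
        warn(sprintf("SNP %s: context outside sequence bounds; skipped.",
                     panel$snp_id[i]))
        next
      }
      ctx <- strsplit(as.character(Biostrings::subseq(genome[[chrom]], from, to)),
                      "")[[1]]
      center <- w  # SNP sits at index w of the 2w-1 context
      ref_chars <- ctx
      ref_chars[center] <- panel$ref[i]
      alt_chars <- ctx
      alt_chars[center] <- panel$alt[i]
      rs <- pwm_best_score(ref_chars, center, pwm, both_strands)
      as_ <- pwm_best_score(alt_chars, center, pwm, both_strands)
      out[[length(out) + 1L]] <- tibble(
        snp_id = panel$snp_id[i], motif_id = pwm$id,
        ref_score = rs, alt_score = as_, delta = as_ - rs
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(snp_id = character(), motif_id = character(),
                  ref_score = numeric(), alt_score = numeric(),
                  delta = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Enrichment of motif-disrupting alleles among regulatory SNPs
#'
#' A SNP counts as motif-disrupting when its largest absolute delta score
#' over all motifs is at least `threshold` (log2 likelihood units); when
#' `peak_support` is given, the SNP must additionally sit inside a
#' supporting peak. The disruption rate is then compared between SNP
#' classes with [fisher_exact_cmle()]: `regulatory` vs
#' `active_nonregulatory`, and `regulatory` vs `inactive`.
#'
#' @param deltas Delta-score tibble from [pwm_delta_scores()].
#' @param classes Tibble with `snp_id` and `class` in `regulatory`,
#'   `active_nonregulatory`, `inactive`.
#' @param threshold Minimum |delta| to call a SNP motif-disrupting.
#' @param peak_support Optional peaks tibble; requires `chrom`/`pos` columns
#'   in `classes` for the overlap test.
#' @return An enrichment tibble with one row per comparison.
#' @export
delta_enrichment <- function(deltas, classes, threshold = 3,
                             peak_support = NULL) {
  check_columns(deltas, c("snp_id", "delta"), "deltas")
  check_columns(classes, c("snp_id", "class"), "classes")
  check_number(threshold, "threshold", lower = 0)
  disrupting <- deltas |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(max_abs_delta = max(abs(.data$delta)), .groups = "drop") |>
    dplyr::mutate(disrupting = .data$max_abs_delta >= threshold)
  tbl <- dplyr::left_join(classes, disrupting, by = "snp_id") |>
    dplyr::mutate(disrupting = tidyr::replace_na(.data$disrupting, FALSE))
  if (!is.null(peak_support)) {
    check_columns(tbl, c("chrom", "pos"), "classes (with peak_support)")
    tbl$disrupting <- tbl$disrupting & snps_in_peaks(tbl, peak_support)
  }
  compare <- function(test, ref) {
    ti <- tbl$class == test
    ri <- tbl$class == ref
    if (!any(ti)) abort(sprintf("No SNPs in class '%s'.", test))
    if (!any(ri)) abort(sprintf("No SNPs in class '%s'.", ref))
    tab <- matrix(c(sum(ti & tbl$disrupting), sum(ti & !tbl$disrupting),
                    sum(ri & tbl$disrupting), sum(ri & !tbl$disrupting)),
                  2, 2, byrow = TRUE)
    ft <- fisher_exact_cmle(tab)
    tibble(test_class = test, reference_class = ref,
           test_in = tab[1, 1], test_out = tab[1, 2],
           ref_in = tab[2, 1], ref_out = tab[2, 2],
           odds_ratio = ft$odds_ratio, ci_lower = ft$ci_lower,
           ci_upper = ft$ci_upper, p_value = ft$p_value)
  }
  dplyr::bind_rows(
    compare("regulatory", "active_nonregulatory"),
    compare("regulatory", "inactive")
  )
}
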