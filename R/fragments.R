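# Fragment filtering and counting: turn reconstructed fragments into the
# region count matrix and per-SNP allele count table that the statistics
# consume.

#' Load, filter and genotype sequenced fragments
#'
#' Accepts a SAM file of aligned proper pairs, a fragment-table TSV (the
#' dialect written by [simulate_dataset()] outputs), or an in-memory fragment
#' tibble. Keeps only fragments whose outer span is between `min_len` and
#' `max_len` bp and which cover at least one panel SNP. Observed bases below
#' `min_base_quality` are masked to unknown (`NA`); unknown alleles stay in
#' region counts but are excluded from allele counts.
#'
#' @param x SAM path, fragment-table TSV path, or fragment tibble with
#'   columns `fragment_id`, `library`, `chrom`, `start`, `end`, `length`,
#'   `snp_id`, `base`, `qual` (one row per fragment x covered SNP; fragments
#'   covering no SNP may appear with `snp_id` `NA`).
#' @param panel Target-SNP panel tibble.
#' @param min_len,max_len Retained fragment length range in bp.
#' @param min_base_quality Phred threshold below which an observed base is
#'   masked to unknown.
#' @param library Library label used when reading a SAM file.
#' @return A filtered fragment tibble (class `starr_fragments`); the
#'   `"starr_filter_stats"` attribute tallies fragments dropped by length or
#'   for covering no panel SNP.
#' @export
load_fragments <- function(x, panel, min_len = 400L, max_len = 600L,
                           min_base_quality = 20L, library = "input_1") {
  panel <- validate_panel(panel)
  check_number(min_len, "min_len", lower = 0)
  check_number(max_len, "max_len", lower = min_len)
  check_number(min_base_quality, "min_base_quality", lower = 0)
  if (is.character(x) && length(x) == 1L) {
    first <- readLines(x, n = 1L)
    if (startsWith(first, "@") || grepl("\\.sam$", x)) {
      x <- read_sam_fragments(x, panel, library = library)
    } else {
      x <- read_starr_tsv(x)
    }
  }
  check_columns(x, c("fragment_id", "library", "chrom", "start", "end",
                     "length", "snp_id", "base", "qual"), "fragments")
  x <- as_tibble(x)
  bad_len <- x$length != x$end - x$start
  if (any(bad_len, na.rm = TRUE)) {
    abort("fragment `length` must equal `end - start`.")
  }

  n_frag_in <- dplyr::n_distinct(x$fragment_id)
  x <- dplyr::mutate(
    x,
    base = ifelse(!is.na(.data$qual) & .data$qual < min_base_quality,
                  NA_character_, .data$base)
  )
  keep_len <- x$length >= min_len & x$length <= max_len
  x <- x[keep_len, , drop = FALSE]
  n_after_len <- dplyr::n_distinct(x$fragment_id)

  covered <- x |>
    dplyr::group_by(.data$fragment_id) |>
    dplyr::summarise(any_snp = any(!is.na(.data$snp_id)), .groups = "drop")
  keep_ids <- covered$fragment_id[covered$any_snp]
  x <- x[x$fragment_id %in% keep_ids & !is.na(x$snp_id), , drop = FALSE]

  attr(x, "starr_filter_stats") <- c(
    fragments_in = n_frag_in,
    dropped_length = n_frag_in - n_after_len,
    dropped_no_snp = n_after_len - length(keep_ids),
    fragments_kept = length(keep_ids)
  )
  class(x) <- c("starr_fragments", class(x))
  x
}

#' Build region count matrix and allele count table from fragments
#'
#' A fragment covering k panel SNPs contributes one count to each of the k
#' SNP regions and one allele observation at each covered SNP. Observed
#' bases are classified against the panel as `ref`, `alt`, `other` (a base
#' matching neither allele) or `unknown` (masked); `other` and `unknown`
#' observations stay in the region counts but are excluded from ref/alt
#' allele tallies.
#'
#' @param fragments Filtered fragment tibble from [load_fragments()] (or the
#'   generator), with a `library` column.
#' @param panel Target-SNP panel tibble; every SNP referenced by a fragment
#'   must be present, and every panel SNP appears in the output (zero-filled).
#' @param libraries Library columns to emit; defaults to those present in
#'   `fragments`, or the standard two-replicate input/output set when
#'   `fragments` is empty.
#' @return A list with `counts` (wide region-by-library tibble) and
#'   `allele_counts` (long tibble: `snp_id`, `library`, `condition`,
#'   `replicate`, `ref_count`, `alt_count`, `other_count`, `unknown_count`).
#' @export
count_matrices <- function(fragments, panel, libraries = NULL) {
  panel <- validate_panel(panel)
  frag_snps <- fragments[!is.na(fragments$snp_id), , drop = FALSE]
  unknown_snps <- setdiff(unique(frag_snps$snp_id), panel$snp_id)
  if (length(unknown_snps) > 0L) {
    abort(sprintf("Fragments reference SNP(s) absent from the panel: %s",
                  paste(head(unknown_snps, 5), collapse = ", ")))
  }
  if (is.null(libraries)) {
    libraries <- sort(unique(frag_snps$library))
    if (length(libraries) == 0L) {
      libraries <- c("input_1", "input_2", "output_1", "output_2")
    }
  }
  grid <- tidyr::expand_grid(snp_id = panel$snp_id, library = libraries)

  tallied <- frag_snps |>
    dplyr::left_join(dplyr::select(panel, "snp_id", "ref", "alt"), by = "snp_id") |>
    dplyr::mutate(allele = dplyr::case_when(
      is.na(.data$base) ~ "unknown",
      .data$base == .data$ref ~ "ref",
      .data$base == .data$alt ~ "alt",
      TRUE ~ "other"
    )) |>
    dplyr::count(.data$snp_id, .data$library, .data$allele)

  allele_counts <- grid |>
    dplyr::left_join(
      tidyr::pivot_wider(tallied, names_from = "allele", values_from = "n",
                         values_fill = 0L),
      by = c("snp_id", "library")
    ) |>
    dplyr::mutate(dplyr::across(dplyr::any_of(c("ref", "alt", "other", "unknown")),
                                ~ tidyr::replace_na(.x, 0L)))
  for (col in c("ref", "alt", "other", "unknown")) {
    if (!col %in% names(allele_counts)) allele_counts[[col]] <- 0L
  }
  allele_counts <- allele_counts |>
    dplyr::transmute(
      snp_id = .data$snp_id, library = .data$library,
      condition = lib_condition(.data$library),
      replicate = lib_replicate(.data$library),
      ref_count = .data$ref, alt_count = .data$alt,
      other_count = .data$other, unknown_count = .data$unknown
    ) |>
    dplyr::arrange(match(.data$snp_id, panel$snp_id), .data$library)

  counts <- allele_counts |>
    dplyr::mutate(total = .data$ref_count + .data$alt_count +
                    .data$other_count + .data$unknown_count) |>
    dplyr::select("snp_id", "library", "total") |>
    tidyr::pivot_wider(names_from = "library", values_from = "total") |>
    dplyr::arrange(match(.data$snp_id, panel$snp_id))

  list(counts = counts, allele_counts = allele_counts)
}
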