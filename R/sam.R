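# Minimal SAM text support: enough of the mandatory fields to reconstruct
# sequenced fragments from proper read pairs and to emit synthetic pairs.
# BAM/CRAM and indel-aware genotyping at SNP sites are out of scope.

FLAG_PAIRED <- 0x1
FLAG_PROPER <- 0x2
FLAG_UNMAPPED <- 0x4
FLAG_MATE_UNMAPPED <- 0x8
FLAG_REVERSE <- 0x10
FLAG_MATE_REVERSE <- 0x20
FLAG_FIRST <- 0x40
FLAG_SECOND <- 0x80

cigar_ops <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
  list(len = as.integer(m[, 2]), op = m[, 3])
}

cigar_reference_length <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

# Base and quality of a read at 1-based reference position p, or NA if the
# position falls in a deletion/skip or outside the aligned span.
read_base_at <- function(pos, cigar, seq, qual, p) {
  ops <- cigar_ops(cigar)
  r <- pos
  q <- 1L
  for (k in seq_along(ops$op)) {
    len <- ops$len[k]
    op <- ops$op[k]
    if (op %in% c("M", "=", "X")) {
      if (p >= r && p <= r + len - 1L) {
        qi <- q + (p - r)
        return(list(base = substr(seq, qi, qi),
                    qual = utf8ToInt(substr(qual, qi, qi)) - 33L))
      }
      r <- r + len
      q <- q + len
    } else if (op %in% c("D", "N")) {
      if (p >= r && p <= r + len - 1L) return(list(base = NA_character_, qual = NA_integer_))
      r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    }
    # H and P consume nothing we track
  }
  list(base = NA_character_, qual = NA_integer_)
}

#' Reconstruct fragments from a SAM alignment file
#'
#' Reads a plain-text SAM file of paired-end reporter-library alignments and
#' reconstructs one fragment per properly paired read pair: the fragment is
#' the outer span of the two mates (0-based half-open). For every panel SNP
#' inside the span the observed base and its quality are recorded; when the
#' two mates overlap a SNP and disagree, the base is set to `NA` (unknown).
#'
#' Malformed lines are skipped with a warning; unmapped, improperly paired or
#' orphaned reads are excluded. All exclusion tallies are returned in the
#' `"starr_sam_stats"` attribute.
#'
#' @param path SAM file path.
#' @param panel Target-SNP panel tibble (see [read_panel()]).
#' @param library Library label attached to every fragment (e.g. `"input_1"`).
#' @return A fragment tibble: one row per fragment x covered SNP with columns
#'   `fragment_id`, `library`, `chrom`, `start`, `end`, `length`, `snp_id`,
#'   `base`, `qual`. Fragments covering no panel SNP appear with `snp_id` `NA`
#'   so that downstream filters can count them.
#' @export
read_sam_fragments <- function(path, panel, library = "input_1") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  panel <- validate_panel(panel)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  n_malformed <- 0L
  n_excluded <- 0L
  reads <- list()
  for (ln in lines) {
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) {
      warn(sprintf("Skipping malformed SAM line: %s", substr(ln, 1, 60)))
      n_malformed <- n_malformed + 1L
      next
    }
    flag <- as.integer(f[2])
    ok <- bitwAnd(flag, FLAG_PAIRED) > 0 &&
      bitwAnd(flag, FLAG_PROPER) > 0 &&
      bitwAnd(flag, FLAG_UNMAPPED) == 0 &&
      bitwAnd(flag, FLAG_MATE_UNMAPPED) == 0
    if (!ok) {
      n_excluded <- n_excluded + 1L
      next
    }
    reads[[length(reads) + 1L]] <- list(
      qname = f[1], flag = flag, rname = f[3], pos = as.integer(f[4]),
      cigar = f[6], seq = f[10], qual = f[11]
    )
  }
  qnames <- vapply(reads, `[[`, character(1), "qname")
  frags <- list()
  for (qn in unique(qnames)) {
    pair <- reads[qnames == qn]
    if (length(pair) != 2L || pair[[1]]$rname != pair[[2]]$rname) {
      n_excluded <- n_excluded + length(pair)
      next
    }
    chrom <- pair[[1]]$rname
    starts <- vapply(pair, `[[`, integer(1), "pos")
    ends1 <- vapply(pair, function(r) r$pos + cigar_reference_length(r$cigar) - 1L,
                    integer(1))
    start0 <- min(starts) - 1L
    end0 <- max(ends1)  # half-open
    covered <- panel[panel$chrom == chrom &
                       point_in_interval(panel$pos, start0, end0), ]
    if (nrow(covered) == 0L) {
      frags[[length(frags) + 1L]] <- tibble(
        fragment_id = qn, library = library, chrom = chrom,
        start = start0, end = end0, length = end0 - start0,
        snp_id = NA_character_, base = NA_character_, qual = NA_integer_
      )
      next
    }
    obs <- purrr::map(covered$pos, function(p) {
      calls <- purrr::map(pair, function(r) {
        if (p >= r$pos && p <= r$pos + cigar_reference_length(r$cigar) - 1L) {
          read_base_at(r$pos, r$cigar, r$seq, r$qual, p)
        } else NULL
      })
      calls <- purrr::compact(calls)
      calls <- calls[!vapply(calls, function(x) is.na(x$base), logical(1))]
      if (length(calls) == 0L) return(list(base = NA_character_, qual = NA_integer_))
      if (length(calls) == 2L && calls[[1]]$base != calls[[2]]$base) {
        return(list(base = NA_character_, qual = NA_integer_))
      }
      best <- which.max(vapply(calls, `[[`, integer(1), "qual"))
      calls[[best]]
    })
    frags[[length(frags) + 1L]] <- tibble(
      fragment_id = qn, library = library, chrom = chrom,
      start = start0, end = end0, length = end0 - start0,
      snp_id = covered$snp_id,
      base = vapply(obs, `[[`, character(1), "base"),
      qual = vapply(obs, `[[`, integer(1), "qual")
    )
  }
  out <- if (length(frags) > 0L) dplyr::bind_rows(frags) else tibble(
    fragment_id = character(), library = character(), chrom = character(),
    start = integer(), end = integer(), length = integer(),
    snp_id = character(), base = character(), qual = integer()
  )
  attr(out, "starr_sam_stats") <- c(malformed = n_malformed, excluded = n_excluded)
  out
}

#' Write synthetic fragments as a minimal SAM file
#'
#' Emits one properly paired read pair per fragment (flags 99/147), with the
#' fragment's observed allele substituted into the read sequence at each
#' covered SNP. Intended for exercising the SAM reader on generator output.
#'
#' @param fragments Fragment tibble as produced by [simulate_dataset()].
#' @param panel Target-SNP panel tibble.
#' @param path Output SAM path.
#' @param genome Optional [Biostrings::DNAStringSet]; when absent, read
#'   sequences are `A`-filled except at covered SNPs.
#' @param read_length Read length in bp (reads are clipped to the fragment).
#' @export
write_sam <- function(fragments, panel, path, genome = NULL, read_length = 250L) {
  panel <- validate_panel(panel)
  frag_tbl <- dplyr::distinct(fragments, .data$fragment_id, .data$chrom,
                              .data$start, .data$end)
  con <- file(path, "w")
  on.exit(close(con))
  chroms <- unique(frag_tbl$chrom)
  chrom_len <- if (!is.null(genome)) {
    setNames(Biostrings::width(genome)[match(chroms, names(genome))], chroms)
  } else {
    setNames(vapply(chroms, function(ch) {
      max(frag_tbl$end[frag_tbl$chrom == ch]) + 1000L
    }, integer(1)), chroms)
  }
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chroms, chrom_len[chroms]), con)

  read_seq <- function(chrom, from, to, fr) {
    len <- to - from + 1L
    s <- if (!is.null(genome)) {
      as.character(Biostrings::subseq(genome[[chrom]], from, to))
    } else {
      strrep("A", len)
    }
    hits <- fr[!is.na(fr$snp_id) & fr$pos >= from & fr$pos <= to, ]
    if (nrow(hits) > 0L) {
      for (k in seq_len(nrow(hits))) {
        substr(s, hits$pos[k] - from + 1L, hits$pos[k] - from + 1L) <- hits$base[k]
      }
    }
    s
  }

  fr_snps <- dplyr::left_join(
    dplyr::filter(fragments, !is.na(.data$snp_id)),
    dplyr::select(panel, "snp_id", "pos"), by = "snp_id"
  )
  for (i in seq_len(nrow(frag_tbl))) {
    fg <- frag_tbl[i, ]
    fr <- fr_snps[fr_snps$fragment_id == fg$fragment_id, ]
    len <- fg$end - fg$start
    rl <- min(read_length, len)
    p1 <- fg$start + 1L
    p2 <- fg$end - rl + 1L
    s1 <- read_seq(fg$chrom, p1, p1 + rl - 1L, fr)
    s2 <- read_seq(fg$chrom, p2, p2 + rl - 1L, fr)
    q <- strrep("I", rl)
    writeLines(sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
                       fg$fragment_id, fg$chrom, p1, rl, p2, len, s1, q), con)
    writeLines(sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
                       fg$fragment_id, fg$chrom, p2, rl, p1, -len, s2, q), con)
  }
  invisible(path)
}
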