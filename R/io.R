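# Plain-text I/O for every table the pipeline exchanges.
#
# All tables are TSV with optional leading metadata lines starting "#".
# BED is 0-based half-open; panel positions are 1-based (VCF-like).

#' Read and write pipeline TSV tables
#'
#' Tables are tab-separated with a header row; lines beginning `#` hold
#' `key: value` run metadata and are skipped on read (returned in the
#' `"starr_meta"` attribute).
#'
#' @param x A data frame to write.
#' @param path File path.
#' @param meta Named character vector of metadata written as `# key: value`.
#' @return `read_starr_tsv()` returns a tibble; `write_starr_tsv()` returns
#'   `path` invisibly.
#' @export
write_starr_tsv <- function(x, path, meta = NULL) {
  lines <- character()
  if (length(meta) > 0L) {
    lines <- sprintf("# %s: %s", names(meta), as.character(meta))
  }
  writeLines(lines, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_starr_tsv
#' @export
read_starr_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- readLines(path, n = 100L)
  meta_lines <- grep("^#", header, value = TRUE)
  meta <- NULL
  if (length(meta_lines) > 0L) {
    kv <- stringr::str_match(meta_lines, "^#\\s*([^:]+):\\s*(.*)$")
    meta <- setNames(kv[, 3], trimws(kv[, 2]))
  }
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  attr(out, "starr_meta") <- meta
  out
}

#' Read and write SNP panel tables
#'
#' A panel lists the designed target SNPs: `chrom`, `pos` (1-based), `snp_id`,
#' `ref`, `alt`, `maf`, plus any extra columns (e.g. `tag_id`).
#'
#' @param panel A panel tibble.
#' @param path File path.
#' @return A validated panel tibble.
#' @export
read_panel <- function(path) {
  panel <- read_starr_tsv(path)
  validate_panel(panel)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  write_starr_tsv(validate_panel(panel), path)
}

validate_panel <- function(panel) {
  check_columns(panel, c("chrom", "pos", "snp_id", "ref", "alt", "maf"), "panel")
  if (anyDuplicated(panel$snp_id)) abort("panel `snp_id` values must be unique.")
  if (any(panel$pos < 1L)) abort("panel `pos` must be 1-based (>= 1).")
  bad <- panel$ref == panel$alt
  if (any(bad)) abort("panel `ref` and `alt` alleles must differ.")
  as_tibble(panel)
}

#' Read and write BED interval files
#'
#' Minimal BED support (chrom, start, end, optional name): coordinates are
#' 0-based half-open, as in the format specification.
#'
#' @param peaks A tibble with `chrom`, `start`, `end` and optionally `name`.
#' @param path File path.
#' @return `read_bed()` returns a tibble with columns `chrom`, `start`,
#'   `end`, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  cols <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  if (ncol(cols) < 3L) abort("BED file must have at least 3 columns.")
  out <- tibble(
    chrom = as.character(cols[[1]]),
    start = as.integer(cols[[2]]),
    end = as.integer(cols[[3]]),
    name = if (ncol(cols) >= 4L) as.character(cols[[4]]) else NA_character_
  )
  validate_peaks(out)
}

#' @rdname read_bed
#' @export
write_bed <- function(peaks, path) {
  validate_peaks(peaks)
  out <- peaks[, intersect(c("chrom", "start", "end", "name"), names(peaks))]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

validate_peaks <- function(peaks) {
  check_columns(peaks, c("chrom", "start", "end"), "peaks")
  if (any(peaks$start >= peaks$end)) {
    abort("peak intervals must satisfy start < end (0-based half-open).")
  }
  if (any(peaks$start < 0L)) abort("peak `start` must be >= 0.")
  as_tibble(peaks)
}

#' Read and write genotype pool tables
#'
#' The pool is a matrix of diploid alt-allele dosages (0/1/2), individuals in
#' rows and panel SNPs in columns; on disk it is a TSV with an `individual`
#' column followed by one column per SNP.
#'
#' @param pool An integer matrix with row and column names.
#' @param path File path.
#' @return `read_pool()` returns an integer matrix.
#' @export
read_pool <- function(path) {
  tbl <- read_starr_tsv(path)
  check_columns(tbl, "individual", "pool table")
  m <- as.matrix(tbl[, setdiff(names(tbl), "individual")])
  storage.mode(m) <- "integer"
  rownames(m) <- tbl$individual
  validate_pool(m)
}

#' @rdname read_pool
#' @export
write_pool <- function(pool, path) {
  validate_pool(pool)
  tbl <- dplyr::bind_cols(tibble(individual = rownames(pool)), as_tibble(pool))
  write_starr_tsv(tbl, path)
}

validate_pool <- function(pool) {
  if (!is.matrix(pool)) abort("genotype pool must be a matrix.")
  if (!all(pool %in% 0:2)) abort("genotypes must be alt-allele dosages 0, 1 or 2.")
  pool
}

#' Read a reference (or synthetic) genome FASTA
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet] named by sequence.
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a genome FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a minimal MEME-style motif file
#'
#' Parses `MOTIF <id>` blocks followed by a
#' `letter-probability matrix: alength= 4 w= <W>` header and W rows of four
#' probabilities (A C G T order). A `Background letter frequencies` line, if
#' present, sets the default background.
#'
#' @param path Motif file path.
#' @param pseudocount Probability added to each matrix cell before log-odds
#'   scoring (renormalized); stored with each motif.
#' @return A named list of motifs; each motif is a list with elements `id`,
#'   `mat` (4 x W matrix, rows A/C/G/T), `pseudocount` and `bg`.
#' @export
read_meme <- function(path, pseudocount = 0.01) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1L && bg_at < length(lines)) {
    toks <- strsplit(trimws(lines[bg_at + 1L]), "\\s+")[[1]]
    if (length(toks) >= 8L) {
      vals <- as.numeric(toks[seq(2, 8, by = 2)])
      names(vals) <- toks[seq(1, 7, by = 2)]
      bg <- vals[c("A", "C", "G", "T")]
    }
  }
  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0L) abort("No MOTIF blocks found.")
  motifs <- lapply(motif_at, function(i) {
    id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    j <- i
    repeat {
      j <- j + 1L
      if (j > length(lines)) abort(sprintf("Motif %s has no probability matrix.", id))
      if (grepl("^letter-probability matrix", lines[j])) break
    }
    w <- as.integer(stringr::str_match(lines[j], "w=\\s*(\\d+)")[, 2])
    rows <- lines[(j + 1L):(j + w)]
    mat <- vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])
    }, numeric(4))  # 4 x W
    dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
    new_pwm(id, mat, pseudocount = pseudocount, bg = bg)
  })
  names(motifs) <- vapply(motifs, `[[`, character(1), "id")
  motifs
}

#' Construct a position weight matrix object
#'
#' @param id Motif identifier.
#' @param mat A 4 x W matrix of per-position base probabilities, rows in
#'   A, C, G, T order; columns are renormalized to sum to one.
#' @param pseudocount Probability mass added per cell before scoring.
#' @param bg Background base frequencies (A, C, G, T).
#' @return A `starr_pwm` list.
#' @export
new_pwm <- function(id, mat, pseudocount = 0.01, bg = c(0.25, 0.25, 0.25, 0.25)) {
  if (!is.matrix(mat) || nrow(mat) != 4L || ncol(mat) < 1L) {
    abort("PWM matrix must be 4 x W with W >= 1.")
  }
  if (any(mat < 0)) abort("PWM probabilities must be non-negative.")
  dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
  mat <- sweep(mat, 2, colSums(mat), "/")
  bg <- as.numeric(bg)
  if (length(bg) != 4L || any(bg <= 0)) abort("`bg` must be 4 positive frequencies.")
  bg <- bg / sum(bg)
  names(bg) <- c("A", "C", "G", "T")
  structure(list(id = id, mat = mat, pseudocount = pseudocount, bg = bg),
            class = "starr_pwm")
}

#' Write motifs in minimal MEME format
#'
#' @param pwms A list of `starr_pwm` objects.
#' @param path Output path.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25", ""),
             con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", ncol(p$mat)),
               con)
    apply(p$mat, 2, function(col) {
      writeLines(paste(sprintf("%.6f", col), collapse = " "), con)
    })
    writeLines("", con)
  }
  invisible(path)
}
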