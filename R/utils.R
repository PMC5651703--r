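# Internal helpers: argument checks and coordinate conversions.
#
# Coordinate conventions, centralized here and used everywhere else:
#   * panel / variant tables: 1-based positions (`pos`), as in VCF;
#   * fragments and peaks: 0-based half-open [start, end), as in BED/SAM spans.
# A SNP at 1-based position p lies inside [start, end) iff start <= p - 1 < end.

check_number <- function(x, name, lower = -Inf, upper = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  if (integerish && x != round(x)) {
    abort(sprintf("`%s` must be a whole number, got %s.", name, x))
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", name))
  }
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Convert between 1-based SNP positions and 0-based half-open intervals
#'
#' `pos_to_zero()` maps a 1-based position to its 0-based coordinate;
#' `zero_to_pos()` is the inverse. `point_in_interval()` tests whether a
#' 1-based position is covered by a 0-based half-open interval, the overlap
#' rule used for SNP-in-peak tests.
#'
#' @param pos integer vector of 1-based positions.
#' @param zero integer vector of 0-based coordinates.
#' @param start,end integer vectors delimiting 0-based half-open intervals.
#' @return An integer (or logical, for `point_in_interval()`) vector.
#' @export
pos_to_zero <- function(pos) as.integer(pos) - 1L

#' @rdname pos_to_zero
#' @export
zero_to_pos <- function(zero) as.integer(zero) + 1L

#' @rdname pos_to_zero
#' @export
point_in_interval <- function(pos, start, end) {
  z <- pos_to_zero(pos)
  z >= start & z < end
}

# Condition labels used in library column names ("input_1", "output_2", ...).
lib_condition <- function(library) sub("_[0-9]+$", "", library)
lib_replicate <- function(library) as.integer(sub("^.*_", "", library))

# Seed streams: derive per-stage seeds from one master seed, kept well below
# .Machine$integer.max so callers can pass any small integer.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147480000L
}
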