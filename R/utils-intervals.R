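# Internal helpers for 0-based half-open interval arithmetic.
#
# Intervals are two-column integer matrices (start, end) with start < end,
# the BED convention used throughout the package. Conversion to the 1-based
# closed convention of GenomicRanges happens only at the boundary.

#' @importFrom IRanges IRanges reduce setdiff start end width
NULL

empty_intervals <- function() {
  matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

as_interval_matrix <- function(x) {
  if (is.null(x) || length(x) == 0L) return(empty_intervals())
  m <- matrix(as.integer(x), ncol = 2L)
  colnames(m) <- c("start", "end")
  if (any(m[, 1L] >= m[, 2L])) stop("interval with start >= end")
  m
}

# 0-based half-open -> IRanges (1-based closed)
intervals_to_iranges <- function(m) {
  IRanges::IRanges(start = m[, 1L] + 1L, end = m[, 2L])
}

iranges_to_intervals <- function(ir) {
  if (length(ir) == 0L) return(empty_intervals())
  m <- cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  m[order(m[, 1L]), , drop = FALSE]
}

# Union of possibly overlapping intervals; adjacent intervals are merged.
merge_intervals <- function(m) {
  m <- as_interval_matrix(m)
  if (nrow(m) == 0L) return(m)
  iranges_to_intervals(IRanges::reduce(intervals_to_iranges(m)))
}

# Complement of `m` within [span_start, span_end)
interval_gaps <- function(m, span_start, span_end) {
  span <- IRanges::IRanges(span_start + 1L, span_end)
  if (nrow(m) == 0L) return(iranges_to_intervals(span))
  iranges_to_intervals(IRanges::setdiff(span, intervals_to_iranges(m)))
}

# Subtract `mask` from `m`, keeping the leftover pieces.
interval_subtract <- function(m, mask) {
  m <- as_interval_matrix(m)
  if (nrow(m) == 0L || nrow(mask) == 0L) return(m)
  iranges_to_intervals(IRanges::setdiff(intervals_to_iranges(m),
                                        intervals_to_iranges(as_interval_matrix(mask))))
}

total_width <- function(m) {
  if (nrow(m) == 0L) return(0L)
  sum(m[, 2L] - m[, 1L])
}

# round half away from zero (classic half-up for non-negative input)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
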