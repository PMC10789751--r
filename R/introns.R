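#' Terminal-intron selection
#'
#' Keeps the first two and last two introns of each gene (transcription
#' order). Genes with four or fewer introns keep all of them; an intron of
#' a short gene may satisfy two position classes (e.g. the only intron of a
#' 1-intron gene is both `first` and `last`) and is then reported once per
#' class.
#'
#' @param table Intron table from [build_intron_table()].
#' @return The table restricted to terminal introns, with an added
#'   `position` column in `{first, second, second_last, last}`.
#' @export
select_terminal_introns <- function(table) {
  keep <- table[table$index_from_start <= 2L | table$index_from_end <= 2L, ,
                drop = FALSE]
  labels <- list(first = keep$index_from_start == 1L,
                 second = keep$index_from_start == 2L,
                 second_last = keep$index_from_end == 2L,
                 last = keep$index_from_end == 1L)
  out <- do.call(rbind, lapply(names(labels), function(pos) {
    d <- keep[labels[[pos]], , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    d$position <- pos
    d
  }))
  if (is.null(out)) {
    out <- table[0, , drop = FALSE]
    out$position <- character(0)
  }
  rownames(out) <- NULL
  out
}

#' Intron RPKM with unit pseudocount
#'
#' `(read_counts + 1) / ((length_bp / 1000) * (total_reads / 1e6))`; the
#' pseudocount keeps every intron's RPKM strictly positive.
#'
#' @param read_counts Reads overlapping the intron.
#' @param length_bp Intron length (> 0).
#' @param total_reads Library size (> 0).
#' @return RPKM value(s) > 0. Vectorized.
#' @export
intron_rpkm <- function(read_counts, length_bp, total_reads) {
  if (any(length_bp <= 0)) stop("intron length must be positive")
  if (any(total_reads <= 0)) stop("total reads must be positive")
  (read_counts + 1) / ((length_bp / 1000) * (total_reads / 1e6))
}

#' Estimate read counts over an intron from coverage
#'
#' `round(sum(depth) / read_length)`, rounding half up.
#'
#' @param track A [coverage_track()].
#' @param intron One row of an intron table (`chrom`, `start`, `end`).
#' @return Integer read count estimate.
#' @export
intron_read_counts <- function(track, intron) {
  total <- region_depth_sum(track, intron$chrom, intron$start, intron$end)
  as.integer(round_half_up(total / track$read_length))
}

#' Per-position intron RPKM table for a sample
#'
#' @param track A [coverage_track()].
#' @param terminal_introns Output of [select_terminal_introns()].
#' @return The input table with `read_counts` and `rpkm` columns added.
#' @export
intron_rpkm_table <- function(track, terminal_introns) {
  counts <- vapply(seq_len(nrow(terminal_introns)), function(i)
    intron_read_counts(track, terminal_introns[i, ]), 0L)
  terminal_introns$read_counts <- counts
  terminal_introns$rpkm <- intron_rpkm(counts, terminal_introns$length_bp,
                                       track$library_size)
  terminal_introns
}

#' Compare intron retention between RT and NRT genes, expression-matched
#'
#' Per position class, RT genes are matched to NRT genes on expression
#' (see [expression_matched_subsamples()]); the matched per-gene RPKM
#' values pooled over all permutations form the two comparison groups.
#' Significance requires Mann-Whitney p < 0.05 AND Cohen's d > 0.3 (the
#' conjunction keeps the huge pooled sample sizes from flagging trivial
#' differences).
#'
#' @param rpkm `data.frame(gene_id, position, rpkm)`, one row per gene and
#'   position class (e.g. mean RPKM across that gene's introns in the
#'   class, averaged over samples).
#' @param rt_ids,nrt_ids Gene id vectors for the two groups.
#' @param expr Named expression vector covering both groups.
#' @param matching A [matching_config()].
#' @param p_threshold,d_threshold Significance thresholds.
#' @return `data.frame` per position: group means, `p_value`, `cohen_d`,
#'   `significant`.
#' @export
compare_intron_retention <- function(rpkm, rt_ids, nrt_ids, expr, matching,
                                     p_threshold = 0.05, d_threshold = 0.3) {
  positions <- unique(rpkm$position)
  out <- lapply(positions, function(pos) {
    d <- rpkm[rpkm$position == pos, ]
    v <- stats::setNames(d$rpkm, d$gene_id)
    rt_pool <- intersect(rt_ids, names(v))
    nrt_pool <- intersect(nrt_ids, names(v))
    if (length(rt_pool) == 0L || length(nrt_pool) == 0L)
      stop("empty position class: ", pos)
    cfg <- matching
    cfg$n_per_subsample <- min(cfg$n_per_subsample, length(rt_pool),
                               length(nrt_pool))
    sub <- expression_matched_subsamples(expr[rt_pool], expr[nrt_pool], cfg)
    a <- unname(v[sub$rt_gene]); b <- unname(v[sub$nrt_gene])
    cmp <- mann_whitney_cohen(a, b)
    data.frame(position = pos, mean_rt = mean(a), mean_nrt = mean(b),
               p_value = cmp$p_value, cohen_d = cmp$cohen_d,
               significant = cmp$p_value < p_threshold &
                 cmp$cohen_d > d_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Row-wise z-scores
#'
#' Per row, `(x - mean) / sd` with the sample standard deviation;
#' zero-variance rows map to all zeros.
#'
#' @param mat Numeric matrix (e.g. tissues x intron positions of mean RPKM).
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  t(apply(mat, 1L, function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
}
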