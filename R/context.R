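#' Chromosome-level enrichment of a gene group
#'
#' Per chromosome, a 2x2 table of group membership vs chromosome membership
#' is tested with a two-sided Fisher exact test; p-values are BH-adjusted
#' across chromosomes and direction assigned by the sample odds ratio at
#' FDR < 0.05. By default the background excludes the group
#' (complement background); `inclusive = TRUE` keeps the group inside the
#' background counts.
#'
#' @param group Character vector of gene ids (subset of `background`).
#' @param background Character vector of gene ids (e.g. expressed genes).
#' @param genes Annotation (list of [gene_model()]).
#' @param inclusive Keep group genes inside the background counts.
#' @param fdr_threshold Direction-call threshold.
#' @return `data.frame` per chromosome: counts, `odds_ratio`, `p_value`,
#'   `fdr`, `direction` in `{enriched, depleted, ns}`.
#' @export
chromosome_enrichment <- function(group, background, genes,
                                  inclusive = FALSE, fdr_threshold = 0.05) {
  if (length(background) == 0L) stop("empty background")
  if (!all(group %in% background)) stop("group must be a subset of background")
  chrom_of <- stats::setNames(vapply(genes, `[[`, "", "chrom"),
                              vapply(genes, `[[`, "", "gene_id"))
  bg <- if (inclusive) background else setdiff(background, group)
  g_chrom <- chrom_of[group]; b_chrom <- chrom_of[bg]
  chroms <- sort(unique(chrom_of[background]))
  out <- lapply(chroms, function(ch) {
    a <- sum(g_chrom == ch); b <- length(group) - a
    c_ <- sum(b_chrom == ch); d <- length(bg) - c_
    or <- (a * d) / (b * c_)  # sample odds ratio; may be Inf/NaN at zeros
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    data.frame(chrom = ch, n_group_on = a, n_group_off = b,
               n_bg_on = c_, n_bg_off = d, odds_ratio = or, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$fdr <- bh_fdr(out$p_value)
  out$direction <- "ns"
  out$direction[out$fdr < fdr_threshold & out$odds_ratio > 1] <- "enriched"
  out$direction[out$fdr < fdr_threshold & out$odds_ratio < 1] <- "depleted"
  rownames(out) <- NULL
  out
}

#' Expressed-gene density per chromosome or per 1-Mb window
#'
#' Each gene is assigned to the unit containing its 5' end; the last window
#' of a chromosome may be shorter. Density is genes per bp.
#'
#' @param genes Annotation (list of [gene_model()]).
#' @param expressed_ids Gene ids to count.
#' @param genome Named chromosome lengths.
#' @param unit `"chromosome"` or `"window"`.
#' @param window_bp Window size when `unit = "window"`.
#' @return `data.frame(unit_id, chrom, n_expressed, length_bp, density)`.
#' @export
gene_density <- function(genes, expressed_ids, genome,
                         unit = c("chromosome", "window"), window_bp = 1e6) {
  unit <- match.arg(unit)
  sel <- Filter(function(g) g$gene_id %in% expressed_ids, genes)
  chrom <- vapply(sel, `[[`, "", "chrom")
  # 5'-most transcribed base: span start for +, last base for -
  p5 <- vapply(sel, function(g)
    if (g$strand == "+") g$start else g$end - 1L, 0L)
  if (unit == "chromosome") {
    cnt <- table(factor(chrom, levels = names(genome)))
    out <- data.frame(unit_id = names(genome), chrom = names(genome),
                      n_expressed = as.integer(cnt),
                      length_bp = as.numeric(genome),
                      stringsAsFactors = FALSE)
  } else {
    rows <- lapply(names(genome), function(ch) {
      n_win <- ceiling(genome[[ch]] / window_bp)
      starts <- (seq_len(n_win) - 1L) * window_bp
      lens <- pmin(starts + window_bp, genome[[ch]]) - starts
      idx <- floor(p5[chrom == ch] / window_bp) + 1L
      cnt <- tabulate(idx, nbins = n_win)
      data.frame(unit_id = sprintf("%s:%d-%d", ch, starts, starts + lens),
                 chrom = ch, n_expressed = cnt, length_bp = lens,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  out$density <- out$n_expressed / out$length_bp
  rownames(out) <- NULL
  out
}

#' Distance from a gene's TTS to the closest downstream expressed gene
#'
#' Only same-strand expressed genes strictly downstream in transcription
#' direction are considered; genes overlapping the query gene are ignored
#' (the bedtools `closest -D a -iu -io -s` convention). The distance is the
#' gap in bp between the TTS and the nearest boundary of that gene.
#'
#' @param gene A [gene_model()].
#' @param genes Annotation.
#' @param expressed_ids Expressed gene ids.
#' @return Integer gap in bp, or `NA` when no such gene exists.
#' @export
distance_to_downstream_expressed <- function(gene, genes, expressed_ids) {
  t0 <- tts(gene)
  cands <- Filter(function(g)
    g$gene_id != gene$gene_id && g$gene_id %in% expressed_ids &&
      g$chrom == gene$chrom && g$strand == gene$strand, genes)
  if (gene$strand == "+") {
    d <- vapply(cands, function(g) g$start - t0, 0L)
  } else {
    d <- vapply(cands, function(g) t0 - g$end, 0L)
  }
  d <- d[d >= 0]
  if (length(d) == 0L) NA_integer_ else min(d)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; two-sided p-value from the t approximation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List `rho`, `p_value`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 observations")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Build TTS-flanking and tail-end region sets
#'
#' Three strand-aware region classes around the calls: `TTSminus`
#' (`window_bp` upstream of the TTS), `TTSplus` (`window_bp` downstream),
#' and `RTend` (+/- `window_bp` around the readthrough tail end). To limit
#' overlap between classes, RT genes with tails shorter than
#' `min_tail_bp_filter` are excluded from all three classes; NRT genes
#' contribute `TTSminus`/`TTSplus` only; UND genes are excluded.
#'
#' @param calls Per-gene calls (one row per gene, with `tts`, `tail_start`,
#'   `tail_end`, `tail_length_bp`, `status`).
#' @param window_bp Region half-width, default 2000.
#' @param min_tail_bp_filter Minimum RT tail length, default 2500.
#' @param genome Optional named chromosome lengths used to clip regions.
#' @return `data.frame(region_class, gene_id, status, chrom, start, end)`.
#' @export
build_flank_regions <- function(calls, window_bp = 2000L,
                                min_tail_bp_filter = 2500L, genome = NULL) {
  is_rt <- calls$status == "RT"
  keep <- (is_rt & calls$tail_length_bp >= min_tail_bp_filter) |
    calls$status == "NRT"
  d <- calls[keep, , drop = FALSE]
  plus <- d$strand == "+"
  rows <- list(
    data.frame(region_class = "TTSminus", gene_id = d$gene_id,
               status = d$status, chrom = d$chrom,
               start = ifelse(plus, d$tts - window_bp, d$tts),
               end = ifelse(plus, d$tts, d$tts + window_bp),
               stringsAsFactors = FALSE),
    data.frame(region_class = "TTSplus", gene_id = d$gene_id,
               status = d$status, chrom = d$chrom,
               start = ifelse(plus, d$tts, d$tts - window_bp),
               end = ifelse(plus, d$tts + window_bp, d$tts),
               stringsAsFactors = FALSE))
  r <- d[d$status == "RT", , drop = FALSE]
  if (nrow(r) > 0L) {
    tail_end <- ifelse(r$strand == "+", r$tail_end, r$tail_start)
    rows[[3L]] <- data.frame(region_class = "RTend", gene_id = r$gene_id,
                             status = r$status, chrom = r$chrom,
                             start = tail_end - window_bp,
                             end = tail_end + window_bp,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$start <- pmax(out$start, 0L)
  if (!is.null(genome)) out$end <- pmin(out$end, genome[out$chrom])
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count genes with at least one peak per region class
#'
#' A gene counts once per region class regardless of how many peaks overlap
#' its region; a 1-bp overlap counts.
#'
#' @param regions Output of [build_flank_regions()].
#' @param peaks `GRanges` of peaks, or a `data.frame` with `chrom`,
#'   `start`, `end` (0-based half-open).
#' @return `data.frame(region_class, status, n_genes, n_with_peak)`.
#' @export
count_genes_with_peak <- function(regions, peaks) {
  if (is.data.frame(peaks)) {
    peaks <- GenomicRanges::GRanges(peaks$chrom,
                                    IRanges::IRanges(peaks$start + 1L,
                                                     peaks$end))
  }
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  hit <- GenomicRanges::countOverlaps(rg, peaks, minoverlap = 1L,
                                      ignore.strand = TRUE) > 0
  agg <- stats::aggregate(cbind(n_genes = 1, n_with_peak = hit),
                          by = list(region_class = regions$region_class,
                                    status = regions$status), FUN = sum)
  agg
}

#' Read a BED/narrowPeak interval file as GRanges
#'
#' @param path File path; `.narrowPeak` files are parsed with their extra
#'   columns, anything else as BED.
#' @return `GRanges`.
#' @export
read_peaks <- function(path) {
  if (grepl("narrowPeak$", path)) {
    rtracklayer::import(path, format = "narrowPeak")
  } else {
    rtracklayer::import(path, format = "bed")
  }
}

#' Fold enrichment of chromatin states within a region set
#'
#' For a genome segmentation into labeled states,
#' `fold(state) = (bases(region & state) / bases(region)) /
#' (bases(state) / bases(genome))`, i.e. the density of the state inside
#' the regions relative to its genome-wide density. Overlapping
#' segmentation records are an error.
#'
#' @param regions `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open); overlapping regions are merged before counting.
#' @param segmentation `data.frame` with `chrom`, `start`, `end`, `state`.
#' @param genome Named chromosome lengths.
#' @return `data.frame(state, region_bases, state_bases, fold)`.
#' @export
state_fold_enrichment <- function(regions, segmentation, genome) {
  seg_gr <- GenomicRanges::GRanges(
    segmentation$chrom,
    IRanges::IRanges(segmentation$start + 1L, segmentation$end))
  red <- GenomicRanges::reduce(seg_gr)
  if (sum(GenomicRanges::width(red)) < sum(GenomicRanges::width(seg_gr)))
    stop("overlapping segmentation records")
  reg_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end)))
  genome_bases <- sum(as.numeric(genome))
  region_bases <- sum(GenomicRanges::width(reg_gr))
  states <- sort(unique(as.character(segmentation$state)))
  out <- lapply(states, function(st) {
    s <- seg_gr[segmentation$state == st]
    state_bases <- sum(GenomicRanges::width(s))
    inter <- GenomicRanges::intersect(reg_gr, s, ignore.strand = TRUE)
    ov <- sum(GenomicRanges::width(inter))
    fold <- (ov / region_bases) / (state_bases / genome_bases)
    data.frame(state = st, region_bases = region_bases,
               state_bases = state_bases, overlap_bases = ov, fold = fold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
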