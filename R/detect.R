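#' Rolling-window readthrough detector configuration
#'
#' Defaults follow the published calling parameters: 500 bp windows, a
#' minimum tail length of 2000 bp and a minimum window coverage of
#' 0.15 FPKM. `max_tail_bp` caps the scan (observed tails reach ~60 kb;
#' 100 kb leaves headroom without unbounded scanning).
#'
#' @param window_bp Window size in bp.
#' @param min_tail_bp Minimum tail length for an RT call.
#' @param min_window_fpkm Minimum FPKM a window must reach to extend the tail.
#' @param max_tail_bp Maximum scanned distance downstream of the TTS.
#' @export
detector_config <- function(window_bp = 500L, min_tail_bp = 2000L,
                            min_window_fpkm = 0.15, max_tail_bp = 100000L) {
  stopifnot(window_bp > 0, min_tail_bp >= window_bp, min_window_fpkm > 0,
            max_tail_bp >= min_tail_bp)
  list(window_bp = as.integer(window_bp), min_tail_bp = as.integer(min_tail_bp),
       min_window_fpkm = min_window_fpkm, max_tail_bp = as.integer(max_tail_bp))
}

#' Call a readthrough tail downstream of one gene
#'
#' Starting at the TTS, consecutive non-overlapping windows of `window_bp`
#' are evaluated in the downstream direction (rightward for `+`, leftward
#' for `-`). A window extends the tail iff its FPKM is at least
#' `min_window_fpkm`; scanning stops at the first failing window, at
#' `max_tail_bp`, or at the chromosome edge (a final window truncated by the
#' edge is evaluated over its actual length). The gene is RT when the tail
#' reaches `min_tail_bp`, otherwise NRT; the UND reclassification for
#' opposite-strand overlap is applied separately by
#' [filter_opposite_strand()].
#'
#' @param track A [coverage_track()].
#' @param gene A [gene_model()]; should be expressed in the sample's tissue
#'   (the caller enforces this upstream).
#' @param config A [detector_config()].
#' @return One-row `data.frame`: `gene_id`, `chrom`, `strand`, `tts`,
#'   `tail_start`, `tail_end`, `tail_length_bp`, `tail_fpkm`, `status`,
#'   `read_in` (NA until [classify_readin()]).
#' @export
call_readthrough <- function(track, gene, config = detector_config()) {
  x <- track$depth[[gene$chrom]]
  if (is.null(x)) stop("gene chromosome absent from track: ", gene$chrom)
  chrom_len <- length(x)
  t0 <- tts(gene)
  w <- config$window_bp
  n_max <- ceiling(config$max_tail_bp / w)

  if (gene$strand == "+") {
    starts <- t0 + (seq_len(n_max) - 1L) * w
    ends <- pmin(starts + w, chrom_len, t0 + config$max_tail_bp)
  } else {
    ends <- t0 - (seq_len(n_max) - 1L) * w
    starts <- pmax(ends - w, 0L, t0 - config$max_tail_bp)
  }
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]

  n_pass <- 0L
  for (i in seq_along(starts)) {
    if (region_fpkm(track, gene$chrom, starts[i], ends[i]) >= config$min_window_fpkm)
      n_pass <- i
    else break
  }
  if (n_pass == 0L) {
    tail_start <- tail_end <- t0
  } else if (gene$strand == "+") {
    tail_start <- t0; tail_end <- ends[n_pass]
  } else {
    tail_start <- starts[n_pass]; tail_end <- t0
  }
  len <- tail_end - tail_start
  fpkm <- if (len > 0) region_fpkm(track, gene$chrom, tail_start, tail_end) else 0
  data.frame(gene_id = gene$gene_id, chrom = gene$chrom, strand = gene$strand,
             tts = t0, tail_start = tail_start, tail_end = tail_end,
             tail_length_bp = len, tail_fpkm = fpkm,
             status = if (len >= config$min_tail_bp) "RT" else "NRT",
             read_in = NA, stringsAsFactors = FALSE)
}

#' Call readthrough for a set of genes in one sample
#'
#' @param track A [coverage_track()].
#' @param genes List of [gene_model()].
#' @param config A [detector_config()].
#' @param expressed_ids Optional character vector restricting detection to
#'   expressed genes (the published workflow calls readthrough only on
#'   genes expressed in the tissue).
#' @return `data.frame` of per-gene calls (see [call_readthrough()]).
#' @export
call_readthrough_all <- function(track, genes, config = detector_config(),
                                 expressed_ids = NULL) {
  if (!is.null(expressed_ids)) {
    genes <- Filter(function(g) g$gene_id %in% expressed_ids, genes)
  }
  do.call(rbind, lapply(genes, call_readthrough, track = track, config = config))
}

#' Reclassify ambiguous readthrough calls as UND
#'
#' In unstranded libraries a putative tail that overlaps any annotated gene
#' on the opposite strand cannot be distinguished from antisense
#' transcription, so such RT calls are reclassified UND (the tail interval
#' is retained for inspection). NRT calls are untouched. All annotated
#' opposite-strand genes are considered, not only expressed ones.
#'
#' @param calls Calls from [call_readthrough_all()].
#' @param genes Full annotation (list of [gene_model()]).
#' @return `calls` with `status` updated.
#' @export
filter_opposite_strand <- function(calls, genes) {
  rt <- which(calls$status == "RT" & calls$tail_length_bp > 0)
  if (length(rt) == 0L) return(calls)
  tails <- GenomicRanges::GRanges(
    calls$chrom[rt],
    IRanges::IRanges(calls$tail_start[rt] + 1L, calls$tail_end[rt]),
    strand = calls$strand[rt])
  anno <- genes_to_granges(genes)
  opp <- GenomicRanges::findOverlaps(tails, GenomicRanges::invertStrand(anno),
                                     minoverlap = 1L)
  hit <- unique(S4Vectors::queryHits(opp))
  calls$status[rt[hit]] <- "UND"
  calls
}

#' Flag read-in events: tails invading downstream expressed genes
#'
#' An RT call is a read-in when its tail overlaps (>= 1 bp) an expressed
#' gene on the same strand other than the host gene.
#'
#' @param calls Calls (after [filter_opposite_strand()]).
#' @param genes Full annotation.
#' @param expressed_ids Expressed gene ids.
#' @return `calls` with logical `read_in` filled for RT rows.
#' @export
classify_readin <- function(calls, genes, expressed_ids) {
  rt <- which(calls$status == "RT")
  calls$read_in <- NA
  if (length(rt) == 0L) return(calls)
  tails <- GenomicRanges::GRanges(
    calls$chrom[rt],
    IRanges::IRanges(calls$tail_start[rt] + 1L, calls$tail_end[rt]),
    strand = calls$strand[rt])
  anno <- genes_to_granges(genes)
  anno <- anno[anno$gene_id %in% expressed_ids]
  ov <- GenomicRanges::findOverlaps(tails, anno, minoverlap = 1L)
  same_strand <- as.character(GenomicRanges::strand(tails))[S4Vectors::queryHits(ov)] ==
    as.character(GenomicRanges::strand(anno))[S4Vectors::subjectHits(ov)]
  not_host <- calls$gene_id[rt][S4Vectors::queryHits(ov)] !=
    anno$gene_id[S4Vectors::subjectHits(ov)]
  hit <- unique(S4Vectors::queryHits(ov)[same_strand & not_host])
  calls$read_in[rt] <- FALSE
  calls$read_in[rt[hit]] <- TRUE
  calls
}

#' RT ratio: tail expression relative to total expression
#'
#' `rt_ratio = rt_levels / (rt_levels + gene_levels)`, defined as 0 when
#' both are 0.
#'
#' @param rt_levels Tail expression (FPKM), non-negative.
#' @param gene_levels Gene-body expression (FPKM), non-negative.
#' @return Value(s) in \[0, 1\]. Vectorized.
#' @export
rt_ratio <- function(rt_levels, gene_levels) {
  if (any(rt_levels < 0) || any(gene_levels < 0))
    stop("rt_ratio requires non-negative inputs")
  denom <- rt_levels + gene_levels
  ifelse(denom > 0, rt_levels / denom, 0)
}

#' Per-gene RT proportion across samples
#'
#' The per-sample ratio `tail_fpkm / (tail_fpkm + gene_fpkm)`, summarized
#' per gene as the median across samples.
#'
#' @param tail_fpkm,gene_fpkm Per-sample values for one gene.
#' @return Median ratio in \[0, 1\].
#' @export
rt_proportion <- function(tail_fpkm, gene_fpkm) {
  if (length(tail_fpkm) == 0L) stop("no samples")
  stats::median(rt_ratio(tail_fpkm, gene_fpkm))
}

#' Build the gene-by-tissue RT-ratio matrix
#'
#' Rows cover the union of RT genes across tissues; a gene absent from a
#' tissue (not RT there, or not expressed) gets 0, the convention used to
#' build the clustering input.
#'
#' @param per_tissue Named list: tissue -> `data.frame(gene_id, rt_ratio)`.
#' @return Numeric matrix, genes x tissues, values in \[0, 1\].
#' @export
build_rt_ratio_matrix <- function(per_tissue) {
  for (tis in names(per_tissue)) {
    if (anyDuplicated(per_tissue[[tis]]$gene_id))
      stop("duplicate gene within tissue ", tis)
  }
  all_genes <- sort(unique(unlist(lapply(per_tissue, `[[`, "gene_id"))))
  m <- matrix(0, nrow = length(all_genes), ncol = length(per_tissue),
              dimnames = list(all_genes, names(per_tissue)))
  for (tis in names(per_tissue)) {
    d <- per_tissue[[tis]]
    m[d$gene_id, tis] <- d$rt_ratio
  }
  if (any(m < 0 | m > 1)) stop("rt_ratio outside [0,1]")
  m
}

#' Tissue-level consensus RT status across samples
#'
#' A gene is RT in a tissue when it is called RT in more than
#' `consensus_fraction` of the tissue's samples; it is UND when called UND
#' in any sample (ambiguity is a property of the locus); otherwise NRT.
#'
#' @param calls_by_sample `data.frame` of per-sample calls with columns
#'   `sample_id`, `gene_id`, `status`.
#' @param consensus_fraction Strict lower bound on the RT sample fraction.
#' @return `data.frame(gene_id, status)`.
#' @export
consensus_rt_status <- function(calls_by_sample, consensus_fraction = 0.5) {
  sp <- split(calls_by_sample$status, calls_by_sample$gene_id)
  status <- vapply(sp, function(s) {
    if (any(s == "UND")) return("UND")
    if (mean(s == "RT") > consensus_fraction) "RT" else "NRT"
  }, "")
  data.frame(gene_id = names(status), status = unname(status),
             stringsAsFactors = FALSE)
}
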