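#' Coverage tracks and FPKM quantification
#'
#' A `CoverageTrack` holds per-base read depth per chromosome (as run-length
#' encoded vectors) together with the normalization constants of the
#' sequencing library: total uniquely-mapped reads and read length. Read
#' counts over a region are estimated as `sum(depth)/read_length`, so FPKM
#' can be computed from a coverage track alone without going back to the
#' alignments.
#'
#' @param depth Named `RleList` (or list of numeric vectors), one entry per
#'   chromosome with length equal to the chromosome length.
#' @param library_size Total uniquely-mapped reads in the library.
#' @param read_length Read length in bp.
#' @param sample_id Sample identifier.
#' @return Object of class `CoverageTrack`.
#' @export
coverage_track <- function(depth, library_size, read_length,
                           sample_id = "sample") {
  if (!methods::is(depth, "RleList")) {
    depth <- methods::as(lapply(depth, S4Vectors::Rle), "RleList")
  }
  if (library_size <= 0) stop("library_size must be positive")
  if (read_length <= 0) stop("read_length must be positive")
  if (any(vapply(depth, function(x) any(S4Vectors::runValue(x) < 0), FALSE)))
    stop("coverage depth must be non-negative")
  structure(list(depth = depth, library_size = as.numeric(library_size),
                 read_length = as.numeric(read_length),
                 sample_id = sample_id),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack '%s': %d chromosome(s), library %.3g reads, read length %d\n",
              x$sample_id, length(x$depth), x$library_size,
              as.integer(x$read_length)))
  invisible(x)
}

#' Read a bedGraph file into a coverage track
#'
#' Positions absent from the file get depth 0. Overlapping records,
#' out-of-bounds intervals and negative values are rejected.
#'
#' @param path bedGraph file path.
#' @param genome Named chromosome lengths (see [genome_index()]).
#' @inheritParams coverage_track
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, genome, library_size, read_length,
                          sample_id = basename(path)) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (is.null(gr$score)) gr$score <- numeric(length(gr))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  if (!all(chroms %in% names(genome)))
    stop("bedGraph chromosome absent from genome index: ",
         paste(unique(setdiff(chroms, names(genome))), collapse = ","))
  if (any(GenomicRanges::end(gr) > genome[chroms]))
    stop("bedGraph interval beyond chromosome end")
  if (any(gr$score < 0)) stop("bedGraph with negative value")
  red <- GenomicRanges::reduce(gr)
  if (sum(GenomicRanges::width(red)) < sum(GenomicRanges::width(gr)))
    stop("bedGraph with overlapping records")
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- unname(genome)
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  coverage_track(cov[names(genome)], library_size, read_length, sample_id)
}

#' Write a coverage track as bedGraph (non-zero runs only)
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  gr <- methods::as(track$depth, "GRanges")
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' FPKM of an arbitrary genomic region
#'
#' Estimated reads are `sum(depth)/read_length`; FPKM divides by region
#' length in kb and library size in millions.
#'
#' @param track A [coverage_track()].
#' @param chrom Chromosome.
#' @param start,end Region, 0-based half-open.
#' @return Non-negative FPKM value.
#' @export
region_fpkm <- function(track, chrom, start, end) {
  len <- end - start
  if (len <= 0) stop("zero-length region")
  total <- region_depth_sum(track, chrom, start, end)
  (total / track$read_length) / ((len / 1000) * (track$library_size / 1e6))
}

region_depth_sum <- function(track, chrom, start, end) {
  x <- track$depth[[chrom]]
  if (is.null(x)) stop("chromosome absent from coverage track: ", chrom)
  s <- max(start + 1L, 1L)
  e <- min(end, length(x))
  if (e < s) return(0)
  sum(S4Vectors::window(x, s, e))
}

#' Gene-level FPKM over the merged exonic footprint
#'
#' @param track A [coverage_track()].
#' @param gene A [gene_model()].
#' @return FPKM over all exonic bases of the gene.
#' @export
gene_fpkm <- function(track, gene) {
  ex <- merged_exonic_intervals(gene)
  len <- total_width(ex)
  if (len == 0L) stop("gene with zero exonic length: ", gene$gene_id)
  total <- sum(vapply(seq_len(nrow(ex)), function(i)
    region_depth_sum(track, gene$chrom, ex[i, 1L], ex[i, 2L]), 0))
  (total / track$read_length) / ((len / 1000) * (track$library_size / 1e6))
}

#' Expressed-gene filter configuration
#'
#' A gene counts as expressed in a tissue when its FPKM is strictly above
#' `fpkm_threshold` in at least `sample_fraction` of that tissue's samples.
#'
#' @param fpkm_threshold FPKM cutoff (strict inequality), default 1.
#' @param sample_fraction Minimum fraction of samples (at-least), default 0.25.
#' @export
expression_filter_config <- function(fpkm_threshold = 1.0,
                                     sample_fraction = 0.25) {
  stopifnot(fpkm_threshold > 0, sample_fraction > 0, sample_fraction <= 1)
  list(fpkm_threshold = fpkm_threshold, sample_fraction = sample_fraction)
}

#' Classify expressed genes from an FPKM matrix
#'
#' @param mat Numeric matrix, genes (rows) by samples (columns), FPKM.
#' @param config An [expression_filter_config()].
#' @return Character vector of expressed gene ids.
#' @export
classify_expressed <- function(mat, config = expression_filter_config()) {
  if (is.null(dim(mat)) || ncol(mat) == 0L) stop("empty sample set")
  if (any(mat < 0)) stop("negative FPKM in expression matrix")
  frac <- rowMeans(mat > config$fpkm_threshold)
  rownames(mat)[frac >= config$sample_fraction]
}

#' Compute a gene-by-sample FPKM matrix from coverage tracks
#'
#' @param tracks List of [coverage_track()].
#' @param genes List of [gene_model()].
#' @return Matrix with gene ids as rownames and sample ids as colnames.
#' @export
expression_from_tracks <- function(tracks, genes) {
  ids <- vapply(genes, `[[`, "", "gene_id")
  m <- vapply(tracks, function(tr)
    vapply(genes, function(g) gene_fpkm(tr, g), 0), numeric(length(genes)))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(ids, vapply(tracks, `[[`, "", "sample_id")))
  m
}

#' Read/write an expression matrix as TSV (genes x samples)
#'
#' @param path TSV path; first column gene id, header row of sample ids.
#' @export
read_expression_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "numeric"
  m
}

#' @rdname read_expression_matrix
#' @param mat Expression matrix.
#' @export
write_expression_matrix <- function(mat, path) {
  d <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
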