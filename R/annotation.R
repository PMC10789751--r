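#' Gene models, introns and termination sites
#'
#' A `GeneModel` is the package's unit of annotation: one gene locus with its
#' strand, genomic span, biotype and the exon structure of every isoform.
#' All coordinates are 0-based half-open (BED convention); GTF input/output
#' converts at the boundary.
#'
#' @param gene_id Character scalar, unique gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end Gene span, 0-based half-open.
#' @param isoforms List of exon interval matrices (columns `start`, `end`),
#'   one matrix per isoform, exons sorted and disjoint within an isoform.
#' @param gene_name Human-readable symbol (defaults to `gene_id`).
#' @param biotype Gene biotype string, e.g. `"protein_coding"`.
#' @return An object of class `GeneModel`.
#' @examples
#' g <- gene_model("g1", "chr1", "+", 0, 100, list(cbind(0, 100)))
#' tts(g)
#' @export
gene_model <- function(gene_id, chrom, strand, start, end, isoforms,
                       gene_name = gene_id, biotype = "other") {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  start <- as.integer(start); end <- as.integer(end)
  if (start >= end) stop("gene span must satisfy start < end")
  isoforms <- unname(lapply(isoforms, as_interval_matrix))
  if (length(isoforms) == 0L) stop("gene must have at least one isoform")
  for (iso in isoforms) {
    if (any(iso[, 1L] < start) || any(iso[, 2L] > end))
      stop("exon outside gene span for gene ", gene_id)
    if (nrow(iso) > 1L) {
      o <- order(iso[, 1L])
      if (!identical(o, seq_len(nrow(iso))))
        stop("exons within an isoform must be sorted for gene ", gene_id)
      if (any(iso[-1L, 1L] < iso[-nrow(iso), 2L]))
        stop("exons within an isoform must be disjoint for gene ", gene_id)
    }
  }
  structure(list(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
                 strand = strand, start = start, end = end,
                 biotype = biotype, isoforms = isoforms),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s) %s:%d-%d(%s) %s, %d isoform(s)\n",
              x$gene_id, x$gene_name, x$chrom, x$start, x$end, x$strand,
              x$biotype, length(x$isoforms)))
  invisible(x)
}

#' Transcription termination site of a gene
#'
#' The downstream-facing boundary of the gene span: `end` for plus-strand
#' genes, `start` for minus-strand genes (0-based half-open convention, so
#' the returned coordinate is the first base past the gene in transcription
#' direction).
#'
#' @param gene A [gene_model()].
#' @return Integer genomic position.
#' @export
tts <- function(gene) {
  if (gene$strand == "+") gene$end else gene$start
}

#' Merged exonic intervals of a gene
#'
#' Union of all exons over all isoforms, merged into sorted disjoint
#' intervals. This is the exonic footprint used for gene-level FPKM and for
#' intron derivation.
#'
#' @param gene A [gene_model()].
#' @return Interval matrix (columns `start`, `end`), 0-based half-open.
#' @export
merged_exonic_intervals <- function(gene) {
  merge_intervals(do.call(rbind, gene$isoforms))
}

#' Parse an Ensembl-dialect GTF into gene models
#'
#' Reads gene/transcript/exon features, groups exons into isoforms by
#' `transcript_id`, and converts the GTF's 1-based closed coordinates to the
#' package's 0-based half-open convention. Genes are returned in
#' deterministic (chrom, start, gene_id) order.
#'
#' @param path GTF file path.
#' @return List of [gene_model()] objects.
#' @export
parse_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(gr$type) || is.null(gr$gene_id))
    stop("GTF parse error: missing type or gene_id attributes in ", path)
  typ <- as.character(gr$type)
  genes_gr <- gr[typ == "gene"]
  exons_gr <- gr[typ == "exon"]
  if (length(exons_gr) == 0L) stop("GTF parse error: no exon features in ", path)
  if (is.null(exons_gr$transcript_id) || anyNA(exons_gr$transcript_id))
    stop("GTF parse error: exon feature without transcript_id in ", path)

  ex <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(exons_gr)),
    start = GenomicRanges::start(exons_gr) - 1L,
    end = GenomicRanges::end(exons_gr),
    strand = as.character(GenomicRanges::strand(exons_gr)),
    gene_id = as.character(exons_gr$gene_id),
    transcript_id = as.character(exons_gr$transcript_id),
    stringsAsFactors = FALSE)
  if (any(ex$start >= ex$end))
    stop("GTF validation error: exon with end <= start")

  span <- NULL
  if (length(genes_gr) > 0L) {
    span <- data.frame(
      gene_id = as.character(genes_gr$gene_id),
      chrom = as.character(GenomicRanges::seqnames(genes_gr)),
      start = GenomicRanges::start(genes_gr) - 1L,
      end = GenomicRanges::end(genes_gr),
      strand = as.character(GenomicRanges::strand(genes_gr)),
      gene_name = as.character(genes_gr$gene_name %||% genes_gr$gene_id),
      biotype = as.character(genes_gr$gene_biotype %||% rep("other", length(genes_gr))),
      stringsAsFactors = FALSE)
    span$gene_name[is.na(span$gene_name)] <- span$gene_id[is.na(span$gene_name)]
    span$biotype[is.na(span$biotype)] <- "other"
  }

  models <- lapply(split(ex, ex$gene_id), function(d) {
    isoforms <- lapply(split(d, d$transcript_id), function(t) {
      m <- cbind(start = t$start, end = t$end)
      m[order(m[, 1L]), , drop = FALSE]
    })
    isoforms <- isoforms[order(names(isoforms))]
    gid <- d$gene_id[1L]
    if (!is.null(span) && gid %in% span$gene_id) {
      s <- span[span$gene_id == gid, , drop = FALSE][1L, ]
      gene_model(gid, s$chrom, s$strand, s$start, s$end, isoforms,
                 gene_name = s$gene_name, biotype = s$biotype)
    } else {
      gene_model(gid, d$chrom[1L], d$strand[1L],
                 min(d$start), max(d$end), isoforms)
    }
  })
  ord <- order(vapply(models, `[[`, "", "chrom"),
               vapply(models, `[[`, 0L, "start"),
               vapply(models, `[[`, "", "gene_id"))
  unname(models[ord])
}

#' Write gene models as GTF
#'
#' Emits gene, transcript and exon features with `gene_id`, `transcript_id`,
#' `gene_name` and `gene_biotype` attributes (Ensembl dialect).
#'
#' @param genes List of [gene_model()].
#' @param path Output file path.
#' @export
write_gtf <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    n_iso <- length(g$isoforms)
    tx_ids <- sprintf("%s.t%d", g$gene_id, seq_len(n_iso))
    recs <- list(data.frame(chrom = g$chrom, start = g$start, end = g$end,
                            strand = g$strand, type = "gene",
                            gene_id = g$gene_id, transcript_id = NA_character_,
                            gene_name = g$gene_name, biotype = g$biotype,
                            stringsAsFactors = FALSE))
    for (i in seq_len(n_iso)) {
      iso <- g$isoforms[[i]]
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = g$chrom, start = min(iso[, 1L]), end = max(iso[, 2L]),
        strand = g$strand, type = "transcript", gene_id = g$gene_id,
        transcript_id = tx_ids[i], gene_name = g$gene_name,
        biotype = g$biotype, stringsAsFactors = FALSE)
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = g$chrom, start = iso[, 1L], end = iso[, 2L],
        strand = g$strand, type = "exon", gene_id = g$gene_id,
        transcript_id = tx_ids[i], gene_name = g$gene_name,
        biotype = g$biotype, stringsAsFactors = FALSE)
    }
    do.call(rbind, recs)
  })
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end),
                               strand = d$strand)
  gr$source <- "rtkit"
  gr$type <- d$type
  gr$gene_id <- d$gene_id
  gr$transcript_id <- d$transcript_id
  gr$gene_name <- d$gene_name
  gr$gene_biotype <- d$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write/read gene models as BED12
#'
#' One BED12 line per isoform; `name` encodes `gene_id|gene_name|biotype`
#' and the thick range carries the gene span, so that reading the file back
#' reconstructs the same gene models.
#'
#' @param genes List of [gene_model()].
#' @param path File path.
#' @return `read_bed12` returns a list of [gene_model()].
#' @export
write_bed12 <- function(genes, path) {
  recs <- unlist(lapply(genes, function(g) {
    lapply(g$isoforms, function(iso)
      list(chrom = g$chrom, start = min(iso[, 1L]), end = max(iso[, 2L]),
           strand = g$strand,
           name = paste(g$gene_id, g$gene_name, g$biotype, sep = "|"),
           thick_start = g$start, thick_end = g$end, iso = iso))
  }), recursive = FALSE)
  gr <- GenomicRanges::GRanges(
    vapply(recs, `[[`, "", "chrom"),
    IRanges::IRanges(vapply(recs, `[[`, 0L, "start") + 1L,
                     vapply(recs, `[[`, 0L, "end")),
    strand = vapply(recs, `[[`, "", "strand"))
  gr$name <- vapply(recs, `[[`, "", "name")
  gr$thick <- IRanges::IRanges(vapply(recs, `[[`, 0L, "thick_start") + 1L,
                               vapply(recs, `[[`, 0L, "thick_end"))
  gr$blocks <- IRanges::IRangesList(lapply(recs, function(r)
    IRanges::IRanges(r$iso[, 1L] - r$start + 1L, r$iso[, 2L] - r$start)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed12
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  key <- as.character(gr$name)
  models <- lapply(split(seq_along(gr), key), function(idx) {
    sub <- gr[idx]
    parts <- strsplit(key[idx[1L]], "|", fixed = TRUE)[[1L]]
    isoforms <- lapply(seq_along(sub), function(i) {
      off <- GenomicRanges::start(sub)[i] - 1L  # 0-based isoform start
      b <- sub$blocks[[i]]
      cbind(start = off + IRanges::start(b) - 1L, end = off + IRanges::end(b))
    })
    gene_model(parts[1L], as.character(GenomicRanges::seqnames(sub))[1L],
               as.character(GenomicRanges::strand(sub))[1L],
               IRanges::start(sub$thick)[1L] - 1L, IRanges::end(sub$thick)[1L],
               isoforms, gene_name = parts[2L], biotype = parts[3L])
  })
  ord <- order(vapply(models, `[[`, "", "chrom"),
               vapply(models, `[[`, 0L, "start"),
               vapply(models, `[[`, "", "gene_id"))
  unname(models[ord])
}

#' Build the intron table for a set of gene models
#'
#' For each gene, introns are the gaps between its merged exonic intervals
#' within the gene span; any sub-interval overlapping an exon of *any*
#' annotated gene (either strand, including nested or overlapping loci) is
#' then removed, mirroring the complement-of-all-exons construction. The
#' remaining pieces are indexed in transcription order (`index_from_start`)
#' and from the last intron (`index_from_end`).
#'
#' @param genes List of [gene_model()].
#' @return `data.frame` with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `index_from_start`, `index_from_end`, `length_bp`.
#' @export
build_intron_table <- function(genes) {
  # all-exon mask per chromosome
  exon_by_chrom <- list()
  for (g in genes) {
    ex <- merged_exonic_intervals(g)
    exon_by_chrom[[g$chrom]] <- rbind(exon_by_chrom[[g$chrom]], ex)
  }
  exon_by_chrom <- lapply(exon_by_chrom, merge_intervals)

  rows <- lapply(genes, function(g) {
    introns <- interval_gaps(merged_exonic_intervals(g), g$start, g$end)
    introns <- interval_subtract(introns, exon_by_chrom[[g$chrom]])
    n <- nrow(introns)
    if (n == 0L) return(NULL)
    # transcription order: left-to-right for +, right-to-left for -
    idx <- if (g$strand == "+") seq_len(n) else rev(seq_len(n))
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               start = introns[, 1L], end = introns[, 2L],
               index_from_start = idx, index_from_end = n + 1L - idx,
               length_bp = introns[, 2L] - introns[, 1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), index_from_start = integer(0),
                      index_from_end = integer(0), length_bp = integer(0))
  rownames(out) <- NULL
  out
}

#' Genome index: chromosome lengths
#'
#' @param lengths Named numeric vector, chromosome name -> length in bp.
#' @return Named integer vector validated as a genome index.
#' @export
genome_index <- function(lengths) {
  if (is.null(names(lengths)) || any(names(lengths) == ""))
    stop("genome index requires chromosome names")
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  stats::setNames(as.integer(lengths), names(lengths))
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a tab-separated file with columns chrom, length.
#' @return Named integer vector (see [genome_index()]).
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("chrom", "length"))
  genome_index(stats::setNames(d$length, d$chrom))
}

#' @rdname read_chrom_sizes
#' @param genome Named chromosome lengths.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(data.frame(names(genome), unname(genome)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# GRanges view of gene spans, for overlap machinery
genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    vapply(genes, `[[`, "", "chrom"),
    IRanges::IRanges(vapply(genes, `[[`, 0L, "start") + 1L,
                     vapply(genes, `[[`, 0L, "end")),
    strand = vapply(genes, `[[`, "", "strand"),
    gene_id = vapply(genes, `[[`, "", "gene_id"))
}
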