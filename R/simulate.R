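#' Synthetic dataset configuration
#'
#' The generator emulates the inputs of a readthrough study: a multi-gene
#' annotation on both strands, per-sample coverage with planted readthrough
#' tails of known length and level, planted intron retention, and
#' machine-readable ground truth. Defaults describe the reference study
#' conditions used by the package's end-to-end checks: 500 genes on 4
#' chromosomes, 3 samples, planted tails spanning the observed 2-60 kb
#' range at window coverages comfortably above the 0.15 FPKM calling
#' threshold, and intergenic spacing wide enough that neighboring tails
#' stay separable.
#'
#' @param rng_seed Integer seed; every generator is deterministic given it.
#' @param n_chromosomes,n_genes Layout size.
#' @param strand_minus_fraction Fraction of genes on the minus strand.
#' @param mean_introns Mean of the geometric intron-count distribution.
#' @param exon_length_range,intron_length_range Structural element sizes (bp).
#' @param intergenic_range Gap between consecutive genes (bp); the default
#'   guarantees two facing 60-kb tails cannot merge.
#' @param chrom_margin_bp Clearance at chromosome ends so edge tails fit.
#' @param rt_fraction Fraction of genes planted with a downstream tail.
#' @param und_fraction Fraction of planted-tail genes that also get an
#'   antisense neighbor inside the tail (exercises the UND filter).
#' @param tail_length_range,tail_fpkm_range Planted tail geometry/level.
#' @param gene_fpkm_meanlog,gene_fpkm_sdlog Log-normal gene expression.
#' @param min_rt_gene_fpkm Floor on the expression of tail-planted genes
#'   (readthrough is defined on expressed genes, so planted truth lives on
#'   robustly expressed hosts).
#' @param intron_depth_fraction Baseline intron depth as a fraction of the
#'   gene's exonic depth.
#' @param retention_multiplier Extra retention planted in RT genes'
#'   `retention_positions` introns.
#' @param retention_positions Position classes receiving the multiplier.
#' @param noise_depth Expected depth of the additive Poisson read noise
#'   floor (0 disables it).
#' @param n_samples,library_size,read_length Library parameters.
#' @param sample_jitter_sdlog Per-sample log-normal jitter on gene levels.
#' @param gc Genome GC content for sequence generation.
#' @return List of class `SimulationConfig`.
#' @export
sim_config <- function(rng_seed = 1L, n_chromosomes = 4L, n_genes = 500L,
                       strand_minus_fraction = 0.5, mean_introns = 4,
                       exon_length_range = c(150L, 400L),
                       intron_length_range = c(200L, 2000L),
                       intergenic_range = c(125000L, 145000L),
                       chrom_margin_bp = 70000L,
                       rt_fraction = 0.4, und_fraction = 0.1,
                       tail_length_range = c(2000L, 60000L),
                       tail_fpkm_range = c(0.3, 3),
                       gene_fpkm_meanlog = 1.5, gene_fpkm_sdlog = 0.8,
                       min_rt_gene_fpkm = 2.0,
                       intron_depth_fraction = 0.05,
                       retention_multiplier = 1,
                       retention_positions = "last",
                       noise_depth = 0,
                       n_samples = 3L, library_size = 2e7,
                       read_length = 100L, sample_jitter_sdlog = 0.05,
                       gc = 0.5) {
  cfg <- as.list(environment())
  stopifnot(rt_fraction >= 0, rt_fraction <= 1, und_fraction >= 0,
            und_fraction <= 1, n_genes >= 1, n_chromosomes >= 1,
            tail_length_range[1] >= 100,
            intergenic_range[1] > tail_length_range[2] + 1000)
  class(cfg) <- "SimulationConfig"
  cfg
}

# depth (x coverage) that yields a given FPKM for any region length
fpkm_to_depth <- function(fpkm, read_length, library_size) {
  fpkm * read_length * library_size / 1e9
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic annotation with planted readthrough truth
#'
#' Genes are laid out with wide intergenic gaps on both strands; a
#' `rt_fraction` of them is planted with a downstream tail whose length and
#' window-level FPKM are drawn from the configured ranges, and an
#' `und_fraction` of those receives a single-exon antisense neighbor placed
#' inside the tail so the ambiguity filter has true positives to find.
#' Planted truth status is RT when the planted tail meets the default
#' calling thresholds (length >= 2000 bp, window FPKM >= 0.15), NRT
#' otherwise, and UND for antisense-overlap hosts.
#'
#' @param config A [sim_config()].
#' @return List: `genes` (list of [gene_model()]), `truth` (`data.frame`),
#'   `genome` (named chromosome lengths).
#' @export
generate_annotation <- function(config) {
  with_seed(config$rng_seed, {
    n_per <- diff(floor(seq(0, config$n_genes,
                            length.out = config$n_chromosomes + 1L)))
    p_geom <- 1 / (1 + config$mean_introns)
    genes <- list(); truth <- list()
    as_counter <- 0L
    genome <- integer(0)

    for (ci in seq_len(config$n_chromosomes)) {
      chrom <- sprintf("chrS%d", ci)
      cursor <- config$chrom_margin_bp
      for (gi in seq_len(n_per[ci])) {
        gid <- sprintf("SIMG%05d", length(truth) + 1L)
        strand <- if (stats::runif(1) < config$strand_minus_fraction) "-" else "+"
        n_introns <- stats::rgeom(1, p_geom)
        n_exons <- n_introns + 1L
        exon_len <- sample(seq(config$exon_length_range[1L],
                               config$exon_length_range[2L]), n_exons,
                           replace = TRUE)
        intron_len <- if (n_introns > 0L)
          sample(seq(config$intron_length_range[1L],
                     config$intron_length_range[2L]), n_introns,
                 replace = TRUE) else integer(0)
        starts <- cursor + c(0L, cumsum(exon_len[-n_exons] + intron_len))
        exons <- cbind(start = starts, end = starts + exon_len)
        span_end <- exons[n_exons, 2L]
        isoforms <- list(exons)
        # occasional exon-skipping isoform (subset, so the merged model
        # and the intron truth are unchanged)
        if (n_exons >= 3L && stats::runif(1) < 0.3) {
          skip <- sample(2:(n_exons - 1L), 1L)
          isoforms[[2L]] <- exons[-skip, , drop = FALSE]
        }
        gene_fpkm <- stats::rlnorm(1, config$gene_fpkm_meanlog,
                                   config$gene_fpkm_sdlog)

        planted <- stats::runif(1) < config$rt_fraction
        tail_len <- tail_fpkm <- NA_real_
        tail_start <- tail_end <- NA_integer_
        status <- "NRT"; antisense_of <- NA_character_
        if (planted) {
          gene_fpkm <- max(gene_fpkm, config$min_rt_gene_fpkm)
          tail_len <- round(stats::runif(1, config$tail_length_range[1L],
                                         config$tail_length_range[2L]))
          tail_fpkm <- stats::runif(1, config$tail_fpkm_range[1L],
                                    config$tail_fpkm_range[2L])
          if (strand == "+") {
            tail_start <- span_end; tail_end <- span_end + tail_len
          } else {
            tail_start <- cursor - tail_len; tail_end <- cursor
          }
          status <- if (tail_len >= 2000 && tail_fpkm >= 0.15) "RT" else "NRT"
        }

        genes[[gid]] <- gene_model(gid, chrom, strand, cursor, span_end,
                                   isoforms, biotype = "protein_coding")
        truth[[gid]] <- data.frame(
          gene_id = gid, chrom = chrom, strand = strand,
          start = cursor, end = span_end, status = status,
          planted_tail = planted, tail_start = tail_start,
          tail_end = tail_end, tail_length_bp = if (planted) tail_len else 0,
          tail_fpkm = if (planted) tail_fpkm else 0,
          gene_fpkm = gene_fpkm,
          retention_multiplier = 1,
          antisense_of = antisense_of, n_introns = n_introns,
          stringsAsFactors = FALSE)

        # antisense neighbor inside the planted tail -> host becomes UND
        if (planted && status == "RT" &&
            stats::runif(1) < config$und_fraction) {
          truth[[gid]]$status <- "UND"
          as_counter <- as_counter + 1L
          as_id <- sprintf("SIMAS%04d", as_counter)
          off <- round(0.3 * tail_len)
          as_width <- 1000L
          if (strand == "+") {
            as_start <- span_end + off
          } else {
            as_start <- cursor - off - as_width
          }
          as_strand <- if (strand == "+") "-" else "+"
          genes[[as_id]] <- gene_model(
            as_id, chrom, as_strand, as_start, as_start + as_width,
            list(cbind(as_start, as_start + as_width)), biotype = "lncRNA")
          truth[[as_id]] <- data.frame(
            gene_id = as_id, chrom = chrom, strand = as_strand,
            start = as_start, end = as_start + as_width, status = "NRT",
            planted_tail = FALSE, tail_start = NA_integer_,
            tail_end = NA_integer_, tail_length_bp = 0, tail_fpkm = 0,
            gene_fpkm = stats::rlnorm(1, config$gene_fpkm_meanlog,
                                      config$gene_fpkm_sdlog),
            retention_multiplier = 1,
            antisense_of = gid, n_introns = 0L,
            stringsAsFactors = FALSE)
        }
        cursor <- span_end + round(stats::runif(1, config$intergenic_range[1L],
                                                config$intergenic_range[2L]))
      }
      genome[chrom] <- cursor + config$chrom_margin_bp
    }
    truth <- do.call(rbind, truth)
    truth$retention_multiplier[truth$status == "RT"] <-
      config$retention_multiplier
    rownames(truth) <- NULL
    ord <- order(vapply(genes, `[[`, "", "chrom"),
                 vapply(genes, `[[`, 0L, "start"),
                 vapply(genes, `[[`, "", "gene_id"))
    list(genes = unname(genes[ord]), truth = truth,
         genome = genome_index(genome))
  })
}

#' Generate per-sample coverage tracks for a synthetic annotation
#'
#' Exonic depth per gene is the truth FPKM with per-sample log-normal
#' jitter; introns get `intron_depth_fraction` of the exonic depth (times
#' the retention multiplier for the configured positions of RT genes);
#' planted tails get a constant plateau at exactly the planted window FPKM
#' so threshold behavior is exact; an optional Poisson read-noise floor
#' adds uniform background reads.
#'
#' @param ann Output of [generate_annotation()].
#' @param config The same [sim_config()].
#' @return List of [coverage_track()], one per sample.
#' @export
generate_coverage <- function(ann, config) {
  truth <- ann$truth
  tr_by_id <- truth[match(vapply(ann$genes, `[[`, "", "gene_id"),
                          truth$gene_id), ]
  lapply(seq_len(config$n_samples), function(s) {
    with_seed(config$rng_seed + 1000L + s, {
      pieces <- vector("list", length(ann$genes) * 3L)
      k <- 0L
      for (i in seq_along(ann$genes)) {
        g <- ann$genes[[i]]
        tt <- tr_by_id[i, ]
        fpkm_s <- tt$gene_fpkm * stats::rlnorm(1, 0, config$sample_jitter_sdlog)
        d_ex <- fpkm_to_depth(fpkm_s, config$read_length, config$library_size)
        ex <- merged_exonic_intervals(g)
        k <- k + 1L
        pieces[[k]] <- data.frame(chrom = g$chrom, start = ex[, 1L],
                                  end = ex[, 2L], depth = d_ex)
        introns <- interval_gaps(ex, g$start, g$end)
        if (nrow(introns) > 0L) {
          n <- nrow(introns)
          idx <- if (g$strand == "+") seq_len(n) else rev(seq_len(n))
          pos <- rep("internal", n)
          pos[idx == 1L] <- "first"; pos[idx == 2L] <- "second"
          pos[n + 1L - idx == 2L] <- ifelse(pos[n + 1L - idx == 2L] != "internal",
                                            pos[n + 1L - idx == 2L], "second_last")
          pos[n + 1L - idx == 1L] <- "last"
          mult <- ifelse(pos %in% config$retention_positions,
                         tt$retention_multiplier, 1)
          k <- k + 1L
          pieces[[k]] <- data.frame(chrom = g$chrom, start = introns[, 1L],
                                    end = introns[, 2L],
                                    depth = d_ex * config$intron_depth_fraction * mult)
        }
        if (isTRUE(tt$planted_tail)) {
          k <- k + 1L
          pieces[[k]] <- data.frame(
            chrom = g$chrom, start = tt$tail_start, end = tt$tail_end,
            depth = fpkm_to_depth(tt$tail_fpkm, config$read_length,
                                  config$library_size))
        }
      }
      d <- do.call(rbind, pieces[seq_len(k)])
      gr <- GenomicRanges::GRanges(d$chrom,
                                   IRanges::IRanges(d$start + 1L, d$end))
      score <- d$depth
      if (config$noise_depth > 0) {
        noise <- lapply(names(ann$genome), function(ch) {
          len <- ann$genome[[ch]]
          n_reads <- stats::rpois(1, config$noise_depth * len /
                                    config$read_length)
          if (n_reads == 0L) return(NULL)
          st <- sample.int(max(len - config$read_length, 1L), n_reads,
                           replace = TRUE)
          GenomicRanges::GRanges(ch, IRanges::IRanges(st, width = config$read_length))
        })
        noise <- do.call(c, Filter(Negate(is.null), noise))
        if (!is.null(noise) && length(noise) > 0L) {
          gr <- c(gr, noise)
          score <- c(score, rep(1, length(noise)))
        }
      }
      GenomeInfoDb::seqlevels(gr) <- names(ann$genome)
      GenomeInfoDb::seqlengths(gr) <- unname(ann$genome)
      cov <- GenomicRanges::coverage(gr, weight = score)
      # weighted coverage can leave values like -1e-15 from float summation
      cov <- methods::as(lapply(cov, function(x) {
        v <- S4Vectors::runValue(x)
        v[v < 0] <- 0
        S4Vectors::runValue(x) <- v
        x
      }), "RleList")
      coverage_track(cov[names(ann$genome)], config$library_size,
                     config$read_length, sample_id = sprintf("s%02d", s))
    })
  })
}

#' Generate a genome sequence with optional composition biases
#'
#' I.i.d. nucleotides at the configured GC content. `hexamer_bias` scales
#' the occurrence count of chosen k-mers inside the TTS +/- `flank_bp`
#' windows of a gene group (occurrences are destroyed or planted and the
#' windows re-scanned until the target count is met). `seed_sites` plants
#' an exact number of miRNA seed-match sites inside planted tails, verified
#' by re-scanning the extracted region (regenerating on spurious
#' collisions). Both operate in the gene's transcription orientation, i.e.
#' patterns are reverse-complemented before editing minus-strand loci.
#'
#' @param ann Output of [generate_annotation()].
#' @param config A [sim_config()].
#' @param hexamer_bias Optional list with `gene_ids`, `kmers`, `factor`
#'   (target count = round(factor * current count)) and `flank_bp`.
#' @param seed_sites Optional `data.frame(gene_id, pattern, n_sites)`;
#'   genes must have planted tails.
#' @return Named `DNAStringSet`. The achieved seed-site counts are stored
#'   in `metadata(result)$seed_sites`.
#' @export
generate_genome_sequence <- function(ann, config, hexamer_bias = NULL,
                                     seed_sites = NULL) {
  with_seed(config$rng_seed + 2000L, {
    probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
               G = config$gc / 2, T = (1 - config$gc) / 2)
    seqs <- vapply(names(ann$genome), function(ch) {
      paste(sample(names(probs), ann$genome[[ch]], replace = TRUE,
                   prob = probs), collapse = "")
    }, "")

    genes_by_id <- stats::setNames(ann$genes,
                                   vapply(ann$genes, `[[`, "", "gene_id"))

    if (!is.null(hexamer_bias)) {
      fl <- hexamer_bias$flank_bp %||% 500L
      for (gid in hexamer_bias$gene_ids) {
        g <- genes_by_id[[gid]]
        t0 <- tts(g)
        s <- max(t0 - fl, 0L); e <- min(t0 + fl, ann$genome[[g$chrom]])
        win <- substr(seqs[[g$chrom]], s + 1L, e)
        for (km in hexamer_bias$kmers) {
          pat <- if (g$strand == "-")
            as.character(Biostrings::reverseComplement(Biostrings::DNAString(km)))
          else km
          win <- scale_kmer_occurrences(win, pat, hexamer_bias$factor, probs)
        }
        substr(seqs[[g$chrom]], s + 1L, e) <- win
      }
    }

    achieved <- NULL
    if (!is.null(seed_sites)) {
      truth <- ann$truth
      achieved <- seed_sites
      achieved$achieved <- NA_integer_
      for (i in seq_len(nrow(seed_sites))) {
        gid <- seed_sites$gene_id[i]
        g <- genes_by_id[[gid]]
        tt <- truth[truth$gene_id == gid, ]
        if (!isTRUE(tt$planted_tail)) stop("seed sites require a planted tail: ", gid)
        s <- tt$tail_start; e <- tt$tail_end
        pat_sense <- seed_sites$pattern[i]
        pat_genomic <- if (g$strand == "-")
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(pat_sense)))
        else pat_sense
        n <- seed_sites$n_sites[i]
        ok <- FALSE
        for (try in 1:20) {
          region <- paste(sample(names(probs), e - s, replace = TRUE,
                                 prob = probs), collapse = "")
          L <- nchar(pat_genomic)
          slots <- floor((e - s) / (L + 2L))
          if (n > slots) stop("tail too short for requested seed sites: ", gid)
          at <- sort(sample(slots, n)) - 1L
          for (a in at) {
            substr(region, a * (L + 2L) + 1L, a * (L + 2L) + L) <- pat_genomic
          }
          if (scan_seed_matches(region, pat_genomic) == n) { ok <- TRUE; break }
        }
        if (!ok) stop("could not plant exact seed-site count for ", gid)
        substr(seqs[[g$chrom]], s + 1L, e) <- region
        achieved$achieved[i] <- n
      }
    }

    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(ann$genome)
    S4Vectors::metadata(out)$seed_sites <- achieved
    out
  })
}

# destroy or plant occurrences of `pat` in `win` until a scaled target
# count is reached; depletion thins binomially so the expected count is
# factor * current even when windows hold single occurrences
scale_kmer_occurrences <- function(win, pat, factor, probs) {
  count0 <- length(Biostrings::matchPattern(pat, Biostrings::DNAString(win)))
  target <- if (factor < 1) stats::rbinom(1, count0, factor)
  else round(factor * count0)
  guard <- 0L
  repeat {
    hits <- Biostrings::matchPattern(pat, Biostrings::DNAString(win))
    n <- length(hits)
    if (n == target || guard > 10L * (count0 + target + 10L)) break
    guard <- guard + 1L
    if (n > target) {
      i <- sample(n, 1L)
      st <- Biostrings::start(hits)[i]
      repl <- paste(sample(names(probs), nchar(pat), replace = TRUE,
                           prob = probs), collapse = "")
      substr(win, st, st + nchar(pat) - 1L) <- repl
    } else {
      st <- sample(nchar(win) - nchar(pat) + 1L, 1L)
      substr(win, st, st + nchar(pat) - 1L) <- pat
    }
  }
  win
}

#' Generate peaks over region sets with group-dependent presence rates
#'
#' Each region receives one peak with the probability configured for its
#' status group; the peak is a fixed-width interval placed uniformly inside
#' the region.
#'
#' @param regions Output of [build_flank_regions()].
#' @param presence_prob Named numeric vector, status -> probability (or a
#'   single probability for all).
#' @param config A [sim_config()] (only the seed is used).
#' @param peak_width Peak width in bp.
#' @return List: `peaks` (`data.frame(chrom, start, end)`) and `truth`
#'   (regions with a logical `has_peak`).
#' @export
generate_peaks <- function(regions, presence_prob, config, peak_width = 200L) {
  with_seed(config$rng_seed + 3000L, {
    prob <- if (length(presence_prob) == 1L && is.null(names(presence_prob)))
      rep(presence_prob, nrow(regions))
    else unname(presence_prob[regions$status])
    has <- stats::runif(nrow(regions)) < prob
    w <- pmin(peak_width, regions$end - regions$start)
    off <- floor(stats::runif(nrow(regions)) *
                   (regions$end - regions$start - w + 1L))
    peaks <- data.frame(chrom = regions$chrom[has],
                        start = (regions$start + off)[has],
                        end = (regions$start + off + w)[has],
                        stringsAsFactors = FALSE)
    truth <- regions
    truth$has_peak <- has
    list(peaks = peaks, truth = truth)
  })
}

#' Generate an expression matrix with known detection fractions
#'
#' Each gene is assigned an exact detection fraction `k/n_samples` (k drawn
#' uniformly from 0..n_samples): k samples get FPKM strictly above 1, the
#' rest strictly below, so the expressed-gene filter's recovery can be
#' checked exactly.
#'
#' @param config A [sim_config()] (uses `n_genes`, `n_samples`, seed).
#' @return List: `matrix` (genes x samples FPKM) and `truth`
#'   (`data.frame(gene_id, detection_fraction)`).
#' @export
generate_expression_matrix <- function(config) {
  with_seed(config$rng_seed + 4000L, {
    n <- config$n_samples
    if (n < 4L) stop("need n_samples >= 4")
    ids <- sprintf("SIMG%05d", seq_len(config$n_genes))
    m <- matrix(0, config$n_genes, n,
                dimnames = list(ids, sprintf("s%02d", seq_len(n))))
    k <- sample(0:n, config$n_genes, replace = TRUE)
    for (i in seq_len(config$n_genes)) {
      hi <- sample(n, k[i])
      m[i, hi] <- stats::runif(k[i], 1.5, 20)
      m[i, setdiff(seq_len(n), hi)] <- stats::runif(n - k[i], 0, 0.99)
    }
    list(matrix = m,
         truth = data.frame(gene_id = ids, detection_fraction = k / n,
                            stringsAsFactors = FALSE))
  })
}

#' Write a full synthetic dataset to disk
#'
#' Emits GTF, chrom.sizes, one bedGraph per sample and the truth table,
#' and returns the in-memory objects alongside the paths.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return List: `ann`, `tracks`, `paths`.
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config)
  tracks <- generate_coverage(ann, config)
  paths <- list(
    gtf = file.path(out_dir, "annotation.gtf"),
    chrom_sizes = file.path(out_dir, "genome.chrom.sizes"),
    truth = file.path(out_dir, "truth.tsv"),
    coverage = vapply(tracks, function(tr)
      file.path(out_dir, paste0(tr$sample_id, ".bedGraph")), ""))
  write_gtf(ann$genes, paths$gtf)
  write_chrom_sizes(ann$genome, paths$chrom_sizes)
  utils::write.table(ann$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (i in seq_along(tracks)) write_bedgraph(tracks[[i]], paths$coverage[i])
  list(ann = ann, tracks = tracks, paths = paths)
}
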