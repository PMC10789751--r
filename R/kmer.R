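#' Hexamer enrichment analysis around termination sites
#'
#' The sequence composition flanking the TTS differs between readthrough
#' and non-readthrough genes (readthrough gene ends are depleted of GC-rich
#' hexamers). The analysis extracts TTS +/- `flank_bp` sequences, counts
#' all k-mers in expression-matched subsamples of the two groups, scores
#' each k-mer as `log2` of the ratio of occurrence counts, assigns
#' significance by a two-sided Welch t-test across the per-permutation
#' count distributions, and classifies k-mers on the volcano thresholds.
#'
#' @param k K-mer length (6 for hexamers).
#' @param flank_bp Flank on each side of the TTS.
#' @param p_threshold FDR threshold for a volcano call.
#' @param score_threshold Absolute log2-ratio threshold for a volcano call.
#' @param pseudocount Added to both counts in the score so the ratio is
#'   defined at zero counts.
#' @export
volcano_config <- function(k = 6L, flank_bp = 500L, p_threshold = 0.001,
                           score_threshold = 0.58, pseudocount = 1.0) {
  stopifnot(k >= 1, flank_bp >= 1, p_threshold > 0, score_threshold > 0,
            pseudocount >= 0)
  list(k = as.integer(k), flank_bp = as.integer(flank_bp),
       p_threshold = p_threshold, score_threshold = score_threshold,
       pseudocount = pseudocount)
}

# uppercase and collapse every non-ACGT symbol to N
sanitize_dna <- function(x) {
  x <- toupper(as.character(x))
  gsub("[^ACGT]", "N", x)
}

#' Extract the TTS-flanking sequence of a gene
#'
#' Fetches the genomic window `[TTS - flank_bp, TTS + flank_bp)`, truncated
#' at chromosome edges, and reverse-complements it for minus-strand genes
#' so position 1 is 5'-most in transcription direction.
#'
#' @param gene A [gene_model()].
#' @param genome A named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param flank_bp Flank size in bp.
#' @return List: `gene_id`, `chrom`, `start`, `end` (genomic window,
#'   0-based half-open) and `sequence` (character, sense-strand oriented).
#' @export
extract_tts_flank <- function(gene, genome, flank_bp = 500L) {
  if (!gene$chrom %in% names(genome))
    stop("chromosome missing from genome: ", gene$chrom)
  chrom_seq <- genome[[gene$chrom]]
  len <- if (methods::is(chrom_seq, "DNAString")) length(chrom_seq) else nchar(chrom_seq)
  t0 <- tts(gene)
  s <- max(t0 - flank_bp, 0L)
  e <- min(t0 + flank_bp, len)
  seq <- if (methods::is(chrom_seq, "DNAString")) {
    as.character(Biostrings::subseq(chrom_seq, s + 1L, e))
  } else substr(chrom_seq, s + 1L, e)
  if (gene$strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      sanitize_dna(seq))))
  }
  list(gene_id = gene$gene_id, chrom = gene$chrom, start = s, end = e,
       sequence = sanitize_dna(seq))
}

#' Count overlapping k-mer occurrences in a set of sequences
#'
#' Every window of length `k` at stride 1 is counted; windows containing N
#' contribute to no k-mer. Counts are summed over all sequences and all
#' `4^k` k-mers are reported (absent ones as 0).
#'
#' @param sequences Character vector of DNA sequences.
#' @param k K-mer length.
#' @return Named integer vector over all k-mers in lexicographic order.
#' @export
count_kmers <- function(sequences, k) {
  stopifnot(k >= 1)
  m <- kmer_count_matrix(sequences, k)
  colSums(m)
}

# per-sequence k-mer count matrix (sequences x 4^k), the workhorse that
# lets the permutation test reuse counts across subsamples
kmer_count_matrix <- function(sequences, k) {
  ss <- Biostrings::DNAStringSet(sanitize_dna(sequences))
  Biostrings::oligonucleotideFrequency(ss, width = k, step = 1)
}

#' K-mer enrichment score
#'
#' `log2((count_rt + pseudocount) / (count_nrt + pseudocount))`.
#'
#' @param count_rt,count_nrt Occurrence counts (vectorized).
#' @param pseudocount Pseudocount guarding zero counts.
#' @return Log2 ratio(s).
#' @export
kmer_score <- function(count_rt, count_nrt, pseudocount = 1.0) {
  if (any(count_rt < 0) || any(count_nrt < 0)) stop("negative counts")
  log2((count_rt + pseudocount) / (count_nrt + pseudocount))
}

#' Permutation k-mer enrichment test between RT and NRT flank sequences
#'
#' For each of `matching$n_permutations` expression-matched subsamples,
#' total k-mer counts are computed for the RT and the NRT side. Per k-mer,
#' the score is computed from counts pooled across permutations, the
#' p-value from a two-sided Welch t-test between the two permutation count
#' vectors, and the volcano call from the FDR-adjusted p-value and the
#' score thresholds.
#'
#' @param rt_seqs,nrt_seqs Named character vectors of flank sequences
#'   (names are gene ids).
#' @param rt_expr,nrt_expr Named expression vectors for the same genes.
#' @param matching A [matching_config()] (requires `n_permutations >= 2`).
#' @param config A [volcano_config()].
#' @return `data.frame` ordered by k-mer: `kmer`, `count_rt`, `count_nrt`,
#'   `score`, `p_value`, `fdr`, `call` in `{enriched, depleted, ns}`.
#' @export
kmer_permutation_test <- function(rt_seqs, nrt_seqs, rt_expr, nrt_expr,
                                  matching, config = volcano_config()) {
  if (matching$n_permutations < 2L)
    stop("k-mer permutation test requires n_permutations >= 2")
  rt_expr <- rt_expr[names(rt_seqs)]
  nrt_expr <- nrt_expr[names(nrt_seqs)]
  if (anyNA(rt_expr) || anyNA(nrt_expr))
    stop("expression missing for some sequences")

  m_rt <- kmer_count_matrix(rt_seqs, config$k)
  m_nrt <- kmer_count_matrix(nrt_seqs, config$k)
  rownames(m_rt) <- names(rt_seqs)
  rownames(m_nrt) <- names(nrt_seqs)

  sub <- expression_matched_subsamples(rt_expr, nrt_expr, matching)
  nperm <- matching$n_permutations
  nk <- ncol(m_rt)
  counts_rt <- matrix(0, nperm, nk)
  counts_nrt <- matrix(0, nperm, nk)
  for (p in seq_len(nperm)) {
    d <- sub[sub$perm_index == p, ]
    counts_rt[p, ] <- colSums(m_rt[d$rt_gene, , drop = FALSE])
    counts_nrt[p, ] <- colSums(m_nrt[d$nrt_gene, , drop = FALSE])
  }

  tot_rt <- colSums(counts_rt)
  tot_nrt <- colSums(counts_nrt)
  score <- kmer_score(tot_rt, tot_nrt, config$pseudocount)
  p <- welch_t_columns(counts_rt, counts_nrt)
  fdr <- bh_fdr(p)
  call <- rep("ns", nk)
  call[fdr <= config$p_threshold & score >= config$score_threshold] <- "enriched"
  call[fdr <= config$p_threshold & score <= -config$score_threshold] <- "depleted"
  data.frame(kmer = colnames(m_rt), count_rt = tot_rt, count_nrt = tot_nrt,
             score = score, p_value = p, fdr = fdr, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

# vectorized two-sided Welch t-test over matched columns of two matrices
welch_t_columns <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- (colSums(a^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(b^2) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(1, length(m1))
  ok <- se2 > 0
  t <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * stats::pt(-abs(t), df)
  # zero variance on both sides but different means: maximally significant
  p[!ok & m1 != m2] <- 0
  p
}
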