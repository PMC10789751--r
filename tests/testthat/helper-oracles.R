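# Independent brute-force oracles and tiny fixture builders. Everything here
# deliberately avoids the package's own code paths (per-base loops, quadratic
# scans, direct formula evaluation) so the tests compare two routes.

make_gene <- function(id, chrom, strand, exons, start = NULL, end = NULL,
                      biotype = "protein_coding") {
  ex <- matrix(as.integer(unlist(exons)), ncol = 2, byrow = TRUE)
  gene_model(id, chrom, strand,
             start %||% min(ex[, 1]), end %||% max(ex[, 2]),
             list(ex), biotype = biotype)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coverage track from dense per-base vectors
dense_track <- function(depths, library_size = 1e6, read_length = 100,
                        sample_id = "t") {
  coverage_track(depths, library_size, read_length, sample_id)
}

# per-base membership union of exon interval lists (0-based half-open)
oracle_union <- function(interval_lists, limit) {
  covered <- logical(limit)
  for (m in interval_lists) {
    for (i in seq_len(nrow(m))) {
      covered[(m[i, 1] + 1):m[i, 2]] <- TRUE
    }
  }
  covered
}

# interval matrix -> per-base logical
intervals_to_mask <- function(m, limit) {
  mask <- logical(limit)
  if (nrow(m) > 0) {
    for (i in seq_len(nrow(m))) mask[(m[i, 1] + 1):m[i, 2]] <- TRUE
  }
  mask
}

# quadratic k-mer scan with N-window skipping
oracle_count_kmers <- function(seqs, k) {
  counts <- new.env()
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) next
    for (i in 1:(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      counts[[w]] <- (counts[[w]] %||% 0L) + 1L
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) integer(0) else out
}

oracle_scan_pattern <- function(s, pat) {
  n <- nchar(s); k <- nchar(pat)
  if (n < k) return(0L)
  sum(vapply(1:(n - k + 1), function(i) substr(s, i, i + k - 1) == pat, FALSE))
}

# exact two-sided Fisher p by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b          # group size
  n_on <- a + c_      # chromosome total
  N <- a + b + c_ + d
  probs <- stats::dhyper(0:min(m, n_on), n_on, N - n_on, m)
  p_obs <- stats::dhyper(a, n_on, N - n_on, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force rolling-window scan on a dense depth vector (plus strand)
oracle_window_scan <- function(depth, tts0, window, min_fpkm, max_tail,
                               library_size, read_length) {
  len <- 0
  pos <- tts0
  chrom_len <- length(depth)
  while (len < max_tail) {
    e <- min(pos + window, chrom_len, tts0 + max_tail)
    if (e <= pos) break
    s_depth <- sum(depth[(pos + 1):e])
    fpkm <- (s_depth / read_length) / (((e - pos) / 1000) * (library_size / 1e6))
    if (fpkm < min_fpkm) break
    len <- len + (e - pos)
    pos <- e
  }
  len
}

random_dna <- function(n, len, gc = 0.5, with_n = 0) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    s <- sample(names(p), len, replace = TRUE, prob = p)
    if (with_n > 0) s[sample(len, min(with_n, len))] <- "N"
    paste(s, collapse = "")
  }, "")
}
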