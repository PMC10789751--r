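#' miRNA seed patterns and sponge prediction
#'
#' The seed of a mature miRNA is nucleotides 2-9 (1-based) of its sequence;
#' the exact-match target site scanned on a transcript's sense strand is
#' the DNA reverse complement of that seed. Readthrough tails extend the
#' sequence available for such sites, so RT genes whose tails carry many
#' sites for one miRNA are candidate competing-endogenous-RNA sponges.
#'
#' @param path FASTA of mature miRNA sequences (RNA alphabet; T tolerated
#'   and treated as U).
#' @return Named character vector, miRNA id -> RNA sequence.
#' @export
read_mirna_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- chartr("tT", "uU", as.character(ss))
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) stop("invalid miRNA alphabet in: ",
                     paste(names(ss)[bad], collapse = ","))
  stats::setNames(seqs, sub("\\s.*", "", names(ss)))
}

#' 8-nt seed-match pattern of a mature miRNA
#'
#' Takes seed positions 2-9 (1-based, inclusive) of the mature sequence,
#' reverse-complements under RNA pairing and transcribes U to T; the result
#' is the DNA string matched on the target's sense strand.
#'
#' @param sequence Mature miRNA sequence (RNA, length >= 9).
#' @return 8-character DNA pattern.
#' @export
seed_pattern <- function(sequence) {
  sequence <- toupper(chartr("tT", "uU", sequence))
  if (nchar(sequence) < 9L) stop("mature miRNA shorter than 9 nt")
  if (grepl("[^ACGU]", sequence)) stop("invalid miRNA alphabet")
  seed <- substr(sequence, 2L, 9L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(seed)))
  chartr("U", "T", rc)
}

#' Count exact seed matches in a DNA sequence
#'
#' Counts possibly overlapping exact occurrences at stride 1; windows with
#' N never match.
#'
#' @param sequence DNA string.
#' @param pattern 8-nt DNA pattern from [seed_pattern()].
#' @return Integer count.
#' @export
scan_seed_matches <- function(sequence, pattern) {
  Biostrings::countPattern(pattern, Biostrings::DNAString(
    sanitize_dna(sequence)), fixed = TRUE)
}

#' Seed-match counts and densities over a set of regions
#'
#' @param region_seqs Named character vector of region sequences
#'   (names are region ids, e.g. gene ids).
#' @param patterns Named character vector of seed patterns
#'   (names are miRNA ids), e.g. from [seed_pattern()].
#' @return `data.frame(region_id, mirna_id, region_length_bp, count,
#'   density)` with `density = count / region_length_bp`.
#' @export
seed_match_table <- function(region_seqs, patterns) {
  seqs <- Biostrings::DNAStringSet(sanitize_dna(region_seqs))
  names(seqs) <- names(region_seqs)
  rows <- lapply(names(patterns), function(m) {
    counts <- Biostrings::vcountPattern(patterns[[m]], seqs, fixed = TRUE)
    data.frame(region_id = names(seqs), mirna_id = m,
               region_length_bp = Biostrings::width(seqs),
               count = counts,
               density = counts / Biostrings::width(seqs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify putative miRNA sponges
#'
#' RT genes whose tail carries at least `threshold` exact seed matches for
#' a miRNA are called putative sponges of that miRNA; a gene may sponge
#' several miRNAs.
#'
#' @param tail_counts `data.frame(region_id, mirna_id, count)` computed on
#'   RT tails (see [seed_match_table()]).
#' @param threshold Minimum site count, default 20.
#' @return `data.frame(gene_id, mirna_id, site_count, threshold)`.
#' @export
classify_sponges <- function(tail_counts, threshold = 20L) {
  d <- tail_counts[tail_counts$count >= threshold, , drop = FALSE]
  out <- data.frame(gene_id = d$region_id, mirna_id = d$mirna_id,
                    site_count = d$count, threshold = threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare miRNA site load between RT tails and last exons
#'
#' Counts and densities are first averaged per gene across miRNAs (and
#' across tissues when the input spans several); the per-gene tail and
#' last-exon vectors are then compared with [mann_whitney_cohen()], once
#' for counts and once for densities.
#'
#' @param results `data.frame` with `region_id` (gene), `region_type`
#'   (`"tail"` or `"last_exon"`), `count`, `density` (rows may repeat per
#'   miRNA/tissue).
#' @return List with elements `count` and `density`, each a
#'   [mann_whitney_cohen()] result.
#' @export
compare_tail_vs_last_exon <- function(results) {
  per_gene <- function(type, what) {
    d <- results[results$region_type == type, ]
    tapply(d[[what]], d$region_id, mean)
  }
  tc <- per_gene("tail", "count"); ec <- per_gene("last_exon", "count")
  genes <- intersect(names(tc), names(ec))
  if (length(genes) < 2L) stop("need both regions quantified for >= 2 genes")
  missing_region <- union(setdiff(names(tc), names(ec)),
                          setdiff(names(ec), names(tc)))
  if (length(missing_region) > 0L)
    stop("gene missing one region: ", paste(missing_region, collapse = ","))
  td <- per_gene("tail", "density"); ed <- per_gene("last_exon", "density")
  list(count = mann_whitney_cohen(unname(tc[genes]), unname(ec[genes])),
       density = mann_whitney_cohen(unname(td[genes]), unname(ed[genes])))
}

#' Extract the last exon of a gene (merged model)
#'
#' The 3'-most exon of the merged exonic intervals: the rightmost for plus
#' strand genes, the leftmost for minus strand.
#'
#' @param gene A [gene_model()].
#' @return Interval matrix with one row.
#' @export
last_exon <- function(gene) {
  ex <- merged_exonic_intervals(gene)
  if (gene$strand == "+") ex[nrow(ex), , drop = FALSE] else ex[1L, , drop = FALSE]
}
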