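# small, fast configurations for generator checks
small_cfg <- function(rng_seed = 5, ...) {
  sim_config(rng_seed = rng_seed, n_chromosomes = 2, n_genes = 40,
             n_samples = 4, intergenic_range = c(12000L, 15000L),
             chrom_margin_bp = 12000L, tail_length_range = c(2000L, 8000L),
             ...)
}

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_cfg()
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  t1 <- generate_coverage(a1, cfg)
  t2 <- generate_coverage(a2, cfg)
  expect_identical(t1, t2)
  expect_false(identical(a1, generate_annotation(small_cfg(rng_seed = 6))))

  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_dataset(cfg, d1); s2 <- simulate_dataset(cfg, d2)
  # data lines byte-identical (header carries a date stamp)
  strip <- function(p) grep("^#", readLines(p), value = TRUE, invert = TRUE)
  expect_identical(strip(s1$paths$gtf), strip(s2$paths$gtf))
  expect_identical(readLines(s1$paths$coverage[1]),
                   readLines(s2$paths$coverage[1]))
  expect_identical(readLines(s1$paths$truth), readLines(s2$paths$truth))
})

test_that("the emitted files round trip to the in-memory objects", {
  cfg <- small_cfg()
  d <- tempfile()
  sim <- simulate_dataset(cfg, d)
  genes <- parse_gtf(sim$paths$gtf)
  expect_equal(length(genes), length(sim$ann$genes))
  expect_equal(genes, sim$ann$genes)
  gi <- read_chrom_sizes(sim$paths$chrom_sizes)
  expect_equal(gi, sim$ann$genome)
  tr <- read_bedgraph(sim$paths$coverage[1], gi, cfg$library_size,
                      cfg$read_length)
  g1 <- sim$ann$genes[[1]]
  expect_equal(gene_fpkm(tr, g1), gene_fpkm(sim$tracks[[1]], g1),
               tolerance = 1e-6)
})

test_that("planted antisense neighbors sit inside their host tails", {
  cfg <- small_cfg(rt_fraction = 0.8, und_fraction = 0.5)
  ann <- generate_annotation(cfg)
  tr <- ann$truth
  as_rows <- tr[!is.na(tr$antisense_of), ]
  expect_gt(nrow(as_rows), 0)
  for (i in seq_len(nrow(as_rows))) {
    host <- tr[tr$gene_id == as_rows$antisense_of[i], ]
    expect_equal(host$status, "UND")
    expect_true(as_rows$start[i] >= host$tail_start &&
                  as_rows$end[i] <= host$tail_end)
    expect_true(as_rows$strand[i] != host$strand)
  }
})

test_that("planted tails drive the detector to the documented outcomes", {
  # one gene per scenario on a clean chromosome
  cfg <- sim_config(rng_seed = 2, n_chromosomes = 1, n_genes = 1,
                    n_samples = 1, rt_fraction = 1, und_fraction = 0,
                    strand_minus_fraction = 0,
                    tail_length_range = c(3000L, 3000L),
                    tail_fpkm_range = c(0.5, 0.5),
                    intergenic_range = c(12000L, 15000L),
                    chrom_margin_bp = 12000L)
  ann <- generate_annotation(cfg)
  tracks <- generate_coverage(ann, cfg)
  call <- call_readthrough(tracks[[1]], ann$genes[[1]])
  expect_equal(call$status, "RT")
  expect_lte(abs(call$tail_length_bp - 3000), 500)

  cfg2 <- sim_config(rng_seed = 2, n_chromosomes = 1, n_genes = 1,
                     n_samples = 1, rt_fraction = 1, und_fraction = 0,
                     strand_minus_fraction = 0,
                     tail_length_range = c(1500L, 1500L),
                     tail_fpkm_range = c(0.5, 0.5),
                     intergenic_range = c(12000L, 15000L),
                     chrom_margin_bp = 12000L)
  ann2 <- generate_annotation(cfg2)
  expect_equal(ann2$truth$status[1], "NRT")  # below the minimum length
  call2 <- call_readthrough(generate_coverage(ann2, cfg2)[[1]],
                            ann2$genes[[1]])
  expect_equal(call2$status, "NRT")

  # no tails and no noise: zero coverage downstream of every TTS
  cfg3 <- small_cfg(rt_fraction = 0)
  ann3 <- generate_annotation(cfg3)
  tr3 <- generate_coverage(ann3, cfg3)[[1]]
  for (g in ann3$genes[1:10]) {
    t0 <- tts(g)
    s <- if (g$strand == "+") t0 else t0 - 2000
    expect_equal(region_fpkm(tr3, g$chrom, s, s + 2000), 0)
  }
})

test_that("expression matrices recover exactly the planted detection fractions", {
  cfg <- sim_config(rng_seed = 3, n_genes = 200, n_samples = 8)
  em <- generate_expression_matrix(cfg)
  got <- classify_expressed(em$matrix)
  want <- em$truth$gene_id[em$truth$detection_fraction >= 0.25]
  expect_setequal(got, want)
  # closed loop across the full 0..1 fraction range
  expect_setequal(unique(em$truth$detection_fraction) * 8, 0:8)
})

test_that("peak generation respects the group presence probabilities", {
  regions <- data.frame(region_class = "TTSplus",
                        gene_id = sprintf("g%04d", 1:1000),
                        status = rep(c("RT", "NRT"), 500), chrom = "c",
                        start = seq(0, by = 3000, length.out = 1000))
  regions$end <- regions$start + 2000
  cfg <- sim_config(rng_seed = 4)
  all_in <- generate_peaks(regions, c(RT = 1, NRT = 1), cfg)
  expect_equal(count_genes_with_peak(regions, all_in$peaks)$n_with_peak,
               c(500, 500))
  none <- generate_peaks(regions, c(RT = 0, NRT = 0), cfg)
  expect_equal(nrow(none$peaks), 0)
  some <- generate_peaks(regions, c(RT = 0.7, NRT = 0.7), cfg)
  n <- sum(some$truth$has_peak)
  expect_lt(abs(n - 700), 3 * sqrt(1000 * 0.7 * 0.3))
  # peaks sit inside their regions
  expect_true(all(some$peaks$start >= 0 &
                    some$peaks$end - some$peaks$start <= 2000))
})

test_that("genome sequences are deterministic with binomial composition", {
  cfg <- sim_config(rng_seed = 8, n_chromosomes = 1, n_genes = 6,
                    n_samples = 4, rt_fraction = 0,
                    intergenic_range = c(2000L, 2500L),
                    chrom_margin_bp = 1500L,
                    tail_length_range = c(900L, 900L))
  ann <- generate_annotation(cfg)
  s1 <- generate_genome_sequence(ann, cfg)
  s2 <- generate_genome_sequence(ann, cfg)
  expect_identical(as.character(s1), as.character(s2))
  L <- sum(ann$genome)
  # genome-wide CCGCGC frequency within 3 SE of the 4^-6 expectation
  n_hits <- sum(vapply(as.character(s1), oracle_scan_pattern, 0L,
                       pat = "CCGCGC"))
  expected <- (L - 5) / 4^6
  expect_lt(abs(n_hits - expected), 3 * sqrt(expected))
})

test_that("hexamer scaling halves occurrences in the chosen flanks", {
  cfg <- sim_config(rng_seed = 12, n_chromosomes = 1, n_genes = 30,
                    n_samples = 4, rt_fraction = 0, gc = 0.6,
                    intergenic_range = c(2500L, 3000L),
                    chrom_margin_bp = 1500L,
                    tail_length_range = c(1200L, 1200L))
  ann <- generate_annotation(cfg)
  ids <- vapply(ann$genes, function(g) g$gene_id, "")
  group <- ids[1:15]
  plain <- generate_genome_sequence(ann, cfg)
  biased <- generate_genome_sequence(ann, cfg,
                                     hexamer_bias = list(gene_ids = group,
                                                         kmers = "CCGCGC",
                                                         factor = 0.5,
                                                         flank_bp = 500))
  n_plain <- sum(vapply(group, function(gid)
    oracle_scan_pattern(extract_tts_flank(
      ann$genes[[which(ids == gid)]], plain, 500)$sequence, "CCGCGC"), 0L))
  n_biased <- sum(vapply(group, function(gid)
    oracle_scan_pattern(extract_tts_flank(
      ann$genes[[which(ids == gid)]], biased, 500)$sequence, "CCGCGC"), 0L))
  # binomial thinning at rate 0.5: compare within 3 SE
  expect_lt(abs(n_biased - 0.5 * n_plain), 3 * sqrt(0.25 * n_plain) + 1)
  expect_gt(n_plain, 5)  # enough occurrences for the check to mean something
})

test_that("planted miRNA seed sites are recovered at the exact count", {
  cfg <- sim_config(rng_seed = 13, n_chromosomes = 1, n_genes = 10,
                    n_samples = 4, rt_fraction = 1, und_fraction = 0,
                    intergenic_range = c(9000L, 10000L),
                    chrom_margin_bp = 9000L,
                    tail_length_range = c(3000L, 6000L))
  ann <- generate_annotation(cfg)
  tr <- ann$truth
  planted <- tr$gene_id[tr$planted_tail][1:5]
  pat <- seed_pattern("UAGCUUAUCAGACUGAUGUUGA")
  sites <- data.frame(gene_id = planted, pattern = pat,
                      n_sites = c(25L, 3L, 0L, 10L, 40L))
  genome <- generate_genome_sequence(ann, cfg, seed_sites = sites)
  ids <- vapply(ann$genes, function(g) g$gene_id, "")
  for (i in seq_len(nrow(sites))) {
    t_row <- tr[tr$gene_id == sites$gene_id[i], ]
    g <- ann$genes[[which(ids == sites$gene_id[i])]]
    region <- substr(as.character(genome[[g$chrom]]),
                     t_row$tail_start + 1, t_row$tail_end)
    if (g$strand == "-")
      region <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(region)))
    expect_equal(scan_seed_matches(region, pat), sites$n_sites[i])
  }
})
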