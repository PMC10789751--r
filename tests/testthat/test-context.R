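grid_genes <- function(n, chroms, strand = "+", width = 100L, gap = 900L) {
  lapply(seq_len(n), function(i) {
    ch <- chroms[((i - 1) %% length(chroms)) + 1]
    s <- (((i - 1) %/% length(chroms)) * (width + gap))
    make_gene(sprintf("g%03d", i), ch, strand, list(c(s, s + width)))
  })
}

test_that("chromosome enrichment matches the hypergeometric oracle", {
  set.seed(51)
  genes <- grid_genes(100, c("c1", "c2", "c3"))
  ids <- vapply(genes, function(g) g$gene_id, "")
  background <- ids
  for (rep in 1:10) {
    group <- sample(ids, 30)
    res <- chromosome_enrichment(group, background, genes)
    for (i in seq_len(nrow(res))) {
      r <- res[i, ]
      expect_equal(r$p_value,
                   oracle_fisher_p(r$n_group_on, r$n_group_off,
                                   r$n_bg_on, r$n_bg_off),
                   tolerance = 1e-6)
      or <- (r$n_group_on * r$n_bg_off) / (r$n_group_off * r$n_bg_on)
      expect_equal(r$odds_ratio, or)
    }
  }
  # the worked 2x2: (8,2,10,80) has sample odds ratio 32 and a p equal to
  # the hypergeometric tail sum
  expect_equal(oracle_fisher_p(8, 2, 10, 80),
               fisher.test(matrix(c(8, 2, 10, 80), 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)
})

test_that("a group concentrated on one chromosome is called enriched", {
  genes <- grid_genes(120, c("c1", "c2", "c3", "c4"))
  ids <- vapply(genes, function(g) g$gene_id, "")
  chrom <- vapply(genes, function(g) g$chrom, "")
  group <- ids[chrom == "c1"]
  res <- chromosome_enrichment(group, ids, genes)
  expect_equal(res$direction[res$chrom == "c1"], "enriched")
  expect_true(all(res$direction[res$chrom != "c1"] %in%
                    c("depleted", "ns")))
  expect_true(any(res$direction == "depleted"))
  # a proportionally spread group is ns everywhere
  set.seed(3)
  prop <- sample(ids, 40)
  resp <- chromosome_enrichment(prop, ids, genes)
  expect_true(mean(resp$direction == "ns") >= 0.75)
})

test_that("gene density counts 5' ends per chromosome and window", {
  genome <- genome_index(c(c1 = 1e7, c2 = 5e6))
  genes <- c(grid_genes(10, "c1", gap = 999900L), grid_genes(3, "c2"))
  ids <- vapply(genes, function(g) g$gene_id, "")
  d <- gene_density(genes, ids, genome, unit = "chromosome")
  expect_equal(d$density[d$chrom == "c1"], 10 / 1e7)
  empty <- gene_density(genes, character(0), genome)
  expect_equal(empty$density, c(0, 0))

  w <- gene_density(genes, ids, genome, unit = "window", window_bp = 1e6)
  expect_equal(sum(w$n_expressed[w$chrom == "c1"]),
               d$n_expressed[d$chrom == "c1"])
  # minus-strand gene is assigned by its 5' end (right end)
  gm <- make_gene("m", "c1", "-", list(c(999000, 1000500)))
  wm <- gene_density(list(gm), "m", genome, unit = "window", window_bp = 1e6)
  expect_equal(wm$n_expressed[2], 1)  # 5' end at 1000499 -> second window
  expect_equal(sum(wm$n_expressed), 1)
})

test_that("downstream distance respects strand and ignores overlaps", {
  a <- make_gene("a", "c", "+", list(c(0, 100)))
  b <- make_gene("b", "c", "+", list(c(150, 300)))
  anti <- make_gene("x", "c", "-", list(c(150, 300)))
  expect_equal(distance_to_downstream_expressed(a, list(a, b), c("a", "b")), 50L)
  expect_true(is.na(distance_to_downstream_expressed(a, list(a, anti),
                                                     c("a", "x"))))
  # overlapping gene is ignored
  ov <- make_gene("o", "c", "+", list(c(50, 120)))
  expect_true(is.na(distance_to_downstream_expressed(
    a, list(a, ov), c("a", "o"))))

  set.seed(61)
  for (rep in 1:20) {
    genes <- lapply(1:8, function(i) {
      s <- sample(0:5000, 1)
      make_gene(paste0("g", i), "c", sample(c("+", "-"), 1),
                list(c(s, s + sample(50:400, 1))))
    })
    ids <- vapply(genes, function(g) g$gene_id, "")
    q <- genes[[1]]
    got <- distance_to_downstream_expressed(q, genes, ids)
    t0 <- tts(q)
    ds <- unlist(lapply(genes[-1], function(g) {
      if (g$strand != q$strand) return(NULL)
      d <- if (q$strand == "+") g$start - t0 else t0 - g$end
      if (d >= 0) d else NULL
    }))
    want <- if (length(ds) == 0) NA_integer_ else min(ds)
    expect_equal(got, want)
  }
})

test_that("spearman correlation matches rank-then-pearson", {
  x <- c(1, 5, 2, 8, 3)
  expect_equal(spearman_cor(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  set.seed(71)
  for (rep in 1:20) {
    a <- sample(1:20, 15, replace = TRUE)  # ties exercised
    b <- rnorm(15)
    got <- spearman_cor(a, b)
    expect_equal(got$rho, cor(rank(a), rank(b)))
  }
  expect_error(spearman_cor(1:3, 1:4), "mismatch")
})

test_that("flank regions apply the 2500-bp tail filter and strand geometry", {
  calls <- data.frame(
    gene_id = c("short", "edge", "minus", "nrt", "und"),
    chrom = "c", strand = c("+", "+", "-", "+", "+"),
    tts = c(10000, 10000, 50000, 30000, 40000),
    tail_start = c(10000, 10000, 47500, 30000, 40000),
    tail_end = c(12400, 12500, 50000, 30000, 45000),
    tail_length_bp = c(2400, 2500, 2500, 0, 5000),
    status = c("RT", "RT", "RT", "NRT", "UND"))
  fr <- build_flank_regions(calls)
  expect_false("short" %in% fr$gene_id)          # 2400 < 2500
  expect_true("edge" %in% fr$gene_id)            # boundary included
  expect_false("und" %in% fr$gene_id)            # UND excluded entirely
  # NRT contributes TTS classes but no RTend
  expect_setequal(fr$region_class[fr$gene_id == "nrt"],
                  c("TTSminus", "TTSplus"))
  # minus-strand: TTSplus extends leftward from the TTS
  mp <- fr[fr$gene_id == "minus" & fr$region_class == "TTSplus", ]
  expect_equal(c(mp$start, mp$end), c(48000, 50000))
  mm <- fr[fr$gene_id == "minus" & fr$region_class == "TTSminus", ]
  expect_equal(c(mm$start, mm$end), c(50000, 52000))
  # RTend is centered on the strand-aware tail end
  me <- fr[fr$gene_id == "minus" & fr$region_class == "RTend", ]
  expect_equal(c(me$start, me$end), c(45500, 49500))
})

test_that("peak counting counts each gene once per class", {
  regions <- data.frame(region_class = "TTSplus", gene_id = c("a", "b"),
                        status = "RT", chrom = "c",
                        start = c(0, 1000), end = c(500, 1500))
  # one peak touching by 1 bp, two peaks inside the same region
  peaks <- data.frame(chrom = "c", start = c(499, 1100, 1200),
                      end = c(600, 1150, 1250))
  got <- count_genes_with_peak(regions, peaks)
  expect_equal(got$n_with_peak, 2)
  none <- count_genes_with_peak(regions,
                                data.frame(chrom = "c", start = 5000,
                                           end = 5100))
  expect_equal(none$n_with_peak, 0)

  set.seed(81)
  for (rep in 1:15) {
    pk <- data.frame(chrom = "c", start = sample(0:1400, 5))
    pk$end <- pk$start + sample(10:200, 5)
    got <- count_genes_with_peak(regions, pk)
    want <- sum(vapply(seq_len(nrow(regions)), function(i)
      any(pk$start < regions$end[i] & pk$end > regions$start[i]), FALSE))
    expect_equal(got$n_with_peak, want)
  }
})

test_that("state fold enrichment matches closed forms and the base oracle", {
  genome <- genome_index(c(c = 10000))
  seg <- data.frame(chrom = "c", start = c(0, 1000, 10000 * 0.1),
                    end = c(500, 1000, 1000), state = NA)
  # build a clean 2-state tiling: state A covers [0,1000) (10%), B the rest
  seg <- data.frame(chrom = "c", start = c(0, 1000), end = c(1000, 10000),
                    state = c("A", "B"))
  regions <- data.frame(chrom = "c", start = 200, end = 700)
  fe <- state_fold_enrichment(regions, seg, genome)
  expect_equal(fe$fold[fe$state == "A"], 10)
  expect_equal(fe$fold[fe$state == "B"], 0)
  # whole genome as region: every fold is 1
  whole <- state_fold_enrichment(data.frame(chrom = "c", start = 0,
                                            end = 10000), seg, genome)
  expect_equal(whole$fold, c(1, 1))
  expect_error(state_fold_enrichment(regions,
                                     data.frame(chrom = "c",
                                                start = c(0, 500),
                                                end = c(1000, 1500),
                                                state = c("A", "B")),
                                     genome), "overlapping")

  set.seed(91)
  for (rep in 1:10) {
    cuts <- sort(sample(1:99, 5)) * 100L
    bounds <- c(0L, cuts, 10000L)
    seg <- data.frame(chrom = "c", start = bounds[-length(bounds)],
                      end = bounds[-1],
                      state = sample(c("A", "B", "C"), 6, replace = TRUE))
    regions <- data.frame(chrom = "c", start = c(100, 5000),
                          end = c(2100, 5800))
    fe <- state_fold_enrichment(regions, seg, genome)
    state_mask <- function(st) {
      m <- logical(10000)
      for (i in which(seg$state == st))
        m[(seg$start[i] + 1):seg$end[i]] <- TRUE
      m
    }
    reg_mask <- intervals_to_mask(cbind(regions$start, regions$end), 10000)
    for (st in unique(seg$state)) {
      sm <- state_mask(st)
      want <- (sum(sm & reg_mask) / sum(reg_mask)) / (sum(sm) / 10000)
      expect_equal(fe$fold[fe$state == st], want)
    }
  }
})

test_that("permuted group labels give uniform Fisher p-values", {
  set.seed(101)
  genes <- grid_genes(200, paste0("c", 1:5))
  ids <- vapply(genes, function(g) g$gene_id, "")
  ps <- unlist(lapply(1:200, function(i)
    chromosome_enrichment(sample(ids, 60), ids, genes)$p_value))
  # discrete p-values are conservative; check uniformity loosely via KS
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(mean(ps < 0.05), 0)   # some signal exists by chance
  expect_lt(mean(ps < 0.05), 0.08)
})
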