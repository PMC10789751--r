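#' Run the readthrough pipeline on one tissue
#'
#' Orchestrates the stages in dependency order: gene-level quantification
#' from coverage, expressed-gene classification, per-sample rolling-window
#' readthrough calling, opposite-strand (UND) filtering, read-in flagging,
#' tissue consensus, RT-ratio quantification and intron-table construction.
#' Every output is written as TSV into `out_dir` and listed in a manifest
#' with MD5 checksums, so reruns can be compared file by file.
#'
#' @param genes Annotation: list of [gene_model()] (e.g. from
#'   [parse_gtf()]).
#' @param tracks List of [coverage_track()], the tissue's samples.
#' @param out_dir Output directory (created if missing).
#' @param detector A [detector_config()].
#' @param expr_filter An [expression_filter_config()].
#' @param consensus_fraction RT consensus threshold across samples.
#' @return List: `expression`, `expressed_ids`, `calls` (per sample,
#'   stacked), `consensus`, `rt_ratio`, `intron_table`, `manifest`.
#' @export
run_pipeline <- function(genes, tracks, out_dir,
                         detector = detector_config(),
                         expr_filter = expression_filter_config(),
                         consensus_fraction = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message("quantify: ", length(genes), " genes x ", length(tracks), " samples")
  expr <- expression_from_tracks(tracks, genes)
  expressed <- classify_expressed(expr, expr_filter)

  message("detect: calling readthrough on ", length(expressed),
          " expressed genes")
  calls <- do.call(rbind, lapply(tracks, function(tr) {
    cc <- call_readthrough_all(tr, genes, detector, expressed)
    cc <- filter_opposite_strand(cc, genes)
    cc <- classify_readin(cc, genes, expressed)
    cc$sample_id <- tr$sample_id
    cc
  }))
  consensus <- consensus_rt_status(calls, consensus_fraction)

  message("ratio: RT-ratio per gene")
  gene_expr_med <- apply(expr[consensus$gene_id, , drop = FALSE], 1, stats::median)
  tail_med <- vapply(split(calls$tail_fpkm, calls$gene_id), stats::median, 0)
  tail_med <- tail_med[consensus$gene_id]
  ratio <- data.frame(gene_id = consensus$gene_id,
                      status = consensus$status,
                      rt_levels = unname(tail_med),
                      gene_levels = unname(gene_expr_med),
                      rt_ratio = rt_ratio(unname(tail_med),
                                          unname(gene_expr_med)),
                      stringsAsFactors = FALSE)

  message("introns: building intron table")
  intron_table <- build_intron_table(genes)

  paths <- c(expression = "expression_matrix.tsv", calls = "calls.tsv",
             consensus = "consensus.tsv", rt_ratio = "rt_ratio.tsv",
             intron_table = "intron_table.tsv")
  paths <- vapply(paths, function(p) file.path(out_dir, p), "")
  write_expression_matrix(expr, paths["expression"])
  for (nm in c("calls", "consensus", "rt_ratio", "intron_table")) {
    obj <- switch(nm, calls = calls, consensus = consensus,
                  rt_ratio = ratio, intron_table = intron_table)
    utils::write.table(obj, paths[nm], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  manifest <- data.frame(output = names(paths), path = unname(paths),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(expression = expr, expressed_ids = expressed, calls = calls,
       consensus = consensus, rt_ratio = ratio,
       intron_table = intron_table, manifest = manifest)
}

#' Compare per-gene RT proportion between two sample groups
#'
#' For each gene, the per-sample RT proportion
#' `tail_fpkm / (tail_fpkm + gene_fpkm)` is compared between the two
#' groups (e.g. young < 40 vs old > 60 donors) with a Mann-Whitney test,
#' BH-adjusted across genes. Direction is the fold change of group medians
#' with a small pseudocount guarding zero medians; a gene is significant at
#' `fdr_threshold`.
#'
#' @param calls `data.frame` with `gene_id`, `sample_id`, `tail_fpkm`,
#'   `gene_fpkm` (one row per gene and sample).
#' @param groups Named character vector, sample id -> group label.
#' @param group_a,group_b The two labels to compare (fold change is
#'   `group_b` over `group_a`, e.g. old over young).
#' @param fdr_threshold Significance threshold.
#' @param eps Pseudocount on the median proportions.
#' @return `data.frame` per gene: medians, `fold_change`, `p_value`,
#'   `fdr`, `direction` in `{up, down}`, `significant`.
#' @export
compare_groups <- function(calls, groups, group_a, group_b,
                           fdr_threshold = 0.05, eps = 1e-6) {
  calls$group <- unname(groups[calls$sample_id])
  calls <- calls[calls$group %in% c(group_a, group_b), ]
  calls$prop <- rt_ratio(calls$tail_fpkm, calls$gene_fpkm)
  out <- lapply(split(calls, calls$gene_id), function(d) {
    a <- d$prop[d$group == group_a]
    b <- d$prop[d$group == group_b]
    if (length(a) < 2L || length(b) < 2L)
      stop("group with < 2 samples for gene ", d$gene_id[1L])
    med_a <- stats::median(a); med_b <- stats::median(b)
    p <- if (stats::var(c(a, b)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(b, a)$p.value)
    data.frame(gene_id = d$gene_id[1L], median_a = med_a, median_b = med_b,
               fold_change = (med_b + eps) / (med_a + eps), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$fdr <- bh_fdr(out$p_value)
  out$direction <- ifelse(out$fold_change > 1, "up", "down")
  out$significant <- out$fdr < fdr_threshold
  rownames(out) <- NULL
  out
}
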