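#' Expression-matched subsampling configuration
#'
#' Repeated nearest-neighbor matching of RT genes to NRT genes on
#' expression removes expression as a confounder before group comparisons.
#' The published analyses use 1000 permutations with subsample sizes of 200
#' (epigenomic peak counting) or 500 (hexamer and intron-retention
#' analyses).
#'
#' @param n_per_subsample Genes drawn per permutation from the RT pool.
#' @param n_permutations Number of matched subsamples.
#' @param rng_seed Integer seed; identical seeds give identical subsamples.
#' @param expression_scale `"log2"` (match on `log2(x + 1)`, default) or
#'   `"linear"`.
#' @export
matching_config <- function(n_per_subsample, n_permutations = 1000L,
                            rng_seed = 1L,
                            expression_scale = c("log2", "linear")) {
  stopifnot(n_per_subsample >= 1, n_permutations >= 1)
  list(n_per_subsample = as.integer(n_per_subsample),
       n_permutations = as.integer(n_permutations),
       rng_seed = as.integer(rng_seed),
       expression_scale = match.arg(expression_scale))
}

#' Build expression-matched RT/NRT subsamples
#'
#' Per permutation, `n_per_subsample` RT genes are drawn uniformly without
#' replacement; each is paired with the unused NRT gene minimizing the
#' absolute expression difference on the configured scale. NRT partners are
#' consumed without replacement within a subsample and reset across
#' permutations. Ties are broken by lexicographic gene id.
#'
#' @param rt,nrt Named numeric vectors: gene id -> expression (FPKM).
#' @param config A [matching_config()].
#' @return `data.frame` with columns `perm_index`, `rt_gene`, `nrt_gene`,
#'   `rt_expr`, `nrt_expr` (original scale).
#' @export
expression_matched_subsamples <- function(rt, nrt, config) {
  if (length(rt) == 0L || length(nrt) == 0L) stop("empty gene pool")
  n <- config$n_per_subsample
  if (n > length(rt) || n > length(nrt))
    stop("n_per_subsample exceeds pool size")
  tf <- if (config$expression_scale == "log2") function(x) log2(x + 1) else identity
  rt_t <- tf(rt); nrt_t <- tf(nrt)

  # NRT pool sorted by (expression, gene id) so that the nearest unused
  # neighbor is found by local outward search, and the lexicographic
  # tie-break falls out of the sort order for exactly equal expressions.
  o <- order(nrt_t, names(nrt_t))
  ne <- unname(nrt_t[o]); nid <- names(nrt_t)[o]
  n_nrt <- length(ne)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$rng_seed)

  out <- vector("list", config$n_permutations)
  rt_ids <- names(rt_t)
  # within a run of equal expressions, prefer the smallest-id alive entry
  # (ids ascend with the index inside a run because of the sort above)
  first_alive_in_run <- function(k, alive) {
    j <- k
    while (j > 1L && ne[j - 1L] == ne[k]) j <- j - 1L
    run <- j:k
    run <- run[alive[run]]
    if (length(run)) run[1L] else k
  }
  for (p in seq_len(config$n_permutations)) {
    sel <- sample(rt_ids, n)
    alive <- rep(TRUE, n_nrt)
    partner <- character(n)
    for (j in seq_len(n)) {
      v <- rt_t[[sel[j]]]
      i <- findInterval(v, ne)
      lo <- i; hi <- i + 1L
      while (lo >= 1L && !alive[lo]) lo <- lo - 1L
      while (hi <= n_nrt && !alive[hi]) hi <- hi + 1L
      if (lo < 1L && hi > n_nrt) stop("NRT pool exhausted")
      pick <- if (lo < 1L) hi
      else if (hi > n_nrt) lo
      else {
        dl <- abs(v - ne[lo]); dh <- abs(v - ne[hi])
        if (dl < dh) lo
        else if (dh < dl) hi
        else {
          l2 <- first_alive_in_run(lo, alive)
          h2 <- first_alive_in_run(hi, alive)
          if (nid[l2] <= nid[h2]) l2 else h2
        }
      }
      pick <- first_alive_in_run(pick, alive)
      partner[j] <- nid[pick]
      alive[pick] <- FALSE
    }
    out[[p]] <- data.frame(perm_index = p, rt_gene = sel, nrt_gene = partner,
                           rt_expr = unname(rt[sel]),
                           nrt_expr = unname(nrt[partner]),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Mann-Whitney test with Cohen's d effect size
#'
#' Two-sided Mann-Whitney U (exact when both groups have at most 20
#' observations and no ties; normal approximation with tie correction
#' otherwise) plus Cohen's d with pooled, (n-1)-weighted standard
#' deviation. Degenerate input (all values identical) returns p = 1, d = 0.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List: `statistic` (U of the first group), `p_value`, `cohen_d`,
#'   `n_a`, `n_b`.
#' @export
mann_whitney_cohen <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  if (stats::var(c(a, b)) == 0) {
    return(list(statistic = na * nb / 2, p_value = 1, cohen_d = 0,
                n_a = na, n_b = nb))
  }
  exact <- na <= 20 && nb <= 20 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  d <- if (sp > 0) (mean(a) - mean(b)) / sp else 0
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       cohen_d = d, n_a = na, n_b = nb)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Mean and SD of per-group summaries across permutations
#'
#' @param per_permutation List (one element per permutation) of named
#'   numeric vectors, all with identical names (the groups).
#' @return `data.frame(group, mean, sd)`.
#' @export
aggregate_permutations <- function(per_permutation) {
  if (length(per_permutation) < 2L) stop("need >= 2 permutations")
  nm <- names(per_permutation[[1L]])
  for (x in per_permutation) {
    if (!identical(names(x), nm)) stop("group mismatch across permutations")
  }
  m <- do.call(rbind, per_permutation)
  data.frame(group = nm, mean = colMeans(m), sd = apply(m, 2, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}
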