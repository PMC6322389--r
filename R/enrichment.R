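#' Hypergeometric co-binding overlap test
#'
#' Within a finite universe of accessible sites, membership of each universe
#' element in a factor's binding set and in a target (e.g. canonical HIF)
#' set is decided by >= `min_overlap` bp overlap; the upper-tail
#' hypergeometric probability of observing at least `k` joint members among
#' `n` draws from a universe of `N` with `K` successes is reported, together
#' with the fold enrichment `(k/n) / (K/N)`.
#'
#' @param universe a [peak_set()] defining the finite population.
#' @param factor_set,target_set [peak_set()]s of the two binding repertoires.
#' @param min_overlap minimum overlapping bases for membership (default 1).
#' @return an `OverlapTest` list: `N`, `K`, `n`, `k`, `p.value`,
#'   `enrichment`.
#' @export
hypergeometric_overlap <- function(universe, factor_set, target_set,
                                   min_overlap = 1) {
  in_f <- .overlaps_any(universe, factor_set, min_overlap)
  in_t <- .overlaps_any(universe, target_set, min_overlap)
  N <- nrow(universe)
  K <- sum(in_f)
  n <- sum(in_t)
  k <- sum(in_f & in_t)
  .assert(K > 0, "no universe element overlaps the factor set (no successes)")
  .assert(n > 0, "no universe element overlaps the target set (no draws)")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, k = k, p.value = p,
                 enrichment = (k / n) / (K / N)),
            class = "OverlapTest")
}

#' @export
print.OverlapTest <- function(x, ...) {
  cat(sprintf(paste0("Hypergeometric overlap: k = %d of n = %d draws ",
                     "(K = %d successes in N = %d)\n",
                     "  enrichment %.2f-fold, P = %.3g\n"),
              x$k, x$n, x$K, x$N, x$enrichment, x$p.value))
  invisible(x)
}

#' Rank genes by signed significance-weighted fold change
#'
#' The ranking score is `pi = log2FC * (-log10 p)`: fold change signed by
#' direction, weighted by significance. Zero p-values are clipped to
#' `p_floor`. Genes are sorted by decreasing score, ties broken by gene_id.
#'
#' @param table data frame with columns `gene_id`, `log2fc`, `pvalue`
#'   (p in (0, 1]).
#' @param p_floor clip for zero p-values (default 1e-300).
#' @return a `RankedGeneList` data frame (`gene_id`, `log2fc`, `pvalue`,
#'   `score`), sorted descending by score.
#' @export
rank_genes <- function(table, p_floor = 1e-300) {
  .assert(all(c("gene_id", "log2fc", "pvalue") %in% names(table)),
          "need gene_id, log2fc, pvalue columns")
  .assert(!anyDuplicated(table$gene_id), "duplicate gene ids")
  .assert(all(is.finite(table$log2fc)), "non-finite log2 fold changes")
  .assert(all(table$pvalue >= 0 & table$pvalue <= 1), "p-values outside [0,1]")
  p <- table$pvalue
  if (any(p == 0)) {
    message(sprintf("%d zero p-value(s) clipped to %g", sum(p == 0), p_floor))
    p <- pmax(p, p_floor)
  }
  out <- data.frame(gene_id = as.character(table$gene_id),
                    log2fc = table$log2fc, pvalue = table$pvalue,
                    score = table$log2fc * (-log10(p)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("RankedGeneList", "data.frame")
  out
}

# Weighted Kolmogorov-Smirnov style running sum; ES = signed maximum
# deviation from zero (classic signed convention).
.gsea_es <- function(scores, hit, p) {
  nh <- sum(hit)
  w <- abs(scores)^p
  denom <- sum(w[hit])
  inc <- rep(-1 / (length(scores) - nh), length(scores))
  if (denom > 0) inc[hit] <- w[hit] / denom
  else inc[hit] <- 1 / nh  # all-zero scores: unweighted hits
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Pre-ranked weighted gene set enrichment analysis
#'
#' Walking down the ranked list, genes in the set add
#' `|score|^weight / sum_hits |score|^weight` to the running sum and genes
#' outside subtract `1 / (N - N_set)`; the enrichment score (ES) is the
#' signed maximum deviation from zero. The null distribution comes from
#' random gene-label permutations of set membership; the nominal P is
#' `(1 + #direction-matched null ES at least as extreme) / (n_perm + 1)` and
#' NES is ES divided by the mean same-sign null ES.
#'
#' @param ranked a [rank_genes()] result (or data frame with `gene_id` and
#'   `score`, sorted descending).
#' @param gene_set character vector of gene ids.
#' @param weight running-sum weight exponent (default 1, the weighted
#'   enrichment score; 0 gives the classic unweighted statistic).
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed for the permutations.
#' @return an `EnrichmentResult` list: `es`, `nes`, `p.value`, `n_perm`,
#'   `running_sum`, `hit_index`, `n_set`.
#' @export
gsea_preranked <- function(ranked, gene_set, weight = 1, n_perm = 1000,
                           seed = NULL) {
  .assert(all(c("gene_id", "score") %in% names(ranked)),
          "ranked list needs gene_id and score columns")
  N <- nrow(ranked)
  hit <- ranked$gene_id %in% gene_set
  nh <- sum(hit)
  .assert(nh > 0, "gene set does not intersect the ranked list")
  .assert(nh < N, "gene set covers the whole ranked list")
  scores <- ranked$score
  es <- .gsea_es(scores, hit, weight)
  w <- abs(scores)^weight
  miss_inc <- -1 / (N - nh)
  null_es <- .with_seed(seed, vapply(seq_len(n_perm), function(b) {
    h <- sample.int(N, nh)
    inc <- rep(miss_inc, N)
    denom <- sum(w[h])
    inc[h] <- if (denom > 0) w[h] / denom else 1 / nh
    rs <- cumsum(inc)
    rs[which.max(abs(rs))]
  }, 0))
  matched <- if (es >= 0) sum(null_es >= es) else sum(null_es <= es)
  p <- (1 + matched) / (n_perm + 1)
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same) > 0) es / mean(same) else NA_real_
  inc <- rep(miss_inc, N)
  denom <- sum(w[hit])
  inc[hit] <- if (denom > 0) w[hit] / denom else 1 / nh
  structure(list(es = es, nes = nes, p.value = p, n_perm = n_perm,
                 running_sum = cumsum(inc), hit_index = which(hit),
                 n_set = nh),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.3f, NES = %.3f, nominal P = %.4g (%d permutations, set size %d)\n",
              x$es, x$nes, x$p.value, x$n_perm, x$n_set))
  invisible(x)
}

#' @export
plot.EnrichmentResult <- function(x, ...) {
  graphics::plot(x$running_sum, type = "l", xlab = "rank",
                 ylab = "running enrichment score", ...)
  graphics::abline(h = 0, lty = 2)
  graphics::rug(x$hit_index)
  invisible(x)
}

#' Gene set of nearest genes to a site set
#'
#' The deduplicated set of nearest gene ids over all sites, the gene set
#' tested for enrichment among hypoxia-upregulated genes.
#'
#' @param sites a [peak_set()] (typically canonical sites).
#' @param ann a [gene_annotation()].
#' @return character vector of gene ids.
#' @export
nearest_gene_set <- function(sites, ann) {
  if (nrow(sites) == 0) return(character(0))
  unique(nearest_tss(sites, ann)$gene_id)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then gene ids, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(f, function(x) x[-(1:2)]),
                  vapply(f, `[`, "", 1))
}
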