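grid_universe <- function(N, width = 10, gap = 100) {
  start <- gap * (seq_len(N) - 1)
  peak_set("chr1", start, start + width, name = sprintf("u%02d", seq_len(N)))
}

# factor/target sets covering chosen universe elements exactly
covering <- function(universe, idx) {
  peak_set("chr1", universe$start[idx], universe$end[idx])
}

test_that("hypergeometric_overlap computes the exact upper tail", {
  u <- grid_universe(10)
  ot <- hypergeometric_overlap(u, covering(u, 1:5), covering(u, c(1:4)))
  expect_equal(ot$N, 10); expect_equal(ot$K, 5)
  expect_equal(ot$n, 4); expect_equal(ot$k, 4)
  expect_equal(ot$p.value, 5 / 210)   # C(5,4)/C(10,4)
  expect_equal(ot$enrichment, (4 / 4) / (5 / 10))
  # k = 0: the upper tail from zero includes all outcomes
  disj <- hypergeometric_overlap(u, covering(u, 1:5), covering(u, 6:9))
  expect_equal(disj$k, 0)
  expect_equal(disj$p.value, 1)
  # factor = target = universe
  all_ <- hypergeometric_overlap(u, u, u)
  expect_equal(all_$p.value, 1)
  expect_error(hypergeometric_overlap(u, covering(u, 1), peak_set("chr2", 0, 5)),
               "no draws")
})

test_that("hypergeometric P matches brute-force enumeration", {
  set.seed(31)
  for (i in 1:50) {
    N <- sample(8:14, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    u <- grid_universe(N)
    ot <- hypergeometric_overlap(u, covering(u, seq_len(K)),
                                 covering(u, sample.int(N, n)))
    expect_equal(ot$p.value, oracle_hyper(N, K, n, ot$k), tolerance = 1e-10)
  }
})

test_that("rank_genes applies the signed significance-weighted score", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    log2fc = c(2, 0, -1), pvalue = c(0.01, 1e-6, 0.1))
  rk <- rank_genes(tab)
  expect_equal(rk$score[rk$gene_id == "a"], 4)    # 2 * -log10(0.01)
  expect_equal(rk$score[rk$gene_id == "b"], 0)
  expect_equal(rk$score[rk$gene_id == "c"], -1)   # -1 * -log10(0.1)
  expect_equal(rk$gene_id, c("a", "b", "c"))      # sorted descending
  # ties broken by gene id; zero p clipped with a message
  tie <- data.frame(gene_id = c("z", "y"), log2fc = c(1, 1),
                    pvalue = c(0.1, 0.1))
  expect_equal(rank_genes(tie)$gene_id, c("y", "z"))
  zp <- data.frame(gene_id = "a", log2fc = 1, pvalue = 0)
  expect_message(rz <- rank_genes(zp), "clipped")
  expect_equal(rz$score, 300)
  expect_error(rank_genes(data.frame(gene_id = c("a", "a"), log2fc = 1,
                                     pvalue = 0.5)), "duplicate")
})

test_that("GSEA running sum follows the weighted convention", {
  rk <- data.frame(gene_id = letters[1:10], score = seq(10, 1))
  class(rk) <- c("RankedGeneList", "data.frame")
  # single-gene set at rank 1 contributes its full weight at the first step
  top <- gsea_preranked(rk, "a", weight = 1, n_perm = 50, seed = 1)
  expect_equal(top$es, 1)
  # a set at the exact bottom of a signed list gets a negative ES
  rk2 <- rk; rk2$score <- seq(5, -4)
  bottom <- gsea_preranked(rk2, c("i", "j"), weight = 1, n_perm = 50,
                           seed = 1)
  expect_lt(bottom$es, 0)
  expect_error(gsea_preranked(rk, "zzz", n_perm = 10), "intersect")
  expect_error(gsea_preranked(rk, letters[1:10], n_perm = 10), "whole")
})

test_that("GSEA ES equals the exhaustive path oracle; permutation P is calibrated", {
  set.seed(33)
  for (i in 1:20) {
    scores <- sort(round(rnorm(10, 0, 2), 3), decreasing = TRUE)
    rk <- data.frame(gene_id = letters[1:10], score = scores)
    hit_idx <- sort(sample.int(10, 3))
    set <- letters[hit_idx]
    g <- gsea_preranked(rk, set, weight = 1, n_perm = 200, seed = i)
    expect_equal(g$es, oracle_gsea_es(scores, seq_len(10) %in% hit_idx, 1),
                 tolerance = 1e-12)
  }
  # permutation P within 0.02 of exact enumeration over all C(10,3) sets
  scores <- c(5, 4, 3, 2.5, 2, 1.5, 1, -0.5, -1, -2)
  rk <- data.frame(gene_id = letters[1:10], score = scores)
  combs <- utils::combn(10, 3)
  all_es <- apply(combs, 2, function(ix)
    oracle_gsea_es(scores, seq_len(10) %in% ix, 1))
  set <- letters[c(1, 2, 4)]
  g <- gsea_preranked(rk, set, weight = 1, n_perm = 10000, seed = 99)
  exact_p <- mean(all_es >= g$es)  # es > 0: direction-matched tail
  expect_lt(abs(g$p.value - exact_p), 0.02)
})

test_that("GSEA ES is scale invariant and reverses for weight 0", {
  set.seed(35)
  scores <- sort(rnorm(40), decreasing = TRUE)
  rk <- data.frame(gene_id = sprintf("g%02d", 1:40), score = scores)
  set <- sprintf("g%02d", c(2, 5, 9, 11))
  e1 <- gsea_preranked(rk, set, weight = 1, n_perm = 10, seed = 1)$es
  rk_scaled <- rk; rk_scaled$score <- rk$score * 17
  e2 <- gsea_preranked(rk_scaled, set, weight = 1, n_perm = 10, seed = 1)$es
  expect_equal(e1, e2)
  rev_rk <- rk[rev(seq_len(nrow(rk))), ]
  f1 <- gsea_preranked(rk, set, weight = 0, n_perm = 10, seed = 1)$es
  f2 <- gsea_preranked(rev_rk, set, weight = 0, n_perm = 10, seed = 1)$es
  expect_equal(f1, -f2)
})

test_that("GSEA agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(37)
  stats <- sort(rnorm(100, 0, 2), decreasing = TRUE)
  names(stats) <- sprintf("g%03d", 1:100)
  rk <- data.frame(gene_id = names(stats), score = unname(stats))
  set <- names(stats)[sample.int(100, 12)]
  ours <- gsea_preranked(rk, set, weight = 1, n_perm = 500, seed = 5)
  ref <- suppressWarnings(fgsea::fgsea(list(s = set), stats,
                                       gseaParam = 1, nproc = 1))
  expect_equal(ours$es, ref$ES, tolerance = 1e-6)
})

test_that("permutation P under random sets controls type-I error", {
  set.seed(39)
  scores <- sort(rnorm(200), decreasing = TRUE)
  rk <- data.frame(gene_id = sprintf("g%03d", 1:200), score = scores)
  rejections <- 0L
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    set <- sprintf("g%03d", sample.int(200, 10))
    g <- gsea_preranked(rk, set, weight = 1, n_perm = 99, seed = 1e5 + i)
    if (g$p.value <= 0.05) rejections <- rejections + 1L
  }
  ci <- qbinom(c(0.025, 0.975), n_sim, 0.05)
  expect_gte(rejections, ci[1])
  expect_lte(rejections, ci[2])
})

test_that("nearest_gene_set deduplicates nearest genes", {
  ann <- gene_annotation(c("gA", "gB"), "chr1", c(1000, 50000), c("+", "+"))
  sites <- peak_set("chr1", c(900, 1500), c(1100, 1700),
                    name = c("s1", "s2"))
  expect_equal(nearest_gene_set(sites, ann), "gA")
  expect_equal(nearest_gene_set(sites[0, ], ann), character(0))
})

test_that("GMT gene sets round-trip through the reader", {
  f <- withr::local_tempfile()
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg9"), f)
  sets <- read_gmt(f)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(sets$setB, "g9")
})
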