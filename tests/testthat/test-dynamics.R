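two_mats <- function(a1, a2, b, scale = 1, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(a1))
  A <- as_site_signal_matrix(data.frame(site_id = ids, alpha1 = a1,
                                        alpha2 = a2, beta = b))
  B <- as_site_signal_matrix(data.frame(site_id = ids, alpha1 = a1 * scale,
                                        alpha2 = a2 * scale,
                                        beta = b * scale))
  list(A = A, B = B)
}

test_that("compare_conditions recovers exact fold changes", {
  set.seed(1)
  m <- two_mats(rlnorm(40, 2), rlnorm(40, 2), rlnorm(40, 2), scale = 2)
  cmp <- compare_conditions(m$A, m$B, pseudocount = 0)
  expect_equal(cmp$stats$r, rep(1, 3))
  expect_equal(cmp$stats$mean_fold_change, rep(2, 3))
  same <- compare_conditions(m$A, m$A, pseudocount = 0)
  expect_equal(same$stats$mean_fold_change, rep(1, 3))
  empty <- as_site_signal_matrix(data.frame(site_id = "zz", alpha1 = 1,
                                            alpha2 = 1, beta = 1))
  expect_error(compare_conditions(m$A, empty), "empty superset")
})

test_that("synthetic condition multipliers {1,2} are recovered", {
  cfg <- sim_config(genome_length = 8e6, n_genes = 600,
                    n_sites_per_isoform = 250, depth_per_assay = 1e6,
                    condition_scales = list(mild = 1, severe = 2), seed = 8)
  gs <- generate_sites(cfg, generate_annotation(cfg))
  mA <- sim_counts_matrix(cfg, gs$truth, "mild")
  mB <- sim_counts_matrix(cfg, gs$truth, "severe")
  cmp <- compare_conditions(mA, mB)
  expect_true(all(cmp$stats$mean_fold_change >= 1.8 &
                    cmp$stats$mean_fold_change <= 2.2))
})

test_that("tertile_corroboration handles degenerate and extreme inputs", {
  ids <- sprintf("s%03d", 1:30)
  A <- as_site_signal_matrix(data.frame(site_id = ids, alpha1 = rlnorm(30, 2),
                                        alpha2 = rlnorm(30, 2),
                                        beta = rep(2, 30)))
  B <- as_site_signal_matrix(data.frame(site_id = ids,
                                        alpha1 = A$alpha1 * rlnorm(30, 0, 0.3),
                                        alpha2 = A$alpha2, beta = rep(2, 30)))
  cmp <- compare_conditions(A, B, pseudocount = 0)
  res <- tertile_corroboration(cmp)   # q_beta identical everywhere
  expect_equal(res$p.value, 1)
  expect_false(res$corroborated)
  expect_equal(as.vector(table(res$tertile)), c(10, 10, 10))
  # q_beta tracking q_alpha exactly: minimal possible P for the group sizes
  set.seed(2)
  q <- rlnorm(30, 0, 0.5)
  A2 <- as_site_signal_matrix(data.frame(site_id = ids, alpha1 = rep(1, 30),
                                         alpha2 = rep(1, 30),
                                         beta = rep(1, 30)))
  B2 <- as_site_signal_matrix(data.frame(site_id = ids, alpha1 = q,
                                         alpha2 = q, beta = q))
  res2 <- tertile_corroboration(compare_conditions(A2, B2, pseudocount = 0))
  expect_equal(res2$p.value, oracle_ranksum(sort(q)[21:30], sort(q)[1:10]))
  expect_true(res2$corroborated)
  expect_error(tertile_corroboration(
    compare_conditions(A[1:5, ], B[1:5, ], pseudocount = 0)), "9 sites")
})

test_that("tertile_corroboration is invariant to global rescaling", {
  cfg <- sim_config(genome_length = 3e6, n_genes = 300,
                    n_sites_per_isoform = 60, depth_per_assay = 3e5,
                    progressive_fraction = 0.5,
                    condition_scales = list(mild = 1, severe = 2), seed = 77)
  gs <- generate_sites(cfg, generate_annotation(cfg))
  mA <- sim_counts_matrix(cfg, gs$truth, "mild")
  mB <- sim_counts_matrix(cfg, gs$truth, "severe")
  p1 <- tertile_corroboration(compare_conditions(mA, mB, pseudocount = 0))
  mB_scaled <- mB
  for (cl in setdiff(names(mB), "site_id")) mB_scaled[[cl]] <- mB[[cl]] * 7
  p2 <- tertile_corroboration(compare_conditions(mA, mB_scaled,
                                                 pseudocount = 0))
  expect_equal(p1$p.value, p2$p.value)
  expect_equal(p1$tertile, p2$tertile)
})

test_that("wilcoxon wrappers match exact enumeration", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    for (alt in c("two.sided", "greater")) {
      expect_equal(wilcox_ranksum(x, y, alt)$p.value,
                   oracle_ranksum(x, y, alt), tolerance = 1e-12)
    }
    d <- rnorm(sample(4:12, 1))
    for (alt in c("two.sided", "greater")) {
      expect_equal(wilcox_signedrank(d, rep(0, length(d)), alt)$p.value,
                   oracle_signedrank(d, alt), tolerance = 1e-12)
    }
  }
})

test_that("isoform_ratio_stability detects conserved and broken mixing", {
  set.seed(12)
  ids <- sprintf("s%04d", 1:1000)
  a1 <- rlnorm(1000, 2); a2 <- rlnorm(1000, 2); b <- a1 + a2
  A <- as_site_signal_matrix(data.frame(site_id = ids, alpha1 = a1,
                                        alpha2 = a2, beta = b))
  B <- as_site_signal_matrix(data.frame(site_id = ids, alpha1 = a1 * 3,
                                        alpha2 = a2 * 3, beta = b * 3))
  expect_equal(isoform_ratio_stability(A, B, pseudocount = 0)$r, 1)
  Bperm <- B; perm <- sample(1000)
  Bperm$alpha1 <- B$alpha1[perm]; Bperm$alpha2 <- B$alpha2[perm]
  expect_lt(abs(isoform_ratio_stability(A, Bperm, pseudocount = 0)$r), 0.15)
  expect_error(isoform_ratio_stability(A[1:2, ], B[1:2, ]), "3 shared")
})

test_that("classify_specificity is exhaustive, exclusive and antisymmetric", {
  m <- as_site_signal_matrix(data.frame(
    site_id = c("a", "b", "c"), alpha1 = c(100, 1, 10),
    alpha2 = c(1, 100, 10), beta = c(50, 50, 10)))
  cls <- classify_specificity(m, threshold_log2 = 1)
  expect_equal(as.character(cls$class),
               c("isoform1_specific", "isoform2_specific", "shared"))
  swapped <- m; swapped$alpha1 <- m$alpha2; swapped$alpha2 <- m$alpha1
  cls2 <- classify_specificity(swapped, threshold_log2 = 1)
  expect_equal(as.character(cls2$class),
               c("isoform2_specific", "isoform1_specific", "shared"))
  expect_equal(cls$s, -cls2$s)
  # threshold 0: shared class empty (degenerate, allowed)
  cls0 <- classify_specificity(m, threshold_log2 = 0)
  expect_false("shared" %in% cls0$class)
})

test_that("knockout_contrast reports shifts and significance per class", {
  set.seed(13)
  ids <- sprintf("s%03d", 1:40)
  wt <- as_site_signal_matrix(data.frame(
    site_id = ids, alpha1 = rlnorm(40, 3), alpha2 = rlnorm(40, 3),
    beta = rlnorm(40, 3)))
  classes <- classify_specificity(wt, threshold_log2 = 0.5)
  same <- knockout_contrast(wt, wt, "alpha2", classes)
  expect_true(all(same$median_shift == 0))
  expect_true(all(same$p_two_sided == 1))
  boosted <- wt
  boosted$alpha2 <- wt$alpha2 * runif(40, 1.5, 3)  # distinct positive shifts
  up <- knockout_contrast(wt, boosted, "alpha2", classes, pseudocount = 0)
  expect_true(all(up$median_shift > 0))
  # every paired difference positive: the exact one-sided P is 2^-n
  for (i in seq_len(nrow(up)))
    expect_equal(up$p_increase[i], 2^(-up$n[i]), tolerance = 1e-12)
  w <- testthat::capture_warnings(
    knockout_contrast(wt[1:6, ], wt[1:6, ], "alpha2",
                      classify_specificity(wt[1:6, ], 0.5)))
  expect_true(any(grepl("skipped", w)))
})

test_that("conservation_count recovers sharing structure", {
  x <- canonical_sites(peak_set("chr1", c(0, 500), c(100, 600)),
                       peak_set("chr1", c(0, 500), c(100, 600)))
  y <- canonical_sites(peak_set("chr1", c(0, 900), c(100, 980)),
                       peak_set("chr1", c(0, 900), c(100, 980)))
  cons <- conservation_count(list(c1 = x, c2 = y))
  expect_equal(nrow(cons$clusters), 3)
  expect_equal(unname(cons$proportions), c(2 / 3, 1 / 3))
  ident <- conservation_count(list(c1 = x, c2 = x, c3 = x))
  expect_equal(unname(ident$proportions), c(0, 0, 1))
  disjoint <- conservation_count(list(
    c1 = canonical_sites(peak_set("chr1", 0, 10), peak_set("chr1", 0, 10)),
    c2 = canonical_sites(peak_set("chr1", 50, 60), peak_set("chr1", 50, 60))))
  expect_equal(disjoint$shared_2plus, 0)
})
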