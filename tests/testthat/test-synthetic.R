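test_that("generate_annotation places bounded, deterministic, spaced TSSs", {
  cfg <- sim_config(genome_length = 1e7, n_genes = 100, seed = 3)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), 100)
  expect_true(all(ann$tss >= 0 & ann$tss < 1e7))
  expect_identical(as.data.frame(generate_annotation(cfg)),
                   as.data.frame(ann))
  expect_equal(nrow(generate_annotation(sim_config(n_genes = 0))), 0)
  expect_error(generate_annotation(sim_config(genome_length = 1e4,
                                              n_genes = 100)),
               "genome too short")
})

test_that("site placement respects class geometry and separation", {
  cfg <- sim_config(genome_length = 2e7, n_genes = 2000,
                    n_sites_per_isoform = 500, shared_fraction = 0,
                    seed = 5)
  gs <- generate_sites(cfg, generate_annotation(cfg))
  tab <- gs$truth$sites
  expect_equal(nrow(tab), 1000)
  iso1 <- tab[tab$class == "isoform1", ]
  iso2 <- tab[tab$class == "isoform2", ]
  # >= 80% of isoform-1-specific sites within 2 kb of their source TSS
  expect_gte(mean(abs(iso1$tss_offset) <= 2000), 0.8)
  expect_true(all(abs(iso2$tss_offset) >= cfg$isoform2_min_distance))
  expect_true(all(abs(iso2$tss_offset) <= cfg$isoform2_distal_range))
  # no mixing parameter strictly between the specific bounds
  expect_true(all(tab$mix >= 0.9 | tab$mix <= 0.1))
  expect_gte(min(diff(sort(tab$summit))), cfg$min_separation)
  all_shared <- generate_sites(sim_config(n_sites_per_isoform = 20,
                                          shared_fraction = 1, seed = 5),
                               generate_annotation(cfg))
  expect_true(all(all_shared$truth$sites$class == "shared"))
  expect_error(generate_sites(sim_config(genome_length = 1e5, n_genes = 10,
                                         n_sites_per_isoform = 200,
                                         min_separation = 1000, seed = 1),
                              generate_annotation(sim_config(
                                genome_length = 1e5, n_genes = 10))),
               "infeasible packing")
})

test_that("expected counts honour the configured stoichiometry exactly", {
  cfg <- sim_config(n_sites_per_isoform = 50, replicate_cv = 0,
                    alpha_beta_ratio = 1, genome_length = 2e6, n_genes = 200,
                    seed = 7)
  gs <- generate_sites(cfg, generate_annotation(cfg))
  e1 <- simulate_site_counts(cfg, gs$truth, "alpha1", "hypoxia")$expected
  e2 <- simulate_site_counts(cfg, gs$truth, "alpha2", "hypoxia")$expected
  eb <- simulate_site_counts(cfg, gs$truth, "beta", "hypoxia")$expected
  expect_equal((e1 + e2) / eb, rep(1, 100))
  # knockout of isoform 1 zeroes the alpha1 expectation at every site
  cfg_ko <- sim_config(n_sites_per_isoform = 50, genome_length = 2e6,
                       n_genes = 200,
                       condition_scales = list(wt = 1, ko1 = c(alpha1 = 0)),
                       seed = 7)
  gs_ko <- generate_sites(cfg_ko, generate_annotation(cfg_ko))
  expect_true(all(simulate_site_counts(cfg_ko, gs_ko$truth, "alpha1",
                                       "ko1")$expected == 0))
  # beta mirrors the surviving isoform
  eb_ko <- simulate_site_counts(cfg_ko, gs_ko$truth, "beta", "ko1")$expected
  e2_ko <- simulate_site_counts(cfg_ko, gs_ko$truth, "alpha2", "ko1")$expected
  expect_equal(eb_ko, e2_ko / gs_ko$truth$sites$ratio)
  expect_error(simulate_site_counts(cfg, gs$truth, "gamma", "hypoxia"),
               "unknown assay")
  expect_error(simulate_site_counts(cfg, gs$truth, "beta", "anoxia"),
               "unknown condition")
})

test_that("doubling a condition multiplier doubles in-peak counts", {
  cfg <- sim_config(genome_length = 8e6, n_genes = 800,
                    n_sites_per_isoform = 300, depth_per_assay = 1e6,
                    condition_scales = list(mild = 1, severe = 2), seed = 9)
  gs <- generate_sites(cfg, generate_annotation(cfg))
  c1 <- simulate_site_counts(cfg, gs$truth, "beta", "mild", 1)$count
  c2 <- simulate_site_counts(cfg, gs$truth, "beta", "severe", 1)$count
  ratio <- mean(c2) / mean(c1)
  expect_gte(ratio, 1.9)
  expect_lte(ratio, 2.1)
})

test_that("coverage tracks embed site counts plus uniform background", {
  cfg <- sim_config(genome_length = 1e6, n_genes = 100,
                    n_sites_per_isoform = 20, depth_per_assay = 2e5,
                    seed = 11)
  gs <- generate_sites(cfg, generate_annotation(cfg))
  tr <- simulate_coverage(cfg, gs$truth, "alpha1", "hypoxia", 1)
  # the recorded total equals the reads actually placed
  whole <- peak_set("chrS1", 0, cfg$genome_length)
  expect_equal(quantify_signal(tr, whole)$count, tr$total_reads)
  # in-site counts reflect the count-level draw (same derived seed)
  sc <- simulate_site_counts(cfg, gs$truth, "alpha1", "hypoxia", 1)
  insite <- track_sum(tr, gs$truth$sites$chrom, gs$truth$sites$start - 200,
                      gs$truth$sites$end + 200)
  expect_gte(cor(insite, sc$count), 0.99)
  # zero depth: empty track
  cfg0 <- sim_config(genome_length = 1e6, n_genes = 100,
                     n_sites_per_isoform = 20, depth_per_assay = 0, seed = 11)
  tr0 <- simulate_coverage(cfg0, gs$truth, "alpha1", "hypoxia", 1)
  expect_equal(tr0$total_reads, 0)
  expect_equal(length(tr0$chroms), 0)
})

test_that("the stand-in caller finds pulse runs (run-length oracle)", {
  flat <- signal_track(data.frame(chrom = "chr1", start = 0, end = 1000,
                                  value = 0), total_reads = 1,
                       chrom_lengths = c(chr1 = 1000))
  expect_equal(nrow(call_peaks(flat, 5, resolution = 10)), 0)
  pulse <- signal_track(data.frame(chrom = "chr1", start = 400, end = 600,
                                   value = 2), total_reads = 1,
                        chrom_lengths = c(chr1 = 1000))
  pk <- call_peaks(pulse, min_count = 10, window = 10, resolution = 10)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$start, pk$end), c(400, 600))
  expect_true(summit_pos(pk) >= 400 && summit_pos(pk) < 600)
  two <- signal_track(data.frame(chrom = "chr1",
                                 start = c(100, 700), end = c(300, 900),
                                 value = 2), total_reads = 1,
                      chrom_lengths = c(chr1 = 1000))
  pk2 <- call_peaks(two, min_count = 10, window = 10, resolution = 10)
  # oracle: direct run-length scan of the 10-bp binned counts
  bins <- track_sum(two, "chr1", seq(0, 990, 10), seq(10, 1000, 10))
  runs <- rle(bins >= 10)
  expect_equal(nrow(pk2), sum(runs$values))
  expect_equal(pk2$start, c(100, 700))
  expect_error(call_peaks(two, min_count = -1), "min_count")
})

test_that("expression tables mark genes nearest bound sites", {
  cfg <- sim_config(genome_length = 2e6, n_genes = 200,
                    n_sites_per_isoform = 20, expression_sd = 0,
                    expression_effect = 3, seed = 13)
  ann <- generate_annotation(cfg)
  gs <- generate_sites(cfg, ann)
  expr <- generate_expression(cfg, gs$truth, ann)
  reg <- expr$gene_id %in% gs$truth$regulated_genes
  expect_true(all(expr$log2fc[reg] == 3))
  expect_true(all(expr$log2fc[!reg] == 0))
  expect_true(all(expr$pvalue > 0 & expr$pvalue <= 1))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(genome_length = 3e5, n_genes = 30,
                    n_sites_per_isoform = 8, depth_per_assay = 3e4, seed = 17)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(cfg, d1)
  write_simulation(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("YAML configs round-trip into sim_config", {
  skip_if_not_installed("yaml")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_genes: 50", "n_sites_per_isoform: 10", "seed: 4",
               "condition_scales:", "  wt: 1.0", "  ko1:", "    alpha1: 0"),
             f)
  cfg <- read_sim_config(f)
  expect_equal(cfg$n_genes, 50)
  expect_equal(cfg$condition_scales$ko1[["alpha1"]], 0)
})
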