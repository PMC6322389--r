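#' Configuration for the synthetic ChIP-seq experiment generator
#'
#' Defines the study conditions the generator emulates: a single synthetic
#' chromosome carrying gene TSSs; heterodimeric 1:1 alpha:beta site loading
#' with multiplicative replicate noise; two alpha-isoforms with site-wise
#' mixing; isoform-dependent TSS-distance placement (isoform 1
#' promoter-proximal, isoform 2 promoter-distal); graded global loading
#' across conditions with an optional site-wise progressive-loading slope;
#' knockout conditions via per-assay multipliers; and cell-type-specific
#' repertoires with a conserved shared core.
#'
#' @param genome_length synthetic chromosome length in bases.
#' @param n_genes number of gene TSSs, uniformly spaced with jitter.
#' @param n_sites_per_isoform number of sites per isoform class (total sites
#'   = 2x this value, split into specific and shared classes).
#' @param shared_fraction proportion of sites with intermediate isoform
#'   mixing; when `n_cell_lines > 1` these shared sites also form the
#'   conserved core present in every cell line, while isoform-specific sites
#'   are unique to one cell line.
#' @param alpha_beta_ratio true total-alpha : beta loading ratio (default 1,
#'   canonical heterodimeric binding).
#' @param ratio_log2_sd site-wise systematic spread of the log2 alpha:beta
#'   ratio (default 0: any observed ratio variation is pure noise).
#' @param replicate_cv coefficient of variation of the multiplicative
#'   log-normal replicate noise on each site mean.
#' @param depth_per_assay total simulated mapped reads per assay track.
#' @param condition_scales named list of conditions; each element is either a
#'   single global loading multiplier or a named numeric vector of per-assay
#'   multipliers (`alpha1`, `alpha2`, `beta`, plus optional `global`), e.g.
#'   `list(wt = 1, ko1 = c(alpha1 = 0))` for an isoform-1 knockout.
#' @param progressive_fraction proportion of sites given an extra
#'   condition-dependent loading slope.
#' @param progressive_slope_sd spread of the site-wise loading slope (the
#'   effective multiplier of a progressive site is `scale^(1 + slope)`).
#' @param isoform1_proximal_sd sd (bases) of isoform-1 site placement around
#'   TSSs.
#' @param isoform2_distal_range maximum |TSS offset| (bases) for isoform-2
#'   site placement.
#' @param isoform2_min_distance minimum |TSS offset| for isoform-2 sites
#'   (the excluded proximal window).
#' @param min_separation minimum distance between site summits.
#' @param footprint_half_width half-width of the triangular site footprint
#'   kernel (bases).
#' @param site_mean_reads median expected reads per site (base loading is
#'   log-normal across sites).
#' @param site_load_sdlog log-sd of the base-loading distribution (~1 gives
#'   the order-of-100-fold spread seen between strong and weak sites).
#' @param resolution coverage track bin size in bases.
#' @param n_replicates replicates per assay and condition.
#' @param n_cell_lines number of cell lines.
#' @param expression_effect mean log2 fold-change of genes nearest bound
#'   sites in the expression table.
#' @param expression_sd sd of log2 fold-changes around their mean.
#' @param seed master integer seed; all per-assay/condition/replicate streams
#'   are derived from it by stable label hashing, so identical configs give
#'   bit-identical outputs.
#' @return a validated `SimConfig` list.
#' @export
sim_config <- function(genome_length = 2e7,
                       n_genes = 2000,
                       n_sites_per_isoform = 500,
                       shared_fraction = 0.25,
                       alpha_beta_ratio = 1,
                       ratio_log2_sd = 0,
                       replicate_cv = 0.2,
                       depth_per_assay = 2e6,
                       condition_scales = list(hypoxia = 1),
                       progressive_fraction = 0,
                       progressive_slope_sd = 0.5,
                       isoform1_proximal_sd = 500,
                       isoform2_distal_range = 1e5,
                       isoform2_min_distance = 5000,
                       min_separation = 1000,
                       footprint_half_width = 150,
                       site_mean_reads = 200,
                       site_load_sdlog = 1,
                       resolution = 10,
                       n_replicates = 2,
                       n_cell_lines = 1,
                       expression_effect = 2,
                       expression_sd = 0.5,
                       seed = 1) {
  cfg <- list(genome_length = genome_length, chrom = "chrS1",
              n_genes = n_genes, n_sites_per_isoform = n_sites_per_isoform,
              shared_fraction = shared_fraction,
              alpha_beta_ratio = alpha_beta_ratio,
              ratio_log2_sd = ratio_log2_sd, replicate_cv = replicate_cv,
              depth_per_assay = depth_per_assay,
              condition_scales = condition_scales,
              progressive_fraction = progressive_fraction,
              progressive_slope_sd = progressive_slope_sd,
              isoform1_proximal_sd = isoform1_proximal_sd,
              isoform2_distal_range = isoform2_distal_range,
              isoform2_min_distance = isoform2_min_distance,
              min_separation = min_separation,
              footprint_half_width = footprint_half_width,
              site_mean_reads = site_mean_reads,
              site_load_sdlog = site_load_sdlog, resolution = resolution,
              n_replicates = n_replicates, n_cell_lines = n_cell_lines,
              expression_effect = expression_effect,
              expression_sd = expression_sd, seed = seed)
  .assert(genome_length > 0, "genome_length must be positive")
  for (p in c("shared_fraction", "progressive_fraction"))
    .assert(cfg[[p]] >= 0 && cfg[[p]] <= 1, "%s must lie in [0, 1]", p)
  .assert(alpha_beta_ratio > 0, "alpha_beta_ratio must be positive")
  .assert(replicate_cv >= 0, "replicate_cv must be non-negative")
  .assert(depth_per_assay >= 0, "depth_per_assay must be non-negative")
  .assert(length(condition_scales) > 0 && !is.null(names(condition_scales)) &&
            all(nzchar(names(condition_scales))),
          "condition_scales must be a non-empty named list")
  .assert(.is_count(n_genes), "n_genes must be a non-negative integer")
  .assert(.is_count(n_sites_per_isoform),
          "n_sites_per_isoform must be a non-negative integer")
  .assert(.is_count(n_replicates) && n_replicates >= 1, "need >= 1 replicate")
  .assert(.is_count(n_cell_lines) && n_cell_lines >= 1, "need >= 1 cell line")
  .assert(isoform2_min_distance < isoform2_distal_range,
          "isoform2_min_distance must be below isoform2_distal_range")
  class(cfg) <- "SimConfig"
  cfg
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf(paste0("SimConfig: %g bp genome, %d genes, %d sites/isoform ",
                     "(shared fraction %.2f)\n",
                     "  alpha:beta ratio %.2f, replicate CV %.2f, depth %g, ",
                     "%d condition(s), %d cell line(s), seed %d\n"),
              x$genome_length, x$n_genes, x$n_sites_per_isoform,
              x$shared_fraction, x$alpha_beta_ratio, x$replicate_cv,
              x$depth_per_assay, length(x$condition_scales), x$n_cell_lines,
              x$seed))
  invisible(x)
}

#' Read a SimConfig from a YAML file
#'
#' Scalars map directly onto [sim_config()] arguments; `condition_scales`
#' may be a mapping of condition label to either a number or a mapping of
#' assay label to multiplier.
#'
#' @param path YAML file.
#' @return a `SimConfig`.
#' @export
read_sim_config <- function(path) {
  .assert(requireNamespace("yaml", quietly = TRUE),
          "the yaml package is required to read config files")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$condition_scales))
    raw$condition_scales <- lapply(raw$condition_scales, function(x)
      if (is.list(x)) unlist(x) else x)
  do.call(sim_config, raw)
}

.sim_assays <- c("alpha1", "alpha2", "beta")

.cond_entry <- function(cfg, condition) {
  .assert(condition %in% names(cfg$condition_scales),
          "unknown condition '%s'", condition)
  cfg$condition_scales[[condition]]
}

.cond_global <- function(entry) {
  if (is.null(names(entry))) return(unname(entry[1]))
  if ("global" %in% names(entry)) unname(entry[["global"]]) else 1
}

.cond_assay_mult <- function(entry, assay) {
  if (!is.null(names(entry)) && assay %in% names(entry))
    unname(entry[[assay]]) else 1
}
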