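#' Generate the synthetic gene annotation
#'
#' Places `n_genes` TSSs uniformly along the synthetic chromosome with
#' +/- 45% jitter around the regular spacing, so promoters never overlap;
#' strands are random. Deterministic under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return a [gene_annotation()].
#' @export
generate_annotation <- function(cfg) {
  n <- cfg$n_genes
  if (n == 0)
    return(gene_annotation(character(0), character(0), numeric(0),
                           character(0)))
  spacing <- cfg$genome_length / n
  .assert(spacing >= 200,
          "genome too short to place %d genes (spacing %.0f < 200 bp)",
          n, spacing)
  .with_seed(.derive_seed(cfg$seed, "annotation"), {
    tss <- floor((seq_len(n) - 0.5) * spacing +
                   stats::runif(n, -0.45, 0.45) * spacing)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gene_annotation(sprintf("g%05d", seq_len(n)), cfg$chrom, tss, strand)
  })
}

#' Generate ground-truth binding sites
#'
#' Places isoform-1-specific sites close to TSSs (normal offset,
#' `isoform1_proximal_sd`), isoform-2-specific sites at larger distances
#' (uniform magnitude in `[isoform2_min_distance, isoform2_distal_range]`,
#' random side), and shared (conserved-core) sites proximally like isoform-1
#' sites. Shared sites receive an intermediate mixing
#' parameter; summits are kept at least `min_separation` bases apart by
#' rejection sampling. Each site draws a log-normal base loading, a site-wise
#' true alpha:beta ratio, an optional progressive loading slope and (for
#' multi-cell configs) its cell-line assignment.
#'
#' @param cfg a [sim_config()].
#' @param ann the [generate_annotation()] output.
#' @return list with `sites` (truth `PeakSet`; score = base loading) and
#'   `truth` (a `SimTruth`: per-site ground-truth table, per-condition
#'   loading matrix, regulated genes, config).
#' @export
generate_sites <- function(cfg, ann) {
  n_total <- 2L * cfg$n_sites_per_isoform
  if (n_total == 0) {
    empty <- peak_set(character(0), numeric(0), numeric(0))
    conds <- names(cfg$condition_scales)
    tab0 <- data.frame(site_id = character(0), chrom = character(0),
                       start = numeric(0), end = numeric(0),
                       summit = numeric(0), class = character(0),
                       mix = numeric(0), base_loading = numeric(0),
                       ratio = numeric(0), progressive = logical(0),
                       slope = numeric(0), tss_offset = numeric(0),
                       source_gene = character(0))
    tab0$cells <- list()
    truth <- structure(list(
      sites = tab0,
      loading = matrix(numeric(0), 0, length(conds),
                       dimnames = list(NULL, conds)),
      regulated_genes = character(0), config = cfg), class = "SimTruth")
    return(list(sites = empty, truth = truth))
  }
  .assert(nrow(ann) > 0, "annotation is empty but sites were requested")
  hw <- cfg$footprint_half_width
  .assert(n_total * cfg$min_separation <= 0.5 * cfg$genome_length,
          "infeasible packing: %d sites at %d bp separation exceed half the genome",
          n_total, cfg$min_separation)
  n_shared <- round(cfg$shared_fraction * n_total)
  n_spec <- n_total - n_shared
  n1 <- ceiling(n_spec / 2)
  n2 <- n_spec - n1
  cls <- c(rep("isoform1", n1), rep("isoform2", n2), rep("shared", n_shared))
  .with_seed(.derive_seed(cfg$seed, "sites"), {
    summits <- numeric(0)
    summit <- numeric(n_total)
    src_gene <- character(n_total)
    offset <- numeric(n_total)
    lo_lim <- hw
    hi_lim <- cfg$genome_length - hw - 1
    for (i in seq_len(n_total)) {
      placed <- FALSE
      for (try in 1:200) {
        g <- sample.int(nrow(ann), 1)
        off <- switch(cls[i],
          isoform1 = stats::rnorm(1, 0, cfg$isoform1_proximal_sd),
          shared = stats::rnorm(1, 0, cfg$isoform1_proximal_sd),
          isoform2 = sample(c(-1, 1), 1) *
            stats::runif(1, cfg$isoform2_min_distance,
                         cfg$isoform2_distal_range))
        s <- round(ann$tss[g] + off)
        if (s < lo_lim || s > hi_lim) next
        if (length(summits) > 0 && min(abs(summits - s)) < cfg$min_separation)
          next
        summit[i] <- s
        src_gene[i] <- ann$gene_id[g]
        offset[i] <- s - ann$tss[g]
        summits <- c(summits, s)
        placed <- TRUE
        break
      }
      .assert(placed,
              "infeasible packing: could not place site %d of %d", i, n_total)
    }
    mix <- numeric(n_total)
    mix[cls == "isoform1"] <- stats::runif(sum(cls == "isoform1"), 0.9, 1)
    mix[cls == "isoform2"] <- stats::runif(sum(cls == "isoform2"), 0, 0.1)
    mix[cls == "shared"] <- stats::runif(sum(cls == "shared"), 0.25, 0.75)
    base <- stats::rlnorm(n_total, log(cfg$site_mean_reads),
                          cfg$site_load_sdlog)
    ratio <- cfg$alpha_beta_ratio *
      2^stats::rnorm(n_total, 0, cfg$ratio_log2_sd)
    progressive <- stats::runif(n_total) < cfg$progressive_fraction
    slope <- ifelse(progressive,
                    stats::rnorm(n_total, 0, cfg$progressive_slope_sd), 0)
    cells <- if (cfg$n_cell_lines == 1) {
      rep(list(1L), n_total)
    } else {
      lapply(seq_len(n_total), function(i)
        if (cls[i] == "shared") seq_len(cfg$n_cell_lines)
        else sample.int(cfg$n_cell_lines, 1))
    }
    site_id <- sprintf("s%05d", seq_len(n_total))
    tab <- data.frame(site_id = site_id, chrom = cfg$chrom,
                      start = summit - hw, end = summit + hw,
                      summit = summit, class = cls, mix = mix,
                      base_loading = base, ratio = ratio,
                      progressive = progressive, slope = slope,
                      tss_offset = offset, source_gene = src_gene,
                      stringsAsFactors = FALSE)
    tab$cells <- cells
    conds <- names(cfg$condition_scales)
    loading <- vapply(conds, function(cd) {
      g <- .cond_global(.cond_entry(cfg, cd))
      base * (if (g > 0) g^(1 + slope) else rep(0, n_total))
    }, numeric(n_total))
    loading <- matrix(loading, nrow = n_total,
                      dimnames = list(site_id, conds))
    # regulated genes: independent brute-force nearest-gene scan, so that
    # downstream nearest-gene recovery checks compare two distinct routes
    reg <- unique(vapply(seq_len(n_total), function(i) {
      same <- ann$chrom == cfg$chrom
      ann$gene_id[same][which.min(abs(ann$tss[same] - summit[i]))]
    }, ""))
    sites <- peak_set(tab$chrom, tab$start, tab$end, name = tab$site_id,
                      score = tab$base_loading, summit = hw,
                      provenance = list(role = "truth_sites"))
    truth <- structure(list(sites = tab, loading = loading,
                            regulated_genes = reg, config = cfg),
                       class = "SimTruth")
    list(sites = sites, truth = truth)
  })
}

#' @export
print.SimTruth <- function(x, ...) {
  cat(sprintf("SimTruth: %d sites (%s), %d condition(s), %d regulated gene(s)\n",
              nrow(x$sites),
              paste(sprintf("%d %s", table(x$sites$class),
                            names(table(x$sites$class))), collapse = ", "),
              ncol(x$loading), length(x$regulated_genes)))
  invisible(x)
}

# Expected (noise-free) read counts per truth site for one assay/condition.
# Beta mirrors total alpha divided by the site's true alpha:beta ratio, so
# the beta signal redistributes with the surviving isoform in knockouts.
.expected_counts <- function(cfg, truth, assay, condition) {
  .assert(assay %in% .sim_assays, "unknown assay '%s'", assay)
  entry <- .cond_entry(cfg, condition)
  L <- truth$loading[, condition]
  a1 <- L * truth$sites$mix * .cond_assay_mult(entry, "alpha1")
  a2 <- L * (1 - truth$sites$mix) * .cond_assay_mult(entry, "alpha2")
  switch(assay,
         alpha1 = a1, alpha2 = a2,
         beta = (a1 + a2) / truth$sites$ratio * .cond_assay_mult(entry, "beta"))
}

#' Simulate per-site read counts for one assay track
#'
#' The count-level heart of the coverage simulator: each site's expected
#' count (base loading x condition multiplier x isoform mix, with beta
#' mirroring total alpha over the site's true alpha:beta ratio) is perturbed
#' by multiplicative log-normal replicate noise (mean 1, CV `replicate_cv`)
#' and drawn as a Poisson count. CPM uses the configured per-assay depth as
#' the mapped-read total.
#'
#' @param cfg a [sim_config()].
#' @param truth the `SimTruth` from [generate_sites()].
#' @param assay one of `"alpha1"`, `"alpha2"`, `"beta"`.
#' @param condition a name of `cfg$condition_scales`.
#' @param replicate replicate index (its own noise stream).
#' @param cell_line optional cell line; restricts to sites carried by it.
#' @return data frame `site_id`, `expected`, `count`, `cpm`; attribute
#'   `total_reads`.
#' @export
simulate_site_counts <- function(cfg, truth, assay, condition, replicate = 1,
                                 cell_line = NULL) {
  exp_all <- .expected_counts(cfg, truth, assay, condition)
  keep <- if (is.null(cell_line)) rep(TRUE, nrow(truth$sites))
  else vapply(truth$sites$cells, function(cl) cell_line %in% cl, TRUE)
  expd <- exp_all[keep]
  n <- length(expd)
  out <- .with_seed(.derive_seed(cfg$seed, "counts", assay, condition,
                                 replicate,
                                 if (is.null(cell_line)) 0 else cell_line), {
    noise <- if (cfg$replicate_cv > 0) {
      sdlog <- sqrt(log(1 + cfg$replicate_cv^2))
      stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    } else rep(1, n)
    stats::rpois(n, expd * noise)
  })
  cpm <- if (cfg$depth_per_assay > 0) out * 1e6 / cfg$depth_per_assay else
    rep(0, n)
  res <- data.frame(site_id = truth$sites$site_id[keep], expected = expd,
                    count = out, cpm = cpm, stringsAsFactors = FALSE)
  attr(res, "total_reads") <- cfg$depth_per_assay
  res
}

#' Simulate a genome-wide coverage track
#'
#' Site counts from [simulate_site_counts()] are spread over each site's
#' footprint with a triangular kernel centred on the summit (mimicking ChIP
#' fragment pileup without modelling fragments); uniform background reads
#' fill the remainder of `depth_per_assay`. The recorded total is the number
#' of reads actually placed.
#'
#' @inheritParams simulate_site_counts
#' @return a [signal_track()] at `cfg$resolution` base resolution.
#' @export
simulate_coverage <- function(cfg, truth, assay, condition, replicate = 1,
                              cell_line = NULL) {
  res <- cfg$resolution
  nb <- ceiling(cfg$genome_length / res)
  if (cfg$depth_per_assay == 0)
    return(signal_track(data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0), value = numeric(0)),
                        total_reads = 0,
                        chrom_lengths = stats::setNames(cfg$genome_length,
                                                        cfg$chrom)))
  sc <- simulate_site_counts(cfg, truth, assay, condition, replicate,
                             cell_line)
  bins <- numeric(nb)
  if (nrow(sc) > 0) {
    keep <- match(sc$site_id, truth$sites$site_id)
    summit_bin <- pmin(nb, pmax(1, floor(truth$sites$summit[keep] / res) + 1))
    bw <- max(1L, round(cfg$footprint_half_width / res))
    kern <- 1 - abs(seq(-bw, bw)) / (bw + 1)
    .with_seed(.derive_seed(cfg$seed, "spread", assay, condition, replicate,
                            if (is.null(cell_line)) 0 else cell_line), {
      for (i in seq_len(nrow(sc))) {
        if (sc$count[i] == 0) next
        alloc <- stats::rmultinom(1, sc$count[i], kern)[, 1]
        at <- summit_bin[i] + seq(-bw, bw)
        ok <- at >= 1 & at <= nb
        bins[at[ok]] <- bins[at[ok]] + alloc[ok]
      }
    })
  }
  bg_total <- max(0, cfg$depth_per_assay - sum(sc$count))
  bg <- .with_seed(.derive_seed(cfg$seed, "background", assay, condition,
                                replicate,
                                if (is.null(cell_line)) 0 else cell_line),
                   stats::rpois(nb, bg_total / nb))
  bins <- bins + bg
  r <- rle(bins)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  runs <- data.frame(chrom = cfg$chrom, start = starts * res,
                     end = pmin(ends * res, cfg$genome_length),
                     value = r$values / res)
  signal_track(runs, total_reads = sum(bins),
               chrom_lengths = stats::setNames(cfg$genome_length, cfg$chrom))
}

#' Stand-in peak caller
#'
#' A deliberately simple caller so the synthetic pipeline runs end-to-end:
#' maximal runs of bins whose smoothed per-bin read count is at least
#' `min_count` become peaks, with the summit at the position of the maximum
#' raw bin count. Deterministic.
#'
#' @param track a [signal_track()].
#' @param min_count per-bin count threshold (> 0).
#' @param window smoothing window in bases (> 0; moving average).
#' @param resolution bin size in bases for scanning the track.
#' @return a [peak_set()] with summits; score = maximum bin count.
#' @export
call_peaks <- function(track, min_count, window = 50, resolution = 10) {
  .assert(is.numeric(min_count) && min_count > 0, "min_count must be > 0")
  .assert(is.numeric(window) && window > 0, "window must be > 0")
  out <- NULL
  for (ch in names(track$chroms)) {
    tr <- track$chroms[[ch]]
    L <- max(tr$end)
    clen <- track$chrom_lengths[[ch]]
    if (!is.null(clen) && !is.na(clen)) L <- max(L, clen)
    nb <- ceiling(L / resolution)
    edges <- resolution * (0:nb)
    binval <- diff(.area_at(tr, edges))  # reads per bin
    k <- max(1L, round(window / resolution))
    if (k %% 2 == 0) k <- k + 1L
    sm <- as.numeric(stats::filter(binval, rep(1 / k, k), sides = 2))
    sm[is.na(sm)] <- 0
    above <- sm >= min_count
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)]) + 1L
    for (j in which(r$values)) {
      b0 <- starts[j]; b1 <- ends[j]
      peak_start <- (b0 - 1) * resolution
      peak_end <- min(b1 * resolution, L)
      rel <- b0 - 1 + which.max(binval[b0:b1])
      summit <- min((rel - 1) * resolution + floor(resolution / 2),
                    peak_end - 1)
      out <- rbind(out, data.frame(chrom = ch, start = peak_start,
                                   end = peak_end,
                                   summit = summit - peak_start,
                                   score = max(binval[b0:b1]),
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    return(peak_set(character(0), numeric(0), numeric(0)))
  peak_set(out$chrom, out$start, out$end,
           name = sprintf("peak_%05d", seq_len(nrow(out))),
           score = out$score, summit = out$summit)
}

#' Generate the ranked gene-expression table
#'
#' Genes nearest truth sites (the generator's regulated set) receive log2
#' fold-changes `expression_effect + Normal(0, expression_sd)` and small
#' p-values; all other genes are null (`Normal(0, expression_sd)` fold
#' change, uniform p-value).
#'
#' @param cfg a [sim_config()].
#' @param truth the `SimTruth` from [generate_sites()].
#' @param ann the [generate_annotation()] output.
#' @return data frame `gene_id`, `log2fc`, `pvalue`; the true regulated
#'   genes in the `regulated` attribute.
#' @export
generate_expression <- function(cfg, truth, ann) {
  n <- nrow(ann)
  .with_seed(.derive_seed(cfg$seed, "expression"), {
    flag <- ann$gene_id %in% truth$regulated_genes
    l2fc <- stats::rnorm(n, 0, cfg$expression_sd) +
      ifelse(flag, cfg$expression_effect, 0)
    pv <- ifelse(flag, stats::runif(n, 1e-8, 1e-3), stats::runif(n))
    out <- data.frame(gene_id = ann$gene_id, log2fc = l2fc, pvalue = pv,
                      stringsAsFactors = FALSE)
    attr(out, "regulated") <- ann$gene_id[flag]
    out
  })
}

#' Run the generator end-to-end and write all files
#'
#' Emits the annotation (GTF + TSS BED6), truth sites (BED with score =
#' expected base loading), per assay x condition x replicate (x cell line)
#' bedGraph coverage with a totals TSV, stand-in peak calls (BED), the
#' ranked expression table (TSV) and a JSON ground-truth file.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param min_count stand-in caller threshold passed to [call_peaks()].
#' @return invisibly, a list with the generated objects and file paths.
#' @export
write_simulation <- function(cfg, outdir, min_count = 5) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "coverage"), showWarnings = FALSE)
  dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
  ann <- generate_annotation(cfg)
  gs <- generate_sites(cfg, ann)
  write_gtf_genes(ann, file.path(outdir, "annotation.gtf"))
  write_tss_bed(ann, file.path(outdir, "tss.bed"))
  write_bed(gs$sites, file.path(outdir, "truth_sites.bed"))
  expr <- generate_expression(cfg, gs$truth, ann)
  utils::write.table(expr, file.path(outdir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  totals <- NULL
  cells <- seq_len(cfg$n_cell_lines)
  for (cell in cells) for (cd in names(cfg$condition_scales))
    for (as in .sim_assays) for (rp in seq_len(cfg$n_replicates)) {
      label <- if (cfg$n_cell_lines > 1)
        sprintf("cell%d_%s_%s_r%d", cell, as, cd, rp)
      else sprintf("%s_%s_r%d", as, cd, rp)
      tr <- simulate_coverage(cfg, gs$truth, as, cd, rp,
                              cell_line = if (cfg$n_cell_lines > 1) cell)
      write_bedgraph(tr, file.path(outdir, "coverage",
                                   paste0(label, ".bedgraph")))
      pk <- call_peaks(tr, min_count = min_count,
                       resolution = cfg$resolution)
      write_bed(pk, file.path(outdir, "peaks", paste0(label, ".bed")))
      totals <- rbind(totals, data.frame(track = label,
                                         total_reads = tr$total_reads))
    }
  utils::write.table(totals, file.path(outdir, "totals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth_json <- list(
    sites = cbind(gs$truth$sites[setdiff(names(gs$truth$sites), "cells")],
                  cells = vapply(gs$truth$sites$cells, paste, "",
                                 collapse = ",")),
    loading = as.data.frame(gs$truth$loading),
    regulated_genes = gs$truth$regulated_genes)
  jsonlite::write_json(truth_json, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(annotation = ann, sites = gs$sites, truth = gs$truth,
                 expression = expr, outdir = outdir))
}
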