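#' Build a site-by-assay signal matrix
#'
#' The central quantitative object: one row per site, one CPM column per
#' assay track. Column names follow the `<assay>_<replicate>` convention
#' (e.g. `alpha1_r1`, `beta_r2`); downstream functions average replicate
#' columns of the same assay on the CPM scale (arithmetic mean after
#' normalization).
#'
#' @param sites a [peak_set()] of canonical sites.
#' @param tracks named list of [signal_track()]s; names become columns.
#' @return a `SiteSignalMatrix` (data frame with `site_id` + CPM columns).
#' @export
site_signal_matrix <- function(sites, tracks) {
  .assert(length(tracks) > 0 && !is.null(names(tracks)),
          "tracks must be a named list")
  out <- data.frame(site_id = sites$name, stringsAsFactors = FALSE)
  for (nm in names(tracks)) out[[nm]] <- quantify_signal(tracks[[nm]], sites)$cpm
  class(out) <- c("SiteSignalMatrix", "data.frame")
  attr(out, "sites") <- sites
  out
}

#' @rdname site_signal_matrix
#' @param df data frame with a `site_id` column and numeric CPM columns, used
#'   when signal was quantified elsewhere (e.g. the count-level simulator).
#' @export
as_site_signal_matrix <- function(df) {
  .assert(is.data.frame(df) && "site_id" %in% names(df),
          "need a data frame with a site_id column")
  num <- setdiff(names(df), "site_id")
  .assert(length(num) > 0 && all(vapply(df[num], is.numeric, TRUE)),
          "all assay columns must be numeric")
  class(df) <- c("SiteSignalMatrix", "data.frame")
  df
}

# Columns of `mat` belonging to an assay: exact name or <assay>_<rep>.
.assay_cols <- function(mat, assay) {
  cols <- grep(sprintf("^%s(_|$)", assay), names(mat), value = TRUE)
  .assert(length(cols) > 0, "no columns for assay '%s'", assay)
  cols
}

.assay_mean <- function(mat, assay) {
  cols <- .assay_cols(mat, assay)
  if (length(cols) == 1) mat[[cols]] else rowMeans(mat[cols])
}

.assay_reps <- function(mat, assay) {
  cols <- .assay_cols(mat, assay)
  reps <- sub(sprintf("^%s_?", assay), "", cols)
  stats::setNames(cols, ifelse(nzchar(reps), reps, "r1"))
}

#' Correlation of total alpha with beta signal
#'
#' Per-site total alpha (alpha1 + alpha2, replicate-averaged CPM) is paired
#' with beta signal and the Pearson correlation computed on
#' `log10(CPM + pseudocount)`, the scatter that underlies the heterodimer
#' stoichiometry argument.
#'
#' @param mat a [site_signal_matrix()] with alpha1/alpha2/beta columns.
#' @param pseudocount CPM pseudocount (default 0.1).
#' @return list with `total_alpha`, `beta` and Pearson `r`.
#' @export
alpha_beta_correlation <- function(mat, pseudocount = 0.1) {
  .assert(nrow(mat) >= 3, "need at least 3 sites for a correlation")
  ta <- .assay_mean(mat, "alpha1") + .assay_mean(mat, "alpha2")
  be <- .assay_mean(mat, "beta")
  list(total_alpha = ta, beta = be,
       r = stats::cor(log10(ta + pseudocount), log10(be + pseudocount)))
}

#' Distribution of per-site alpha:beta stoichiometry ratios
#'
#' Computes `r = (alpha1 + alpha2 + pc) / (beta + pc)` per site on
#' replicate-averaged CPM and summarizes its distribution on the log2 scale:
#' histogram, median, mode bin and central-98% fold-range (the multiplicative
#' span between the 1st and 99th percentile ratio).
#'
#' @param mat a [site_signal_matrix()].
#' @param pseudocount CPM pseudocount (default 0.1).
#' @param n_bins number of log2 histogram bins (default 50).
#' @return a `StoichiometryResult` list: `ratio`, `log2_ratio`, `histogram`
#'   (bin edges/mids/proportions), `median`, `mode`, `fold_range_98`.
#' @export
ratio_distribution <- function(mat, pseudocount = 0.1, n_bins = 50) {
  ta <- .assay_mean(mat, "alpha1") + .assay_mean(mat, "alpha2")
  be <- .assay_mean(mat, "beta")
  r <- (ta + pseudocount) / (be + pseudocount)
  l2 <- log2(r)
  rng <- range(l2)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
  h <- graphics::hist(l2, breaks = edges, plot = FALSE)
  prop <- h$counts / sum(h$counts)
  q <- stats::quantile(r, c(0.01, 0.99), type = 1, names = FALSE)
  structure(list(ratio = r, log2_ratio = l2,
                 histogram = data.frame(mid = h$mids, proportion = prop),
                 median = stats::median(r),
                 mode = h$mids[which.max(prop)],
                 fold_range_98 = q[2] / q[1]),
            class = "StoichiometryResult")
}

#' @export
print.StoichiometryResult <- function(x, ...) {
  cat(sprintf(paste0("alpha:beta stoichiometry over %d sites\n",
                     "  median ratio %.3f, mode at log2 %.3f, ",
                     "central-98%% fold range %.2f\n"),
              length(x$ratio), x$median, x$mode, x$fold_range_98))
  invisible(x)
}

#' @export
plot.StoichiometryResult <- function(x, ...) {
  graphics::plot(x$histogram$mid, x$histogram$proportion, type = "h",
       xlab = "log2 (total alpha / beta)", ylab = "proportion of sites", ...)
  invisible(x)
}

#' Replicate reproducibility of the alpha:beta ratio
#'
#' The per-site log2 total-alpha:beta ratio is computed independently in each
#' replicate and correlated between replicates. If apparent deviations from
#' 1:1 stoichiometry are stochastic noise, this correlation is near zero; a
#' genuine site-wise stoichiometry difference would reproduce. The result is
#' flagged `noise_dominated` when `r` falls below `threshold`.
#'
#' @param mat a [site_signal_matrix()] with per-replicate columns
#'   (`alpha1_r1`, `alpha1_r2`, ...).
#' @param pseudocount CPM pseudocount (default 0.1).
#' @param threshold flag threshold on the correlation (default 0.2).
#' @return list with per-replicate log2 ratios, Pearson `r`, least-squares
#'   `slope` of replicate 2 on replicate 1, and `noise_dominated`.
#' @export
ratio_reproducibility <- function(mat, pseudocount = 0.1, threshold = 0.2) {
  reps <- lapply(c("alpha1", "alpha2", "beta"), function(a) .assay_reps(mat, a))
  common <- Reduce(intersect, lapply(reps, names))
  .assert(length(common) >= 2,
          "need at least two replicates shared by all assays")
  r12 <- lapply(common[1:2], function(rp) {
    ta <- mat[[reps[[1]][rp]]] + mat[[reps[[2]][rp]]]
    be <- mat[[reps[[3]][rp]]]
    log2((ta + pseudocount) / (be + pseudocount))
  })
  r <- stats::cor(r12[[1]], r12[[2]])
  slope <- stats::cov(r12[[1]], r12[[2]]) / stats::var(r12[[1]])
  list(log2_ratio_rep1 = r12[[1]], log2_ratio_rep2 = r12[[2]], r = r,
       slope = slope, noise_dominated = r < threshold)
}
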