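#' Empirical nearest-rank percentile
#'
#' The value of the ascending sort at the smallest rank strictly exceeding
#' `p/100 * N` (capped at N), without interpolation, so thresholds are
#' exactly reproducible across platforms. This is the rank at which a count
#' strictly above the threshold has an empirical tail probability below
#' `1 - p/100`; at non-integer `p*N/100` it coincides with the usual
#' `ceiling(p/100 * N)` nearest-rank value.
#'
#' @param x numeric sample.
#' @param percentile percentile in (0, 100).
#' @return the nearest-rank percentile value.
#' @export
percentile_threshold <- function(x, percentile) {
  .assert(length(x) > 0, "empty sample")
  .assert(is.numeric(percentile) && percentile > 0 && percentile < 100,
          "percentile must lie in (0, 100)")
  v <- round(percentile / 100 * length(x), 6)
  sort(x)[min(length(x), floor(v) + 1L)]
}

#' Filter candidate peaks against an empirical background percentile
#'
#' Keeps peaks whose total count is strictly greater than the nearest-rank
#' percentile (default the 99.99th) of counts at random background regions,
#' the quantitative filter applied to every candidate peak list.
#'
#' @param peaks a [peak_set()] of candidate peaks.
#' @param counts numeric vector of counts under each peak (aligned to `peaks`).
#' @param background_counts counts at background regions (non-empty).
#' @param percentile percentile in (0, 100); default 99.99.
#' @return the retained subset of `peaks`, with the threshold in the
#'   `threshold` attribute.
#' @export
percentile_filter <- function(peaks, counts, background_counts,
                              percentile = 99.99) {
  .assert(length(counts) == nrow(peaks), "counts not aligned to peaks")
  .assert(length(background_counts) > 0, "empty background counts")
  thr <- percentile_threshold(background_counts, percentile)
  out <- peaks[counts > thr, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Replicate-consensus peaks
#'
#' Peaks from two independent replicates that overlap by at least
#' `min_overlap` bases are merged into consensus sites. Mutually overlapping
#' peaks are clustered (single linkage), a cluster is kept only when it
#' contains peaks from both replicates, its coordinates are the union span
#' (no supported base is lost), and the summit is taken from the strongest
#' member peak (highest score).
#'
#' @param rep1,rep2 filtered [peak_set()]s from the two replicates.
#' @param min_overlap minimum overlapping bases (default 1).
#' @return a `PeakSet` of consensus sites; provenance records member counts.
#' @export
replicate_consensus <- function(rep1, rep2, min_overlap = 1) {
  .assert(.is_count(min_overlap) && min_overlap >= 1,
          "min_overlap must be a positive integer")
  if (nrow(rep1) == 0 || nrow(rep2) == 0)
    return(peak_set(character(0), numeric(0), numeric(0)))
  pooled <- rbind(
    cbind(as.data.frame(rep1), .rep = 1L),
    cbind(as.data.frame(rep2), .rep = 2L))
  o <- order(pooled$chrom, pooled$start, pooled$end)
  pooled <- pooled[o, , drop = FALSE]
  ids <- .cluster_ids(pooled, min_overlap)
  out <- .merge_clusters(pooled, ids, require_groups = 2L,
                         group = pooled$.rep)
  attr(out, "provenance") <- list(step = "replicate_consensus",
                                  n_rep1 = nrow(rep1), n_rep2 = nrow(rep2))
  out
}

# Collapse clusters into union-span sites; optionally require members from
# `require_groups` distinct groups. Summit/score from the strongest member.
.merge_clusters <- function(pooled, ids, require_groups = 1L, group = NULL) {
  keep_cl <- unique(ids)
  if (!is.null(group) && require_groups > 1L) {
    ngrp <- vapply(split(group, ids), function(g) length(unique(g)), 0L)
    keep_cl <- as.integer(names(ngrp)[ngrp >= require_groups])
  }
  rows <- split(seq_along(ids), ids)
  rows <- rows[as.character(keep_cl)]
  if (length(rows) == 0)
    return(peak_set(character(0), numeric(0), numeric(0)))
  chrom <- start <- end <- summit <- score <- NULL
  chrom <- vapply(rows, function(r) pooled$chrom[r[1]], "")
  start <- vapply(rows, function(r) min(pooled$start[r]), 0)
  end <- vapply(rows, function(r) max(pooled$end[r]), 0)
  best <- vapply(rows, function(r) r[which.max(pooled$score[r])], 0L)
  score <- pooled$score[best]
  bsum <- pooled$summit[best]
  bsum_abs <- ifelse(is.na(bsum),
                     pooled$start[best] + floor((pooled$end[best] - pooled$start[best]) / 2),
                     pooled$start[best] + bsum)
  ps <- peak_set(chrom, start, end,
                 name = sprintf("site_%05d", seq_along(rows)),
                 score = score, summit = bsum_abs - start)
  # peak_set() re-sorts; rows built from sorted pooled input remain in order
  ps
}

#' Canonical heterodimer sites
#'
#' Canonical sites for one isoform are the alpha-subunit consensus sites
#' (supported by both alpha replicates) that also overlap the beta-subunit
#' consensus (supported by both beta replicates) by at least `min_overlap`
#' bases. Alpha coordinates are retained.
#'
#' @param alpha_consensus,beta_consensus outputs of [replicate_consensus()].
#' @param min_overlap minimum overlapping bases (default 1).
#' @param isoform label, `"isoform1"` or `"isoform2"`.
#' @return a `CanonicalSiteSet` (a `PeakSet` with an `isoform` attribute).
#' @export
canonical_sites <- function(alpha_consensus, beta_consensus, min_overlap = 1,
                            isoform = "isoform1") {
  out <- intersect_peaks(alpha_consensus, beta_consensus, min_overlap)
  class(out) <- c("CanonicalSiteSet", class(out))
  attr(out, "isoform") <- isoform
  attr(out, "provenance") <- list(step = "canonical_sites",
                                  n_alpha = nrow(alpha_consensus),
                                  n_beta = nrow(beta_consensus))
  out
}

#' Cross-condition superset of canonical sites
#'
#' Combines canonical site sets from several conditions into the superset of
#' sites identified in one condition or another or both: sites are clustered
#' by single-linkage overlap, cluster coordinates are the union span, and
#' per-condition membership flags are recorded in `in_<label>` columns.
#'
#' @param site_sets named list of `CanonicalSiteSet`s with the same isoform.
#' @param min_overlap minimum overlapping bases (default 1).
#' @return a `CanonicalSiteSet` with membership columns.
#' @export
condition_superset <- function(site_sets, min_overlap = 1) {
  .assert(length(site_sets) >= 1, "need at least one site set")
  isoforms <- unique(vapply(site_sets, function(s) {
    iso <- attr(s, "isoform")
    if (is.null(iso)) NA_character_ else iso
  }, ""))
  .assert(length(isoforms) == 1, "mixed isoform labels in superset input")
  labels <- names(site_sets)
  if (is.null(labels)) labels <- sprintf("set%d", seq_along(site_sets))
  pooled <- do.call(rbind, lapply(seq_along(site_sets), function(i)
    cbind(as.data.frame(site_sets[[i]]), .set = labels[i])))
  o <- order(pooled$chrom, pooled$start, pooled$end)
  pooled <- pooled[o, , drop = FALSE]
  ids <- .cluster_ids(pooled, min_overlap)
  out <- .merge_clusters(pooled, ids)
  cl <- sort(unique(ids))  # rows of `out` follow increasing cluster id
  for (lb in sort(labels))
    out[[paste0("in_", lb)]] <- cl %in% ids[pooled$.set == lb]
  class(out) <- c("CanonicalSiteSet", class(out))
  attr(out, "isoform") <- isoforms
  out
}
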