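#' Quantify normalized signal at a set of sites
#'
#' For each site the raw count is the sum of per-base coverage over
#' `[start, end)`; CPM is `count * 1e6 / total_mapped_reads` and RPKM is
#' `CPM * 1e3 / (end - start)`.
#'
#' @param track a [signal_track()] with `total_reads > 0`.
#' @param sites a [peak_set()].
#' @return data frame with columns `site_id`, `width`, `count`, `cpm`, `rpkm`.
#' @export
quantify_signal <- function(track, sites) {
  .assert(inherits(track, "SignalTrack"), "track must be a SignalTrack")
  .assert(track$total_reads > 0, "track has no mapped reads recorded")
  width <- sites$end - sites$start
  .assert(all(width > 0), "zero-length site")
  count <- track_sum(track, sites$chrom, sites$start, sites$end)
  cpm <- count * 1e6 / track$total_reads
  data.frame(site_id = sites$name, width = width, count = count, cpm = cpm,
             rpkm = cpm * 1e3 / width, stringsAsFactors = FALSE)
}

#' Sample random non-overlapping background regions
#'
#' Draws `n` fixed-width, non-overlapping regions from within the intervals of
#' a universe (e.g. accessible chromatin), the empirical null against which
#' candidate peaks are percentile-filtered. Each universe interval is covered
#' by a grid of width-`width` slots at a random offset and `n` slots are
#' sampled uniformly without replacement, which guarantees non-overlap.
#'
#' @param universe a [peak_set()] of intervals to draw from.
#' @param n number of regions.
#' @param width region width in bases (default 400).
#' @param seed integer seed; the same seed yields the identical sample.
#' @return a `PeakSet` of `n` regions with provenance `role = "background"`.
#' @export
sample_background <- function(universe, n, width = 400, seed = 1) {
  .assert(.is_count(n), "n must be a non-negative integer")
  .assert(.is_count(width) && width >= 1, "width must be a positive integer")
  caps <- floor((universe$end - universe$start) / width)
  .assert(sum(caps) >= n,
          "cannot place %d non-overlapping regions of %d bases; maximum is %d",
          n, width, sum(caps))
  .with_seed(.derive_seed(seed, "background", n, width), {
    starts <- chroms <- NULL
    slot_start <- vector("list", nrow(universe))
    for (i in seq_len(nrow(universe))) {
      if (caps[i] == 0) next
      slack <- (universe$end[i] - universe$start[i]) - caps[i] * width
      off <- if (slack > 0) sample.int(slack + 1, 1) - 1 else 0
      slot_start[[i]] <- universe$start[i] + off + width * (seq_len(caps[i]) - 1)
    }
    all_starts <- unlist(slot_start)
    all_chroms <- rep(universe$chrom, vapply(slot_start, length, 0L))
    pick <- sample.int(length(all_starts), n)
    peak_set(all_chroms[pick], all_starts[pick], all_starts[pick] + width,
             name = sprintf("bg_%06d", seq_len(n)),
             provenance = list(role = "background", width = width))
  })
}

#' Signal heatmap matrix around site summits
#'
#' One row per site (sorted descending by `order_by`, as in heatmaps ordered
#' by partner-subunit signal intensity), one column per bin across
#' `[summit - flank, summit + flank)`. Values are CPM-normalized mean per-base
#' counts per bin. Windows truncated by chromosome ends are zero-padded and
#' flagged in the `truncated` attribute.
#'
#' @param track a [signal_track()].
#' @param sites a [peak_set()].
#' @param flank half-window in bases (> 0), e.g. 5000 for +/- 5 kb.
#' @param bins number of equal-width bins (>= 1).
#' @param order_by numeric vector (one per site) used to sort rows descending;
#'   defaults to the site scores.
#' @return numeric matrix with site names as row names.
#' @export
heatmap_matrix <- function(track, sites, flank = 5000, bins = 100,
                           order_by = NULL) {
  .assert(flank > 0, "flank must be > 0")
  .assert(.is_count(bins) && bins >= 1, "bins must be >= 1")
  if (is.null(order_by)) order_by <- sites$score
  .assert(length(order_by) == nrow(sites), "order_by length mismatch")
  o <- order(-order_by)
  sites <- sites[o, , drop = FALSE]
  centers <- summit_pos(sites)
  binw <- 2 * flank / bins
  m <- matrix(0, nrow(sites), bins,
              dimnames = list(sites$name, NULL))
  truncated <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    tr <- track$chroms[[sites$chrom[i]]]
    edges <- centers[i] - flank + binw * (0:bins)
    if (!is.null(tr)) {
      a <- .area_at(tr, edges)
      m[i, ] <- diff(a) / binw * 1e6 / track$total_reads
    }
    clen <- track$chrom_lengths[sites$chrom[i]]
    truncated[i] <- edges[1] < 0 ||
      (!is.null(clen) && !is.na(clen) && edges[bins + 1] > clen)
  }
  attr(m, "truncated") <- truncated
  attr(m, "flank") <- flank
  m
}

#' Compare site signal to the empirical background baseline
#'
#' The baseline is the mean background signal (e.g. HIF-1beta CPM at non-HIF
#' accessible sites); the fraction of sites strictly above it and the
#' rank-ordered site series (sites sorted ascending by signal, for line
#' plots against rank) are returned.
#'
#' @param site_signal numeric vector of per-site signal (e.g. beta CPM).
#' @param background_signal numeric vector of background signal.
#' @return list with `baseline`, `fraction_above` and `series`.
#' @export
baseline_comparison <- function(site_signal, background_signal) {
  .assert(length(background_signal) > 0, "empty background signal")
  .assert(length(site_signal) > 0, "empty site signal")
  baseline <- mean(background_signal)
  list(baseline = baseline,
       fraction_above = mean(site_signal > baseline),
       series = sort(site_signal))
}
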