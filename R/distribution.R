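#' Signed distance from each site to its nearest TSS
#'
#' For each site summit (midpoint fallback when no summit is recorded) the
#' TSS minimizing `|TSS - summit|` on the same chromosome is found by an
#' exhaustive same-chromosome search (binary partition internally). The
#' signed distance is `(summit - TSS) * strand_sign`, so negative values are
#' upstream of the TSS relative to gene orientation. Equidistant TSSs are
#' broken deterministically towards the lexicographically smaller gene_id and
#' flagged. Sites on chromosomes absent from the annotation are excluded and
#' listed in the `excluded` attribute.
#'
#' @param sites a [peak_set()].
#' @param ann a [gene_annotation()] (non-empty).
#' @return data frame with `site_id`, `gene_id`, `distance`, `tie`;
#'   attributes `excluded` (site ids without a same-chromosome TSS).
#' @export
nearest_tss <- function(sites, ann) {
  .assert(nrow(ann) > 0, "empty gene annotation")
  sm <- summit_pos(sites)
  out <- data.frame(site_id = sites$name, gene_id = NA_character_,
                    distance = NA_real_, tie = FALSE,
                    stringsAsFactors = FALSE)
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    a <- ann[ann$chrom == ch, , drop = FALSE]
    if (nrow(a) == 0) next
    # annotation is sorted by tss; resolve ties among equal positions by
    # gene_id (gene_annotation sorts that way already)
    pos <- a$tss
    i <- findInterval(sm[idx], pos)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, nrow(a))
    dlo <- abs(sm[idx] - pos[lo])
    dhi <- abs(sm[idx] - pos[hi])
    pick <- ifelse(i < 1L, hi, ifelse(i >= nrow(a), lo,
                                      ifelse(dlo <= dhi, lo, hi)))
    tie <- i >= 1L & i < nrow(a) & dlo == dhi & lo != hi
    # tie-break: smaller gene_id lexicographically
    for (t in which(tie)) {
      cand <- c(lo[t], hi[t])
      pick[t] <- cand[order(a$gene_id[cand])][1]
    }
    sgn <- ifelse(a$strand[pick] == "-", -1, 1)
    out$gene_id[idx] <- a$gene_id[pick]
    out$distance[idx] <- (sm[idx] - pos[pick]) * sgn
    out$tie[idx] <- tie
  }
  excluded <- out$site_id[is.na(out$distance)]
  if (length(excluded))
    message(sprintf("%d site(s) on chromosomes absent from the annotation were excluded",
                    length(excluded)))
  res <- out[!is.na(out$distance), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

# Default symmetric log-magnitude bin scheme: per side 0-1 kb, 1-10 kb,
# 10-100 kb, > 100 kb, plus a dedicated zero bin.
.default_bins <- function() {
  lo <- c(-Inf, -1e5, -1e4, -1e3, 0, 0, 1e3, 1e4, 1e5)
  hi <- c(-1e5, -1e4, -1e3, 0, 0, 1e3, 1e4, 1e5, Inf)
  data.frame(bin_low = lo, bin_high = hi)
}

#' Bin signed TSS distances into a frequency profile
#'
#' Default bins are symmetric log-spaced magnitude bins (0-1 kb, 1-10 kb,
#' 10-100 kb, > 100 kb on each side) plus a dedicated bin for exactly zero.
#' A custom scheme is given as a numeric vector of signed edges
#' (left-open, right-closed). Counts are retained alongside proportions;
#' two profiles are comparable only on an identical scheme.
#'
#' @param distances numeric vector of signed distances (>= 1 value), e.g.
#'   the `distance` column of [nearest_tss()].
#' @param breaks optional numeric vector of signed bin edges.
#' @return a `DistanceProfile` data frame (`bin_low`, `bin_high`, `count`,
#'   `proportion`) with `n_sites` and `breaks` attributes.
#' @export
distance_histogram <- function(distances, breaks = NULL) {
  .assert(length(distances) >= 1, "no distances to bin")
  .assert(!anyNA(distances), "NA distances")
  if (is.null(breaks)) {
    bins <- .default_bins()
    zero <- bins$bin_low == 0 & bins$bin_high == 0
    count <- integer(nrow(bins))
    count[zero] <- sum(distances == 0)
    d <- distances[distances != 0]
    for (i in which(!zero)) {
      # magnitude bins: (low, high] on the positive side, [low, high) mirrored
      if (bins$bin_high[i] <= 0)
        count[i] <- sum(d >= bins$bin_low[i] & d < bins$bin_high[i] |
                          (is.infinite(bins$bin_low[i]) & d < bins$bin_high[i]))
      else
        count[i] <- sum(d > bins$bin_low[i] & d <= bins$bin_high[i])
    }
    key <- "default"
  } else {
    .assert(is.numeric(breaks) && length(breaks) >= 2 &&
              !is.unsorted(breaks, strictly = TRUE), "invalid breaks")
    .assert(all(distances > breaks[1] & distances <= breaks[length(breaks)]),
            "distances outside the bin scheme")
    cutc <- cut(distances, breaks = breaks, right = TRUE)
    count <- as.integer(table(cutc))
    bins <- data.frame(bin_low = breaks[-length(breaks)],
                       bin_high = breaks[-1])
    key <- paste(breaks, collapse = ",")
  }
  out <- cbind(bins, count = count, proportion = count / sum(count))
  class(out) <- c("DistanceProfile", "data.frame")
  attr(out, "n_sites") <- length(distances)
  attr(out, "breaks") <- key
  out
}

#' @export
plot.DistanceProfile <- function(x, ...) {
  graphics::barplot(x$proportion,
                    names.arg = sprintf("%g..%g", x$bin_low, x$bin_high),
                    las = 2, ylab = "proportion of sites", ...)
  invisible(x)
}

#' Chi-squared comparison of two distance profiles
#'
#' Two-sample chi-squared test on the 2 x k table of bin counts. Bins with a
#' zero joint count are dropped; if fewer than 80% of the remaining bins have
#' expected counts >= 5, tail bins are merged pairwise inwards until the rule
#' is met (or only two bins remain). No continuity correction is applied.
#'
#' @param profileA,profileB [distance_histogram()] profiles on an identical
#'   bin scheme.
#' @return list with `statistic`, `df`, `p.value` and the tested `table`.
#' @export
compare_distance_profiles <- function(profileA, profileB) {
  .assert(identical(attr(profileA, "breaks"), attr(profileB, "breaks")),
          "profiles use different bin schemes")
  cA <- profileA$count
  cB <- profileB$count
  keep <- (cA + cB) > 0
  cA <- cA[keep]; cB <- cB[keep]
  expected <- function(a, b) {
    tot <- sum(a) + sum(b)
    outer(c(sum(a), sum(b)), (a + b)) / tot
  }
  repeat {
    E <- expected(cA, cB)
    if (length(cA) <= 2 || mean(apply(E, 2, min) >= 5) >= 0.8) break
    # merge the sparser tail bin into its neighbour
    if (sum(E[, 1]) <= sum(E[, ncol(E)])) {
      cA <- c(cA[1] + cA[2], cA[-(1:2)])
      cB <- c(cB[1] + cB[2], cB[-(1:2)])
    } else {
      k <- length(cA)
      cA <- c(cA[1:(k - 2)], cA[k - 1] + cA[k])
      cB <- c(cB[1:(k - 2)], cB[k - 1] + cB[k])
    }
  }
  if (length(cA) < 2 || sum(cA) == 0 || sum(cB) == 0)
    return(list(statistic = 0, df = 0, p.value = 1,
                table = rbind(A = cA, B = cB)))
  ht <- suppressWarnings(stats::chisq.test(rbind(cA, cB), correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = if (is.nan(ht$p.value)) 1 else ht$p.value,
       table = rbind(A = cA, B = cB))
}

#' TSS-distance profile of accessible motif occurrences
#'
#' Restricts motif occurrences to those overlapping accessible regions by at
#' least one base (the "available motif" baseline against which isoform
#' profiles are compared), then computes their nearest-TSS distance profile.
#'
#' @param motifs a [peak_set()] of motif occurrences.
#' @param accessible a [peak_set()] of accessible (open chromatin) regions.
#' @param ann a [gene_annotation()].
#' @param breaks optional bin scheme, as in [distance_histogram()].
#' @return a `DistanceProfile`; accessible motif distances in the
#'   `distances` attribute.
#' @export
accessible_motif_distribution <- function(motifs, accessible, ann,
                                          breaks = NULL) {
  kept <- intersect_peaks(motifs, accessible, 1)
  .assert(nrow(kept) > 0, "no motif occurrences overlap accessible regions")
  nt <- nearest_tss(kept, ann)
  prof <- distance_histogram(nt$distance, breaks = breaks)
  attr(prof, "distances") <- nt$distance
  prof
}

#' Distance profiles stratified by cross-cell conservation
#'
#' One TSS-distance profile per conservation stratum (sites shared by k,
#' k-1, ..., 1 cell lines). Empty strata are skipped with a warning.
#'
#' @param cons a [conservation_count()] result.
#' @param ann a [gene_annotation()].
#' @param breaks optional bin scheme, as in [distance_histogram()].
#' @return named list of `DistanceProfile`s (`cells_<k>`), each carrying its
#'   distances in the `distances` attribute.
#' @export
stratify_by_conservation <- function(cons, ann, breaks = NULL) {
  clusters <- cons$clusters
  out <- list()
  for (k in sort(unique(clusters$n_cells), decreasing = TRUE)) {
    sub <- clusters[clusters$n_cells == k, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning(sprintf("no sites shared by %d cells; stratum skipped", k))
      next
    }
    nt <- nearest_tss(sub, ann)
    prof <- distance_histogram(nt$distance, breaks = breaks)
    attr(prof, "distances") <- nt$distance
    out[[sprintf("cells_%d", k)]] <- prof
  }
  out
}
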