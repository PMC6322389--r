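#' Compare per-site signal between two conditions
#'
#' Pairs replicate-averaged CPM per site and assay between conditions A and B
#' over a common site superset, computing the Pearson correlation on log10
#' signals and the per-site loading ratio `q = (B + pc) / (A + pc)` (fold
#' change of B over A; the reported mean fold change is the geometric mean).
#' Total-alpha and beta ratios (`q_alpha`, `q_beta`) feed the tertile
#' corroboration test.
#'
#' @param matA,matB [site_signal_matrix()]s quantified on the same superset
#'   (paired by `site_id`).
#' @param pseudocount CPM pseudocount (default 0.1; pass 0 for exact ratios
#'   on strictly positive data).
#' @return a `ConditionComparison` list: `table` (per-site ratios) and
#'   `stats` (per-assay correlation and mean fold change).
#' @export
compare_conditions <- function(matA, matB, pseudocount = 0.1) {
  m <- merge(as.data.frame(matA), as.data.frame(matB), by = "site_id",
             suffixes = c(".A", ".B"), sort = TRUE)
  .assert(nrow(m) > 0, "no shared sites between conditions (empty superset)")
  assays <- c("alpha1", "alpha2", "beta")
  getm <- function(which, a) {
    sub <- m[grep(sprintf("^%s(_|\\.)", a), names(m), value = TRUE)]
    sub <- sub[grep(sprintf("\\.%s$", which), names(sub), value = TRUE)]
    .assert(ncol(sub) > 0, "no columns for assay '%s'", a)
    if (ncol(sub) == 1) sub[[1]] else rowMeans(sub)
  }
  tab <- data.frame(site_id = m$site_id, stringsAsFactors = FALSE)
  st <- data.frame(assay = assays, r = NA_real_, mean_fold_change = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_along(assays)) {
    a <- getm("A", assays[i]); b <- getm("B", assays[i])
    q <- (b + pseudocount) / (a + pseudocount)
    tab[[paste0("q_", assays[i])]] <- q
    la <- log10(a + pseudocount); lb <- log10(b + pseudocount)
    ok <- is.finite(la) & is.finite(lb)
    st$r[i] <- if (sum(ok) >= 3 && stats::sd(la[ok]) > 0 &&
                     stats::sd(lb[ok]) > 0) stats::cor(la[ok], lb[ok])
    else NA_real_
    st$mean_fold_change[i] <- .geomean(q)
  }
  ta_A <- getm("A", "alpha1") + getm("A", "alpha2")
  ta_B <- getm("B", "alpha1") + getm("B", "alpha2")
  tab$q_alpha <- (ta_B + pseudocount) / (ta_A + pseudocount)
  structure(list(table = tab, stats = st, pseudocount = pseudocount),
            class = "ConditionComparison")
}

#' @export
print.ConditionComparison <- function(x, ...) {
  cat(sprintf("Condition comparison over %d sites\n", nrow(x$table)))
  print.data.frame(x$stats, row.names = FALSE)
  invisible(x)
}

#' Tertile corroboration of progressive loading
#'
#' Sites are ranked by their total-alpha loading ratio between conditions and
#' split into tertiles (sizes differing by at most one; ties broken by
#' site_id order, extra members assigned to the lower then middle tertile).
#' A genuine progressive/early-loading difference should be mirrored by the
#' partner beta subunit, so the beta loading ratio is compared between the
#' upper and lower alpha-tertile by a two-sided Wilcoxon rank-sum test. The
#' corroboration flag requires `P < alpha_level` and a positive direction
#' (upper-tertile beta ratios higher).
#'
#' @param cmp a [compare_conditions()] result with at least 9 sites.
#' @param alpha_level significance level for the flag (default 0.05).
#' @return list with `p.value`, `direction` (+1/0/-1 sign of the median
#'   difference), `corroborated`, and the `tertile` assignment (1 = lower,
#'   3 = upper by alpha ratio).
#' @export
tertile_corroboration <- function(cmp, alpha_level = 0.05) {
  tab <- cmp$table
  n <- nrow(tab)
  .assert(n >= 9, "need at least 9 sites for tertiles")
  o <- order(tab$q_alpha, tab$site_id)
  k <- n %/% 3L; extra <- n %% 3L
  sizes <- c(k + (extra >= 1), k + (extra >= 2), k)
  tert <- integer(n)
  tert[o] <- rep(1:3, times = sizes)
  qb_up <- tab$q_beta[tert == 3]
  qb_lo <- tab$q_beta[tert == 1]
  if (length(unique(tab$q_beta)) == 1L) {
    return(list(p.value = 1, direction = 0L, corroborated = FALSE,
                tertile = tert))
  }
  ht <- wilcox_ranksum(qb_up, qb_lo, alternative = "two.sided")
  dir <- sign(stats::median(qb_up) - stats::median(qb_lo))
  list(p.value = ht$p.value, direction = dir,
       corroborated = ht$p.value < alpha_level && dir > 0, tertile = tert)
}

#' Stability of the isoform ratio across conditions or cell types
#'
#' Per-site `s = log2((alpha1 + pc) / (alpha2 + pc))` on replicate-averaged
#' CPM in each of two conditions (or cell lines), and their Pearson
#' correlation; a high correlation means the isoform specificity of
#' individual sites is conserved.
#'
#' @param matA,matB [site_signal_matrix()]s with alpha1/alpha2 columns,
#'   paired by `site_id` (shared sites only).
#' @param pseudocount CPM pseudocount (default 0.1).
#' @return list with the per-site table (`s_A`, `s_B`) and Pearson `r`.
#' @export
isoform_ratio_stability <- function(matA, matB, pseudocount = 0.1) {
  sA <- data.frame(site_id = matA$site_id,
                   s_A = log2((.assay_mean(matA, "alpha1") + pseudocount) /
                                (.assay_mean(matA, "alpha2") + pseudocount)))
  sB <- data.frame(site_id = matB$site_id,
                   s_B = log2((.assay_mean(matB, "alpha1") + pseudocount) /
                                (.assay_mean(matB, "alpha2") + pseudocount)))
  m <- merge(sA, sB, by = "site_id", sort = TRUE)
  .assert(nrow(m) >= 3, "need at least 3 shared sites")
  list(table = m, r = stats::cor(m$s_A, m$s_B))
}

#' Classify sites by isoform specificity
#'
#' `s = log2((alpha1 + pc) / (alpha2 + pc))`; a site is isoform1-specific if
#' `s >= threshold_log2`, isoform2-specific if `s <= -threshold_log2`, and
#' shared otherwise. With `threshold_log2 = 0` the shared class is empty
#' (degenerate but allowed).
#'
#' @param mat a [site_signal_matrix()].
#' @param threshold_log2 symmetric class threshold (default 1, i.e. 2-fold).
#' @param pseudocount CPM pseudocount (default 0.1).
#' @return an `IsoformSpecificity` data frame: `site_id`, `s`, `class`.
#' @export
classify_specificity <- function(mat, threshold_log2 = 1, pseudocount = 0.1) {
  s <- log2((.assay_mean(mat, "alpha1") + pseudocount) /
              (.assay_mean(mat, "alpha2") + pseudocount))
  cls <- ifelse(s >= threshold_log2, "isoform1_specific",
                ifelse(s <= -threshold_log2, "isoform2_specific", "shared"))
  out <- data.frame(site_id = mat$site_id, s = s,
                    class = factor(cls, levels = c("isoform1_specific",
                                                   "shared",
                                                   "isoform2_specific")),
                    stringsAsFactors = FALSE)
  class(out) <- c("IsoformSpecificity", "data.frame")
  out
}

#' Knockout contrast for the surviving isoform
#'
#' For each isoform-specificity class, paired per-site signals of the
#' surviving isoform in wild-type and knockout cells are compared on the
#' log2 CPM scale by a Wilcoxon signed-rank test: the two-sided P, the median
#' paired difference (KO - WT, in log2 units) and a one-sided "increase" P
#' (KO greater than WT) are reported. Classes with fewer than `min_n` sites
#' are skipped with a warning.
#'
#' @param wt_mat,ko_mat [site_signal_matrix()]s paired by `site_id`.
#' @param assay the surviving isoform's assay label (`"alpha1"` or
#'   `"alpha2"`).
#' @param classes a [classify_specificity()] result (from wild-type signal).
#' @param pseudocount CPM pseudocount (default 0.1).
#' @param min_n minimum class size (default 5).
#' @return data frame with one row per tested class: `class`, `n`,
#'   `median_shift`, `p_two_sided`, `p_increase`.
#' @export
knockout_contrast <- function(wt_mat, ko_mat, assay, classes,
                              pseudocount = 0.1, min_n = 5) {
  wt <- data.frame(site_id = wt_mat$site_id, wt = .assay_mean(wt_mat, assay))
  ko <- data.frame(site_id = ko_mat$site_id, ko = .assay_mean(ko_mat, assay))
  m <- merge(merge(wt, ko, by = "site_id"), as.data.frame(classes),
             by = "site_id", sort = TRUE)
  out <- NULL
  for (cl in levels(m$class)) {
    sub <- m[m$class == cl, , drop = FALSE]
    if (nrow(sub) < min_n) {
      if (nrow(sub) > 0 || cl %in% m$class)
        warning(sprintf("class '%s' has %d sites (< %d); skipped",
                        cl, nrow(sub), min_n))
      next
    }
    lx <- log2(sub$wt + pseudocount)
    ly <- log2(sub$ko + pseudocount)
    out <- rbind(out, data.frame(
      class = cl, n = nrow(sub),
      median_shift = stats::median(ly - lx),
      p_two_sided = wilcox_signedrank(ly, lx, "two.sided")$p.value,
      p_increase = wilcox_signedrank(ly, lx, "greater")$p.value,
      stringsAsFactors = FALSE))
  }
  out
}

#' Cross-cell conservation of binding sites
#'
#' Canonical site sets from several cell lines are clustered by
#' single-linkage overlap (>= `min_overlap` bases); each cluster is annotated
#' with the number of supporting cell lines and the proportions of clusters
#' shared by 1, 2, ..., k cells are reported.
#'
#' @param sets named list (>= 2) of site sets (`PeakSet`s), one per cell
#'   line, same isoform.
#' @param min_overlap minimum overlapping bases (default 1).
#' @return list with `clusters` (a `PeakSet` with `n_cells` and `in_<cell>`
#'   columns) and `proportions` (named vector over cell counts `1..k`).
#' @export
conservation_count <- function(sets, min_overlap = 1) {
  .assert(length(sets) >= 2, "need at least two cell-line site sets")
  isoforms <- unique(unlist(lapply(sets, function(s) attr(s, "isoform"))))
  .assert(length(isoforms) <= 1, "mixed isoform labels across cells")
  labels <- names(sets)
  if (is.null(labels)) labels <- sprintf("cell%d", seq_along(sets))
  pooled <- do.call(rbind, lapply(seq_along(sets), function(i) {
    df <- as.data.frame(sets[[i]])[c("chrom", "start", "end", "name",
                                     "score", "strand", "summit")]
    cbind(df, .set = labels[i])
  }))
  o <- order(pooled$chrom, pooled$start, pooled$end)
  pooled <- pooled[o, , drop = FALSE]
  ids <- .cluster_ids(pooled, min_overlap)
  out <- .merge_clusters(pooled, ids)
  cl <- sort(unique(ids))
  for (lb in labels) out[[paste0("in_", lb)]] <- cl %in% ids[pooled$.set == lb]
  ncell <- vapply(split(pooled$.set, ids), function(s) length(unique(s)), 0L)
  out$n_cells <- as.integer(ncell[as.character(cl)])
  k <- length(sets)
  prop <- vapply(seq_len(k), function(j) mean(out$n_cells == j), 0)
  names(prop) <- as.character(seq_len(k))
  list(clusters = out, proportions = prop,
       shared_2plus = sum(prop[-1]))
}
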