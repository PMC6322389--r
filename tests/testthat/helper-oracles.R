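# Independent brute-force oracles used to check the package's fast paths.

# All-pairs interval overlap scan: rows of `a` overlapping any row of `b`
# by >= min_overlap bases (0-based half-open).
oracle_intersect <- function(a, b, min_overlap = 1) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap) { keep[i] <- TRUE; break }
    }
  }
  keep
}

# Union-find single-linkage clustering by pairwise overlap >= min_overlap.
oracle_cluster <- function(df, min_overlap = 1) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || df$chrom[i] != df$chrom[j]) next
    ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j])
    if (ov >= min_overlap) parent[find(i)] <- find(j)
  }
  vapply(seq_len(n), find, 0L)
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, n) draws.
oracle_hyper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)  # elements 1..K are the successes
  mean(succ >= k)
}

# Exact Wilcoxon rank-sum P by enumerating all group assignments (no ties).
oracle_ranksum <- function(x, y, alternative = "two.sided") {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ranks <- seq_len(nx + ny)
  u_all <- colSums(matrix(ranks[combs], nrow = nx)) - nx * (nx + 1) / 2
  pl <- mean(u_all <= u_obs); pg <- mean(u_all >= u_obs)
  switch(alternative,
         two.sided = min(1, 2 * min(pl, pg)),
         greater = pg, less = pl)
}

# Exact Wilcoxon signed-rank P by enumerating all 2^n sign assignments.
oracle_signedrank <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  pl <- mean(v_all <= v_obs); pg <- mean(v_all >= v_obs)
  switch(alternative,
         two.sided = min(1, 2 * min(pl, pg)),
         greater = pg, less = pl)
}

# Explicit running-sum GSEA enrichment score (loop form).
oracle_gsea_es <- function(scores, hit, p) {
  N <- length(scores); nh <- sum(hit)
  denom <- sum(abs(scores[hit])^p)
  rs <- 0; best <- 0
  for (i in seq_len(N)) {
    rs <- rs + if (hit[i]) abs(scores[i])^p / denom else -1 / (N - nh)
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# Naive per-base window sum over a run-length track data frame.
oracle_window_sum <- function(runs, chrom, start, end) {
  total <- 0
  for (i in seq_len(nrow(runs))) {
    if (runs$chrom[i] != chrom) next
    ov <- min(runs$end[i], end) - max(runs$start[i], start)
    if (ov > 0) total <- total + ov * runs$value[i]
  }
  total
}

# Nearest-rank percentile by explicit sort-and-index.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  s[max(1, ceiling(p / 100 * length(s)))]
}

# Exhaustive nearest-TSS scan.
oracle_nearest <- function(chrom, pos, ann) {
  best <- NA_integer_
  for (j in seq_len(nrow(ann))) {
    if (ann$chrom[j] != chrom) next
    if (is.na(best) || abs(ann$tss[j] - pos) < abs(ann$tss[best] - pos) ||
        (abs(ann$tss[j] - pos) == abs(ann$tss[best] - pos) &&
         ann$gene_id[j] < ann$gene_id[best]))
      best <- j
  }
  best
}

# Textbook two-sample chi-squared statistic, independent two-pass form.
oracle_chisq <- function(a, b) {
  tot <- sum(a) + sum(b)
  stat <- 0
  for (i in seq_along(a)) {
    for (row in list(c(a[i], sum(a)), c(b[i], sum(b)))) {
      E <- row[2] * (a[i] + b[i]) / tot
      stat <- stat + (row[1] - E)^2 / E
    }
  }
  stat
}

# Random PeakSet for property tests.
random_peaks <- function(n, chroms = c("chr1", "chr2"), span = 10000,
                         max_width = 300) {
  start <- sample.int(span, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  peak_set(sample(chroms, n, replace = TRUE), start, start + width,
           name = sprintf("p%03d", seq_len(n)))
}
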