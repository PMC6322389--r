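#' Construct a PeakSet of genomic intervals
#'
#' A `PeakSet` is a sorted data frame of genomic intervals in BED convention
#' (0-based, half-open), the unit of all site arithmetic in the package.
#' Each interval may carry a summit (offset from `start`, in bases), a name
#' and a numeric score. Intervals are sorted by (chrom, start, end) and exact
#' duplicates of (chrom, start, end) are dropped (first occurrence kept).
#'
#' @param chrom character vector of chromosome names (exact string matching is
#'   used throughout; no alias table).
#' @param start,end integer vectors, 0-based half-open: `0 <= start < end`.
#' @param name optional interval names; defaults to `peak_<i>`.
#' @param score numeric score (default 0).
#' @param strand one of `"+"`, `"-"`, `"."` (default `"."`; strand is ignored
#'   for peak arithmetic and only honoured for TSS distance signs).
#' @param summit integer offset of the summit from `start`, in
#'   `[0, end - start)`, or `NA` when unknown.
#' @param provenance optional list recording where the set came from
#'   (assay, condition, replicate, ...).
#' @return an object of class `PeakSet` (a data frame).
#' @examples
#' peak_set("chr1", c(100, 500), c(300, 900), summit = c(80, NA))
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = 0, strand = ".",
                     summit = NA_integer_, provenance = NULL) {
  n <- length(start)
  .assert(length(end) == n, "start and end lengths differ")
  chrom <- rep_len(as.character(chrom), n)
  start <- as.numeric(start)
  end <- as.numeric(end)
  score <- rep_len(as.numeric(score), n)
  strand <- rep_len(as.character(strand), n)
  summit <- rep_len(as.numeric(summit), n)
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  name <- rep_len(as.character(name), n)
  if (n > 0) {
    .assert(all(!is.na(start) & !is.na(end)), "NA coordinates in PeakSet")
    .assert(all(start >= 0), "negative start coordinate")
    .assert(all(start < end), "interval with start >= end")
    .assert(all(strand %in% c("+", "-", ".")), "invalid strand")
    ok <- is.na(summit) | (summit >= 0 & summit < end - start)
    .assert(all(ok), "summit offset outside [0, end - start)")
  }
  df <- data.frame(chrom = chrom, start = start, end = end, name = name,
                   score = score, strand = strand, summit = summit,
                   stringsAsFactors = FALSE)
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  dup <- duplicated(df[, c("chrom", "start", "end")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("PeakSet", "data.frame")
  attr(df, "provenance") <- provenance
  df
}

.as_peak_set <- function(df, provenance = NULL) {
  peak_set(df$chrom, df$start, df$end, name = df$name,
           score = if (is.null(df$score)) 0 else df$score,
           strand = if (is.null(df$strand)) "." else df$strand,
           summit = if (is.null(df$summit)) NA else df$summit,
           provenance = provenance)
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet with %d interval(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  prov <- attr(x, "provenance")
  if (!is.null(prov) && length(prov))
    cat("provenance:", paste(names(prov), unlist(prov), sep = "=",
                             collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Absolute summit positions of a PeakSet
#'
#' Returns `start + summit`; when the summit is absent the deterministic
#' fallback `floor((end - start) / 2)` (interval midpoint) is used.
#'
#' @param ps a [peak_set()].
#' @return numeric vector of genomic positions.
#' @export
summit_pos <- function(ps) {
  off <- ps$summit
  fall <- floor((ps$end - ps$start) / 2)
  off[is.na(off)] <- fall[is.na(off)]
  ps$start + off
}

.ps_iranges <- function(ps) {
  IRanges::IRanges(start = as.integer(ps$start) + 1L, end = as.integer(ps$end))
}

# Logical vector: does a[i] overlap any interval of b by >= min_overlap bases?
.overlaps_any <- function(a, b, min_overlap = 1) {
  out <- logical(nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(out)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    hits <- IRanges::findOverlaps(.ps_iranges(a[ia, , drop = FALSE]),
                                  .ps_iranges(b[ib, , drop = FALSE]),
                                  minoverlap = as.integer(min_overlap))
    out[ia[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  out
}

#' Intersect two PeakSets by minimum overlap
#'
#' Returns the intervals of `a` that overlap at least one interval of `b` by
#' `min_overlap` or more bases, with `a`'s coordinates retained. Intervals are
#' half-open, so `[100,200)` and `[200,300)` do not overlap.
#'
#' @param a,b [peak_set()] objects.
#' @param min_overlap minimum overlapping bases (default 1).
#' @return the qualifying subset of `a`, still a `PeakSet`.
#' @export
intersect_peaks <- function(a, b, min_overlap = 1) {
  .assert(.is_count(min_overlap) && min_overlap >= 1,
          "min_overlap must be a positive integer")
  keep <- .overlaps_any(a, b, min_overlap)
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Single-linkage clustering of intervals by pairwise overlap >= min_overlap.
# Returns an integer cluster id per row (input must be coordinate-sorted,
# which peak_set() guarantees). Sweep: a new interval joins the open cluster
# when it overlaps the furthest end seen so far by >= min_overlap bases.
.cluster_ids <- function(ps, min_overlap = 1) {
  n <- nrow(ps)
  ids <- integer(n)
  if (n == 0) return(ids)
  cl <- 0L
  cur_chrom <- ""
  cur_end <- -Inf
  for (i in seq_len(n)) {
    ov <- min(cur_end, ps$end[i]) - ps$start[i]
    if (!identical(ps$chrom[i], cur_chrom) || ov < min_overlap) {
      cl <- cl + 1L
      cur_end <- ps$end[i]
    } else {
      cur_end <- max(cur_end, ps$end[i])
    }
    cur_chrom <- ps$chrom[i]
    ids[i] <- cl
  }
  ids
}

#' Read intervals from a BED / narrowPeak file
#'
#' Accepts BED3, BED6 and the MACS narrowPeak dialect (10 columns, 10th column
#' = summit offset from start; -1 means absent). Lines starting with `track`,
#' `browser` or `#` are skipped. Malformed lines raise an error naming the
#' line number.
#'
#' @param path file path.
#' @return a [peak_set()].
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(peak_set(character(0), numeric(0), numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  .assert(length(bad) == 0, "malformed BED line %d: fewer than 3 fields",
          if (length(bad)) lineno[bad[1]] else 0L)
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(get(i)))
    bad <- which(is.na(v) & !is.na(get(i)))
    .assert(length(bad) == 0, "malformed BED line %d: non-numeric %s",
            if (length(bad)) lineno[bad[1]] else 0L, what)
    v
  }
  start <- num(2, "start")
  end <- num(3, "end")
  bad <- which(is.na(start) | is.na(end) | start >= end)
  .assert(length(bad) == 0, "invalid interval at line %d: start >= end",
          if (length(bad)) lineno[bad[1]] else 0L)
  name <- if (any(nf >= 4)) get(4) else NULL
  score <- if (any(nf >= 5)) suppressWarnings(as.numeric(get(5))) else 0
  score[is.na(score)] <- 0
  strand <- if (any(nf >= 6)) get(6) else "."
  strand[is.na(strand) | !strand %in% c("+", "-", ".")] <- "."
  summit <- NA_real_
  if (all(nf >= 10)) {
    summit <- num(10, "summit offset")
    summit[summit < 0] <- NA_real_
  }
  peak_set(get(1), start, end, name = name, score = score, strand = strand,
           summit = summit)
}

#' Write a PeakSet to BED6 or narrowPeak
#'
#' When no interval has a summit the set is written as BED6; otherwise the
#' 10-column narrowPeak dialect is used (summit offset in column 10, -1 when
#' absent). Output is sorted (PeakSets are always sorted).
#'
#' @param ps a [peak_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ps, path) {
  if (nrow(ps) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  base <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", ps$chrom, as.integer(ps$start),
                  as.integer(ps$end), ps$name, as.character(ps$score),
                  ps$strand)
  if (all(is.na(ps$summit))) {
    writeLines(base, path)
  } else {
    summit <- ifelse(is.na(ps$summit), -1L, as.integer(ps$summit))
    writeLines(sprintf("%s\t%s\t-1\t-1\t%d", base, as.character(ps$score),
                       summit), path)
  }
  invisible(path)
}
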