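#' Construct a run-length coverage track
#'
#' A `SignalTrack` stores per-base read coverage as non-overlapping runs
#' (0-based, half-open) per chromosome, with the total number of mapped reads
#' attached; totals are the denominator of all CPM/RPKM normalisation.
#'
#' @param runs data frame with columns `chrom`, `start`, `end`, `value`
#'   (mean per-base read count over the run); runs must not overlap.
#' @param total_reads total mapped reads of the assay the track came from.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return an object of class `SignalTrack`.
#' @export
signal_track <- function(runs, total_reads, chrom_lengths = NULL) {
  .assert(is.data.frame(runs) &&
            all(c("chrom", "start", "end", "value") %in% names(runs)),
          "runs must have chrom/start/end/value columns")
  .assert(is.numeric(total_reads) && length(total_reads) == 1 &&
            total_reads >= 0, "total_reads must be a single non-negative number")
  runs <- runs[runs$value != 0, , drop = FALSE]
  if (nrow(runs) > 0) {
    .assert(all(runs$value >= 0), "negative coverage value")
    .assert(all(runs$start < runs$end), "run with start >= end")
    o <- order(runs$chrom, runs$start)
    runs <- runs[o, , drop = FALSE]
  }
  by_chrom <- list()
  for (ch in unique(runs$chrom)) {
    r <- runs[runs$chrom == ch, , drop = FALSE]
    .assert(all(r$start[-1] >= r$end[-nrow(r)]) || nrow(r) < 2,
            "overlapping runs on %s", ch)
    by_chrom[[ch]] <- list(
      start = r$start, end = r$end, value = r$value,
      # cumulative area strictly before each run
      cum = c(0, cumsum((r$end - r$start) * r$value))[seq_len(nrow(r))])
  }
  structure(list(chroms = by_chrom, total_reads = total_reads,
                 chrom_lengths = chrom_lengths),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  nr <- sum(vapply(x$chroms, function(c) length(c$start), 0L))
  cat(sprintf("SignalTrack: %d run(s) on %d chromosome(s), %g mapped reads\n",
              nr, length(x$chroms), x$total_reads))
  invisible(x)
}

# Cumulative coverage area A(x) = integral of the step function over [0, x),
# evaluated at (possibly fractional) positions x. Positions outside all runs
# contribute nothing, so windows truncated by chromosome ends are zero-padded.
.area_at <- function(tr, x) {
  a <- numeric(length(x))
  if (length(tr$start) == 0) return(a)
  i <- findInterval(x, tr$start)
  pos <- i > 0
  ii <- i[pos]
  a[pos] <- tr$cum[ii] +
    tr$value[ii] * pmax(0, pmin(x[pos], tr$end[ii]) - tr$start[ii])
  a
}

#' Sum of per-base counts over genomic windows
#'
#' @param track a [signal_track()].
#' @param chrom,start,end parallel vectors of 0-based half-open windows.
#' @return numeric vector of per-base count sums.
#' @export
track_sum <- function(track, chrom, start, end) {
  n <- length(start)
  chrom <- rep_len(as.character(chrom), n)
  out <- numeric(n)
  for (ch in unique(chrom)) {
    tr <- track$chroms[[ch]]
    idx <- which(chrom == ch)
    if (is.null(tr)) next
    out[idx] <- .area_at(tr, end[idx]) - .area_at(tr, start[idx])
  }
  out
}

#' Read a bedGraph coverage file with its mapped-read total
#'
#' The totals file is a two-column TSV mapping a track label to its total
#' mapped reads. The label defaults to the bedGraph file name without its
#' extension; a missing total is an explicit error (no silent default).
#'
#' @param path bedGraph file (`chrom start end value`, 0-based half-open).
#' @param totals_path two-column TSV (`track<TAB>total_reads`, no header).
#' @param track label to look up in the totals file.
#' @return a [signal_track()].
#' @export
read_bedgraph <- function(path, totals_path, track = NULL) {
  .assert(file.exists(totals_path),
          "totals file '%s' not found; total mapped reads are required",
          totals_path)
  totals <- utils::read.table(totals_path, sep = "\t", header = FALSE,
                              col.names = c("track", "total_reads"),
                              stringsAsFactors = FALSE)
  if (is.null(track)) track <- sub("\\.(bedgraph|bg|bedGraph)$", "", basename(path))
  hit <- match(track, totals$track)
  .assert(!is.na(hit), "no total mapped reads recorded for track '%s'", track)
  runs <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "value"),
                            stringsAsFactors = FALSE)
  .assert(all(runs$value >= 0), "negative value in bedGraph '%s'", path)
  signal_track(runs, total_reads = totals$total_reads[hit])
}

#' Write a SignalTrack as bedGraph
#'
#' Zero-valued runs are omitted; output is sorted.
#'
#' @param track a [signal_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in sort(names(track$chroms))) {
    tr <- track$chroms[[ch]]
    if (length(tr$start) == 0) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(tr$start),
                       as.integer(tr$end), as.character(tr$value)), con)
  }
  invisible(path)
}

#' Construct a gene annotation of transcription start sites
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome of each TSS.
#' @param tss 0-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `GeneAnnotation` (a data frame).
#' @export
gene_annotation <- function(gene_id, chrom, tss, strand) {
  n <- length(gene_id)
  .assert(!anyDuplicated(gene_id), "duplicate gene_id in annotation")
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = rep_len(as.character(chrom), n),
                   tss = as.numeric(tss),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  if (n > 0) .assert(all(df$strand %in% c("+", "-")), "strand must be + or -")
  df <- df[order(df$chrom, df$tss, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Read gene TSSs from a GTF file
#'
#' Only `gene` features are used. GTF coordinates are 1-based inclusive and
#' are converted to the package's 0-based convention on read: the TSS is
#' `start - 1` on the plus strand and `end - 1` on the minus strand.
#'
#' @param path GTF file path.
#' @return a [gene_annotation()].
#' @export
read_gtf_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 9 && x[3] == "gene", TRUE)
  f <- f[keep]
  if (length(f) == 0)
    return(gene_annotation(character(0), character(0), numeric(0), character(0)))
  attrs <- vapply(f, `[`, "", 9)
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", attrs)
  chrom <- vapply(f, `[`, "", 1)
  start1 <- as.numeric(vapply(f, `[`, "", 4))
  end1 <- as.numeric(vapply(f, `[`, "", 5))
  strand <- vapply(f, `[`, "", 7)
  tss <- ifelse(strand == "-", end1 - 1, start1 - 1)
  gene_annotation(gid, chrom, tss, strand)
}

#' Write a gene annotation as GTF (gene features) or TSS BED6
#'
#' `write_gtf_genes` emits one 1-bp `gene` feature per TSS with a `gene_id`
#' attribute; `write_tss_bed` / `read_tss_bed` use BED6 with
#' `start = TSS, end = TSS + 1, name = gene_id`.
#'
#' @param ann a [gene_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf_genes <- function(ann, path) {
  writeLines(sprintf('%s\thifbindr\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                     ann$chrom, as.integer(ann$tss) + 1L,
                     as.integer(ann$tss) + 1L, ann$strand, ann$gene_id), path)
  invisible(path)
}

#' @rdname write_gtf_genes
#' @export
write_tss_bed <- function(ann, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", ann$chrom, as.integer(ann$tss),
                     as.integer(ann$tss) + 1L, ann$gene_id, ann$strand), path)
  invisible(path)
}

#' @rdname write_gtf_genes
#' @export
read_tss_bed <- function(path) {
  ps <- read_bed(path)
  strand <- ifelse(ps$strand == "-", "-", "+")
  gene_annotation(ps$name, ps$chrom, ps$start, strand)
}
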