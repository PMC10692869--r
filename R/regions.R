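#' Read a BED file into a normalized region set
#'
#' Regions are stored as a [GenomicRanges::GRanges] in 1-based closed
#' coordinates (the BED file itself is 0-based half-open). Overlapping or
#' adjacent intervals on the same contig are merged on load so membership
#' tests are unambiguous.
#'
#' @param path BED file (plain or gzip; first three columns used).
#' @return a `GRanges` with merged intervals.
#' @export
readBedRegions <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    bad <- which(lengths(parts) < 3L)[1L]
    stop("malformed BED line ", bad, " in ", path, ": fewer than 3 columns")
  }
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start0 <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  end0 <- as.numeric(vapply(parts, `[[`, character(1), 3L))
  if (any(is.na(start0)) || any(is.na(end0)) || any(start0 >= end0)) {
    stop("malformed BED intervals in ", path, " (need start < end)")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  GenomicRanges::reduce(gr)
}

#' Write regions to BED
#'
#' @param regions a `GRanges` (1-based closed, as used throughout the package).
#' @param path output path.
#' @export
writeBedRegions <- function(regions, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions)
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Restrict variant records to target regions
#'
#' Keeps a record when its 1-based position falls inside one of the intervals
#' (BED half-open convention: a BED interval `(start, end)` covers 1-based
#' positions `start+1 .. end`). Records on contigs absent from the region set
#' are dropped, not an error. Input order is preserved.
#'
#' @param records data.frame of SNV records as returned by [readSNVs()].
#' @param regions `GRanges` region set from [readBedRegions()].
#' @return the retained rows of `records`.
#' @export
restrictToRegions <- function(records, regions) {
  if (nrow(records) == 0L) return(records)
  pts <- GenomicRanges::GRanges(records$chrom,
                                IRanges::IRanges(records$pos, records$pos))
  keep <- IRanges::overlapsAny(pts, regions)
  dropped <- sum(!keep)
  if (dropped > 0L) .msg(dropped, " record(s) outside target regions dropped")
  records[keep, , drop = FALSE]
}
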