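## Default values used when a genomic track cannot inform a feature.
## 0.42 / 0.02 are the genome-wide GC and CpG-island priors; 0.5 encodes
## "condition holds with probability one half" for the boolean features.
GC_DEFAULT <- 0.42
CPG_DEFAULT <- 0.02
BOOL_MISSING <- 0.5

#' GC fraction in a window around a position
#'
#' Fraction of G/C bases (case-insensitive) among the reference bases in
#' `[pos - halfwidth, pos + halfwidth]`. The denominator is the number of
#' non-N bases actually available (the window is truncated at contig edges);
#' when no informative base is available, or the contig is absent from the
#' reference, the genome-wide default 0.42 is returned.
#'
#' @param tracks a [GenomeTracks-class] object.
#' @param chrom,pos contig and 1-based position (vectorized over `pos`).
#' @param halfwidth window half-width in bp (default 75, i.e. a 151 bp
#'   window).
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
computeGC <- function(tracks, chrom, pos, halfwidth = 75L) {
  stopifnot(halfwidth >= 0)
  n <- length(pos)
  out <- rep(GC_DEFAULT, n)
  for (ctg in unique(chrom)) {
    idx <- which(chrom == ctg)
    if (!ctg %in% names(tracks@reference)) {
      .msg("contig ", ctg, " absent from reference; GC defaulted")
      next
    }
    seq <- tracks@reference[[ctg]]
    len <- length(seq)
    from <- pmax(1L, pos[idx] - halfwidth)
    to <- pmin(len, pos[idx] + halfwidth)
    ok <- from <= to & pos[idx] >= 1L & pos[idx] <= len
    if (any(ok)) {
      v <- Biostrings::Views(seq, start = from[ok], end = to[ok])
      af <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
      gc <- af[, "G"] + af[, "C"]
      informative <- rowSums(af)
      frac <- ifelse(informative > 0, gc / informative, GC_DEFAULT)
      out[idx[ok]] <- frac
    }
  }
  out
}

#' CpG-island coverage fraction in a window around a position
#'
#' Fraction of the window's positions (truncated at contig edges when the
#' contig length is known) covered by CpG-island intervals. When no CpG track
#' is loaded the genome-wide default 0.02 is returned.
#'
#' @inheritParams computeGC
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
computeCpG <- function(tracks, chrom, pos, halfwidth = 75L) {
  stopifnot(halfwidth >= 0)
  n <- length(pos)
  if (is.null(tracks@cpgIslands)) {
    return(rep(CPG_DEFAULT, n))
  }
  out <- numeric(n)
  islands <- tracks@cpgIslands
  for (ctg in unique(chrom)) {
    idx <- which(chrom == ctg)
    len <- if (ctg %in% names(tracks@reference)) {
      length(tracks@reference[[ctg]])
    } else NA_integer_
    from <- pmax(1L, pos[idx] - halfwidth)
    to <- pos[idx] + halfwidth
    if (!is.na(len)) to <- pmin(len, to)
    isl <- IRanges::ranges(islands[GenomicRanges::seqnames(islands) == ctg])
    win <- IRanges::IRanges(from, to)
    hits <- IRanges::findOverlaps(win, isl)
    covered <- integer(length(win))
    if (length(hits)) {
      ov <- IRanges::pintersect(win[S4Vectors::queryHits(hits)],
                                isl[S4Vectors::subjectHits(hits)])
      covered <- as.integer(tapply(IRanges::width(ov),
                                   factor(S4Vectors::queryHits(hits),
                                          levels = seq_along(win)),
                                   sum, default = 0L))
      covered[is.na(covered)] <- 0L
    }
    out[idx] <- covered / IRanges::width(win)
  }
  out
}

#' Transition/transversion indicator
#'
#' Returns 1 for a transversion (purine/pyrimidine exchange), 0 for a
#' transition (A/G or C/T), and 0.5 when either allele is missing — the
#' "condition holds with 50% probability" encoding used for all missing
#' boolean genomic features.
#'
#' @param ref,alt single-base alleles in `{A, C, G, T}` or `NA` for missing
#'   information (vectorized).
#' @return numeric vector with values in `{0, 0.5, 1}`.
#' @export
computeIsTV <- function(ref, alt) {
  purine <- c("A", "G")
  known <- !is.na(ref) & !is.na(alt)
  if (any(known & ref == alt)) {
    stop("ref == alt: not a variant")
  }
  out <- rep(BOOL_MISSING, length(ref))
  tv <- (ref %in% purine) != (alt %in% purine)
  out[known] <- as.numeric(tv[known])
  out
}

#' Ancestral base at a position
#'
#' Looks up the ancestral-base store and returns the uppercased base when it
#' is one of A/C/G/T, and `"O"` (Other) for absent positions, gaps, Ns or any
#' other symbol — the total fallback for missing or complex ancestral
#' information.
#'
#' @inheritParams computeGC
#' @return character vector with values in `{A, C, G, T, O}`.
#' @export
lookupAncestral <- function(tracks, chrom, pos) {
  n <- length(pos)
  out <- rep("O", n)
  if (is.null(tracks@ancestral)) return(out)
  for (ctg in unique(chrom)) {
    idx <- which(chrom == ctg)
    if (!ctg %in% names(tracks@ancestral)) next
    seq <- tracks@ancestral[[ctg]]
    len <- length(seq)
    ok <- pos[idx] >= 1L & pos[idx] <= len
    if (any(ok)) {
      base <- toupper(as.character(Biostrings::extractAt(
        seq, IRanges::IRanges(pos[idx][ok], pos[idx][ok]))))
      base[!base %in% c("A", "C", "G", "T")] <- "O"
      out[idx[ok]] <- base
    }
  }
  out
}

#' Derived-allele indicator
#'
#' Compares the observed (alternative) allele with the ancestral base:
#' 1 when the allele differs from the ancestral base (evolutionarily
#' derived), 0 when it equals it, and 0.5 when the ancestral base is
#' unknown (`"O"`).
#'
#' @param alt alternative allele in `{A, C, G, T}`.
#' @param anc ancestral base in `{A, C, G, T, O}`.
#' @return numeric vector with values in `{0, 0.5, 1}`.
#' @export
computeIsDerived <- function(alt, anc) {
  ifelse(anc == "O", BOOL_MISSING, as.numeric(alt != anc))
}

#' Annotate SNV records with genomic features
#'
#' Computes, per record: the ancestral base (`anc`), GC and CpG window
#' fractions (`gc`, `cpg`), the transition/transversion indicator (`is_tv`,
#' set to 0.5 inside variation-type track gaps), the derived-allele indicator
#' (`is_derived`, 0.5 when the ancestral base is unknown), and the
#' reference/alternative amino-acid codes (`o_aa`, `n_aa`; `U` for variants
#' without consequence annotation).
#'
#' @param records SNV records from [readSNVs()].
#' @param tracks a [GenomeTracks-class] object.
#' @param halfwidth window half-width for GC/CpG (default 75 bp).
#' @return data.frame with columns `anc, gc, cpg, is_tv, is_derived, o_aa,
#'   n_aa`, row-aligned with `records`.
#' @export
annotateVariants <- function(records, tracks, halfwidth = 75L) {
  n <- nrow(records)
  anc <- lookupAncestral(tracks, records$chrom, records$pos)
  gc <- computeGC(tracks, records$chrom, records$pos, halfwidth)
  cpg <- computeCpG(tracks, records$chrom, records$pos, halfwidth)
  isTv <- computeIsTV(records$ref, records$alt)
  if (!is.null(tracks@tvGaps) && n > 0L) {
    pts <- GenomicRanges::GRanges(records$chrom,
                                  IRanges::IRanges(records$pos, records$pos))
    gap <- IRanges::overlapsAny(pts, tracks@tvGaps)
    isTv[gap] <- BOOL_MISSING
  }
  isDerived <- computeIsDerived(records$alt, anc)
  oAA <- rep("U", n)
  nAA <- rep("U", n)
  if (!is.null(tracks@aaEffect) && n > 0L) {
    key <- variantKey(records$chrom, records$pos, records$ref, records$alt)
    aaKey <- variantKey(tracks@aaEffect$chrom, tracks@aaEffect$pos,
                        tracks@aaEffect$ref, tracks@aaEffect$alt)
    hit <- match(key, aaKey)
    found <- !is.na(hit)
    oAA[found] <- tracks@aaEffect$o_aa[hit[found]]
    nAA[found] <- tracks@aaEffect$n_aa[hit[found]]
  }
  data.frame(anc = anc, gc = gc, cpg = cpg, is_tv = isTv,
             is_derived = isDerived, o_aa = oAA, n_aa = nAA,
             stringsAsFactors = FALSE)
}
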