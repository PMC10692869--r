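## Default mapping from record fields to GATK VCF INFO keys. GQ and GT are
## always taken from the sample FORMAT columns (GATK convention).
#' Default INFO key mapping for GATK HaplotypeCaller VCFs
#' @return named character vector mapping record fields to INFO keys.
#' @export
gatkKeyMap <- function() {
  c(dp = "DP", qd = "QD", fs = "FS", sor = "SOR", mq = "MQ",
    mq_rank_sum = "MQRankSum", base_q_rank_sum = "BaseQRankSum",
    read_pos_rank_sum = "ReadPosRankSum")
}

#' @keywords internal
.isSNVAllele <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
}

## Cheap structural validation so malformed files fail with a line number
## before VariantAnnotation's parser produces an opaque error.
#' @keywords internal
.validateVcfLines <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L || !startsWith(lines[1L], "##fileformat=VCF")) {
    stop("not a VCF 4.x file (missing ##fileformat header): ", path)
  }
  isData <- !startsWith(lines, "#")
  nf <- integer(0)
  if (any(isData)) {
    nf <- vapply(strsplit(lines[isData], "\t", fixed = TRUE), length, 1L)
    bad <- which(nf < 8L)
    if (length(bad)) {
      stop("malformed VCF record at line ", which(isData)[bad[1L]],
           " of ", path, ": fewer than 8 tab-separated fields")
    }
  }
  invisible(lines)
}

#' Read biallelic SNV records and GATK metrics from a VCF
#'
#' Parses a VCF 4.x file, splits multiallelic sites into one record per ALT
#' allele, and keeps only single-nucleotide substitutions. Indels, MNPs,
#' symbolic and spanning-deletion alleles are skipped and counted (attribute
#' `nSkipped`). Quality metrics are read from INFO fields; GQ and the diploid
#' genotype from the sample FORMAT columns. INFO or FORMAT keys absent from a
#' record yield `NA` — the explicit "absent" marker, never silently zero.
#'
#' @param vcfPath path to a VCF (plain or gzip).
#' @param sampleName sample to read FORMAT fields from; required for
#'   multi-sample files.
#' @param keyMap named character vector mapping record fields to INFO keys,
#'   see [gatkKeyMap()] for the GATK defaults.
#' @return data.frame with columns `chrom, pos, ref, alt, dp, qd, fs, sor,
#'   mq, gq, mq_rank_sum, base_q_rank_sum, read_pos_rank_sum, genotype`
#'   (plus `fpscore` and `kit` when the corresponding INFO keys are present),
#'   and attribute `nSkipped`.
#' @export
readSNVs <- function(vcfPath, sampleName = NULL, keyMap = gatkKeyMap()) {
  .validateVcfLines(vcfPath)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(vcfPath, genome = "unknown")),
    error = function(e) stop("failed to parse VCF ", vcfPath, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  keep <- .isSNVAllele(ref, alt)
  nSkipped <- sum(!keep)

  inf <- VariantAnnotation::info(vcf)
  getInfo <- function(key) {
    if (!is.null(key) && key %in% colnames(inf)) {
      v <- inf[[key]]
      if (is.list(v)) v <- vapply(v, function(x) {
        if (length(x)) as.numeric(x[[1L]]) else NA_real_
      }, numeric(1))
      as.numeric(v)
    } else rep(NA_real_, length(ref))
  }

  nsamp <- length(VariantAnnotation::samples(VariantAnnotation::header(vcf)))
  sampleIdx <- 1L
  if (nsamp > 1L) {
    if (is.null(sampleName)) {
      stop("multi-sample VCF: sampleName is required")
    }
    sn <- VariantAnnotation::samples(VariantAnnotation::header(vcf))
    sampleIdx <- match(sampleName, sn)
    if (is.na(sampleIdx)) stop("sample '", sampleName, "' not found in ", vcfPath)
  } else if (!is.null(sampleName) && nsamp == 1L) {
    sn <- VariantAnnotation::samples(VariantAnnotation::header(vcf))
    if (!identical(sampleName, sn)) {
      stop("sample '", sampleName, "' not found in ", vcfPath)
    }
  }
  gen <- VariantAnnotation::geno(vcf)
  gq <- if ("GQ" %in% names(gen)) as.numeric(gen$GQ[, sampleIdx]) else
    rep(NA_real_, length(ref))
  gt <- if ("GT" %in% names(gen)) as.character(gen$GT[, sampleIdx]) else
    rep(NA_character_, length(ref))

  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref,
    alt = alt,
    dp = getInfo(keyMap[["dp"]]),
    qd = getInfo(keyMap[["qd"]]),
    fs = getInfo(keyMap[["fs"]]),
    sor = getInfo(keyMap[["sor"]]),
    mq = getInfo(keyMap[["mq"]]),
    gq = gq,
    mq_rank_sum = getInfo(keyMap[["mq_rank_sum"]]),
    base_q_rank_sum = getInfo(keyMap[["base_q_rank_sum"]]),
    read_pos_rank_sum = getInfo(keyMap[["read_pos_rank_sum"]]),
    genotype = gt,
    stringsAsFactors = FALSE
  )
  if ("FPSCORE" %in% colnames(inf)) out$fpscore <- getInfo("FPSCORE")
  if ("KIT" %in% colnames(inf)) {
    kit <- inf[["KIT"]]
    out$kit <- as.character(kit)
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nSkipped") <- nSkipped
  out
}

#' Write a scored, filtered copy of a VCF
#'
#' Streams the input VCF and, for each SNV allele with a score, appends an
#' `FPSCORE` INFO entry (per-allele, 4 decimals) and sets the FILTER column:
#' `FP_ML` when any allele score is strictly below `threshold`, `PASS`
#' otherwise. Records without scored alleles (indels, MNPs) pass through
#' unchanged; every other field is byte-preserved. `records`/`scores` must be
#' in the order produced by [readSNVs()] on the same file.
#'
#' @param vcfPath the VCF the records were read from.
#' @param records SNV records from [readSNVs()] (possibly after region
#'   restriction; unmatched lines are left unscored).
#' @param scores numeric vector in `[0, 1]`, one per record; higher means
#'   more likely a true variant.
#' @param threshold decision threshold in `[0, 1]`; a score strictly below it
#'   marks the call `FP_ML`, a score equal to it passes.
#' @param outPath output VCF path.
#' @return `outPath`, invisibly.
#' @export
writeScoredVcf <- function(vcfPath, records, scores, threshold, outPath) {
  if (length(scores) != nrow(records)) {
    stop("score count (", length(scores), ") does not match record count (",
         nrow(records), ")")
  }
  if (any(is.na(scores)) || any(scores < 0) || any(scores > 1)) {
    stop("scores must be in [0, 1] with no missing values")
  }
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]")
  }
  lines <- .validateVcfLines(vcfPath)
  isData <- !startsWith(lines, "#")
  chromIdx <- which(startsWith(lines, "#CHROM"))
  if (length(chromIdx) != 1L) stop("missing #CHROM header line in ", vcfPath)

  newHeader <- c(
    sprintf('##INFO=<ID=FPSCORE,Number=A,Type=Float,Description="FPsieve probability that the allele is a true variant; values near 0 indicate a likely false positive">'),
    sprintf('##FILTER=<ID=FP_ML,Description="FPsieve false-positive call (FPSCORE below %s)">',
            format(threshold))
  )
  out <- c(lines[seq_len(chromIdx - 1L)], newHeader, lines[chromIdx])

  key <- variantKey(records$chrom, records$pos, records$ref, records$alt)
  cursor <- 1L
  dataLines <- lines[isData]
  body <- character(length(dataLines))
  for (i in seq_along(dataLines)) {
    ln <- dataLines[i]
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    alts <- strsplit(f[5L], ",", fixed = TRUE)[[1L]]
    snv <- .isSNVAllele(rep(f[4L], length(alts)), alts)
    lineScores <- rep(NA_real_, length(alts))
    for (j in which(snv)) {
      k <- paste(f[1L], f[2L], f[4L], alts[j], sep = ":")
      if (cursor <= length(key) && identical(key[cursor], k)) {
        lineScores[j] <- scores[cursor]
        cursor <- cursor + 1L
      }
    }
    if (any(!is.na(lineScores))) {
      tag <- paste0("FPSCORE=", paste(
        ifelse(is.na(lineScores), ".", sprintf("%.4f", lineScores)),
        collapse = ","))
      f[8L] <- if (f[8L] %in% c(".", "")) tag else paste0(f[8L], ";", tag)
      f[7L] <- if (any(lineScores < threshold, na.rm = TRUE)) "FP_ML" else "PASS"
      ln <- paste(f, collapse = "\t")
    }
    body[i] <- ln
  }
  if (cursor != length(key) + 1L) {
    stop("failed to place ", length(key) - cursor + 1L,
         " score(s): records do not match ", vcfPath,
         " (were they read from this file, in order?)")
  }
  writeLines(c(out, body), outPath)
  invisible(outPath)
}
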