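#' Synthetic call-set configuration
#'
#' Defines the statistical conditions a generated call set emulates: class
#' imbalance (default 27% false positives, the training-data ratio the
#' filter is designed around), class-conditional GATK metric distributions
#' (truncated normals; FP calls centered at lower QD/MQ/DP/GQ and higher
#' FS/SOR, the direction hard filtering exploits), the homozygote rate
#' (homozygous calls lack all three rank-sum metrics), class-conditional
#' missingness of the ancestral base and of the variation-type track
#' (both strongly enriched in FPs: the defaults are calibrated so that
#' roughly 91% of isTV-missing and 79% of ancestral-missing calls are FPs
#' at the default class ratio), transition/transversion composition per
#' class, duplicate calls from multiple capture kits, and the coding
#' fraction carrying amino-acid consequences.
#'
#' @param nVariants number of distinct variants to generate.
#' @param fpFraction probability a variant is a false positive.
#' @param contigName,contigLength the single synthetic contig.
#' @param gcBias expected G+C fraction of the reference.
#' @param cpgIslandFraction,cpgMeanLength CpG-island track density.
#' @param tp,fp per-class metric distributions: named list of `c(mean, sd)`
#'   for `qd, mq, fs, sor, dp, gq, rank`.
#' @param tiTvProb per-class probability that a variant is a transition.
#' @param ancMissing per-class probability that the ancestral base is
#'   unknown (drives both `anc = "O"` and `is_derived = 0.5`).
#' @param ancAltFraction among known ancestral bases, fraction set to the
#'   alternative allele (so the reference allele is the derived one).
#' @param tvMissing per-class probability that the variation-type track has
#'   a gap at the variant.
#' @param homRate probability a call is homozygous (rank sums absent).
#' @param duplicateRate fraction of variants re-called by additional kits.
#' @param nSources number of capture kits.
#' @param codingFraction fraction of variants with amino-acid consequences.
#' @param testShift optional named numeric of additive column shifts used by
#'   the covariate-shifted scenario (applied to a test partition via
#'   [applyTestShift()]).
#' @return a config list (class `fpsieveSynthConfig`).
#' @export
synthConfig <- function(nVariants = 5000L,
                        fpFraction = 0.27,
                        contigName = "chr1",
                        contigLength = 250000L,
                        gcBias = 0.45,
                        cpgIslandFraction = 0.02,
                        cpgMeanLength = 700L,
                        tp = list(qd = c(17, 4), mq = c(59, 1.5),
                                  fs = c(2, 2), sor = c(1, 0.5),
                                  dp = c(60, 20), gq = c(80, 20),
                                  rank = c(0, 1)),
                        fp = list(qd = c(11, 5), mq = c(54, 6),
                                  fs = c(5, 4.5), sor = c(1.7, 0.9),
                                  dp = c(40, 20), gq = c(65, 25),
                                  rank = c(-0.8, 1.2)),
                        tiTvProb = c(tp = 0.70, fp = 0.45),
                        ancMissing = c(tp = 0.0144, fp = 0.1463),
                        ancAltFraction = 0.15,
                        tvMissing = c(tp = 0.00358, fp = 0.0977),
                        homRate = 0.30,
                        duplicateRate = 0.10,
                        nSources = 3L,
                        codingFraction = 0.30,
                        testShift = NULL) {
  cfg <- list(nVariants = as.integer(nVariants), fpFraction = fpFraction,
              contigName = contigName, contigLength = as.integer(contigLength),
              gcBias = gcBias, cpgIslandFraction = cpgIslandFraction,
              cpgMeanLength = as.integer(cpgMeanLength),
              tp = tp, fp = fp, tiTvProb = tiTvProb,
              ancMissing = ancMissing, ancAltFraction = ancAltFraction,
              tvMissing = tvMissing, homRate = homRate,
              duplicateRate = duplicateRate, nSources = as.integer(nSources),
              codingFraction = codingFraction, testShift = testShift)
  probs <- c(fpFraction, cpgIslandFraction, tiTvProb, ancMissing, tvMissing,
             homRate, duplicateRate, codingFraction, ancAltFraction, gcBias)
  stopifnot(all(probs >= 0 & probs <= 1), nVariants >= 1L)
  usable <- cfg$contigLength - 152L
  if (usable < cfg$nVariants) {
    stop("contigLength ", cfg$contigLength, " too small for ",
         cfg$nVariants, " variants (need >= nVariants + 152)")
  }
  if (fpFraction == 0) {
    warning("fpFraction = 0: no false positives will be generated; ",
            "FP-conditional distribution parameters are unused")
  }
  class(cfg) <- "fpsieveSynthConfig"
  cfg
}

#' Named scenario presets
#'
#' Ships the study conditions as ready-made configs:
#' * `"imbalanced-27"` — the default conditions: 27% FPs, moderately
#'   separated metric distributions, duplicates from 3 kits.
#' * `"separable"` — large class shifts on every metric; an end-to-end run
#'   should satisfy the selection constraints (TPR > 0.99, TNR > 0.40).
#' * `"hard"` — strongly overlapping class distributions, where the
#'   cost-sensitive / traditional trade-off is visible.
#' * `"shifted-test"` — the default conditions plus an additive covariate
#'   shift for the test partition, which the covariate-shift check must
#'   flag.
#'
#' @return named list of configs from [synthConfig()].
#' @export
scenarioPresets <- function() {
  list(
    "imbalanced-27" = synthConfig(),
    "separable" = synthConfig(
      tp = list(qd = c(30, 2), mq = c(60, 0.5), fs = c(1, 0.5),
                sor = c(0.8, 0.2), dp = c(80, 10), gq = c(95, 5),
                rank = c(0, 0.5)),
      fp = list(qd = c(3, 1.5), mq = c(35, 5), fs = c(15, 5),
                sor = c(3.5, 0.8), dp = c(15, 8), gq = c(30, 15),
                rank = c(-3, 1)),
      tiTvProb = c(tp = 0.75, fp = 0.40)),
    "hard" = synthConfig(
      fp = list(qd = c(13, 5), mq = c(56, 4), fs = c(4, 3.5),
                sor = c(1.5, 0.8), dp = c(45, 20), gq = c(70, 22),
                rank = c(-0.5, 1.2)),
      tiTvProb = c(tp = 0.65, fp = 0.55)),
    "shifted-test" = synthConfig(
      testShift = c(qd = 8, mq = -8, dp = 25))
  )
}

#' Apply a scenario's covariate shift to a partition
#'
#' Adds the config's `testShift` offsets to the named numeric columns of a
#' dataset partition, emulating a test set drawn from a shifted metric
#' distribution (e.g. a different capture kit or sequencing batch).
#'
#' @param dataset assembled dataset rows.
#' @param config a [synthConfig()] with a non-`NULL` `testShift`.
#' @return the shifted dataset.
#' @export
applyTestShift <- function(dataset, config) {
  if (is.null(config$testShift)) return(dataset)
  for (cn in names(config$testShift)) {
    dataset[[cn]] <- dataset[[cn]] + config$testShift[[cn]]
  }
  dataset
}

#' Generate a random reference sequence
#'
#' @param length sequence length in bp (at least 151, one annotation
#'   window).
#' @param gcBias expected G+C fraction.
#' @param seed integer seed (same seed, same sequence).
#' @param contigName contig name.
#' @param path optional FASTA output path.
#' @return a named `DNAStringSet`; written to `path` when given.
#' @export
generateReference <- function(length, gcBias = 0.45, seed = 1L,
                              contigName = "chr1", path = NULL) {
  if (length < 151L) stop("reference length must be at least 151 bp")
  chars <- .withSeed(seed, sample(c("A", "T", "G", "C"), length,
                                  replace = TRUE,
                                  prob = c((1 - gcBias) / 2, (1 - gcBias) / 2,
                                           gcBias / 2, gcBias / 2)))
  seq <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(seq) <- contigName
  if (!is.null(path)) Biostrings::writeXStringSet(seq, path)
  seq
}

## Transition partner and transversion alternatives for each base.
TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

## Draw a (codon, position) context for ref consistent with a non-stop
## oAA -> nAA substitution; returns c(oAA, nAA).
#' @keywords internal
.drawAAPair <- function(ref, alt) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  repeat {
    k <- sample.int(3L, 1L)
    codon <- sample(bases, 3L, replace = TRUE)
    codon[k] <- ref
    mutated <- codon
    mutated[k] <- alt
    o <- gc[[paste(codon, collapse = "")]]
    n <- gc[[paste(mutated, collapse = "")]]
    if (o != "*" && n != "*") return(c(o, n))
  }
}

#' Generate a synthetic called SNV set with tracks and truth data
#'
#' Produces, as a pure function of `(config, seed)`, everything the rest of
#' the package consumes: a reference and ancestral sequence, CpG-island and
#' variation-type-gap tracks, an amino-acid consequence table, a truth VCF
#' (exactly the true variants), a confident-region BED covering the contig,
#' and a called VCF carrying GATK-style INFO/FORMAT fields in which
#' homozygous calls lack all three rank-sum metrics and a configurable
#' fraction of variants is re-called by additional kits with jittered
#' metrics (INFO key `KIT`). When `dir` is `NULL` no files are written and
#' only the in-memory objects are returned.
#'
#' @param config a [synthConfig()].
#' @param seed integer seed.
#' @param dir output directory for the fixture files, or `NULL`.
#' @return list with `records` (a data.frame in [readSNVs()] layout plus
#'   `label`), `tracks` (a [GenomeTracks-class]), `truthKeys`,
#'   `confidentRegions`, `config`, `seed`, and — when `dir` is given —
#'   `paths` (named file paths) incl. a `manifest.json`.
#' @export
generateCallset <- function(config = synthConfig(), seed = 1L, dir = NULL) {
  stopifnot(inherits(config, "fpsieveSynthConfig"))
  out <- .withSeed(seed, .generateCallsetImpl(config))
  out$seed <- as.integer(seed)
  if (!is.null(dir)) {
    out$paths <- .writeFixtures(out, dir)
  }
  out
}

#' @keywords internal
.generateCallsetImpl <- function(config) {
  n <- config$nVariants
  L <- config$contigLength
  ctg <- config$contigName
  refSeq <- generateReference(L, config$gcBias, seed = sample.int(1e6, 1L),
                              contigName = ctg)
  refChars <- strsplit(as.character(refSeq[[1L]]), "")[[1L]]

  ## CpG islands
  nIsl <- max(1L, round(L * config$cpgIslandFraction / config$cpgMeanLength))
  islLen <- pmax(50L, round(rnorm(nIsl, config$cpgMeanLength,
                                  config$cpgMeanLength / 4)))
  islStart <- sample.int(L - max(islLen), nIsl, replace = TRUE)
  cpg <- GenomicRanges::reduce(GenomicRanges::GRanges(
    ctg, IRanges::IRanges(islStart, width = islLen)))

  ## variant positions, labels, alleles
  pos <- sort(sample(76:(L - 76), n))
  label <- rbinom(n, 1L, 1 - config$fpFraction)
  ref <- refChars[pos]
  pTi <- ifelse(label == 1, config$tiTvProb[["tp"]], config$tiTvProb[["fp"]])
  isTi <- rbinom(n, 1L, pTi) == 1L
  alt <- character(n)
  alt[isTi] <- TRANSITION_OF[ref[isTi]]
  tvPick <- rbinom(n, 1L, 0.5) + 1L
  alt[!isTi] <- mapply(function(r, k) TRANSVERSIONS_OF[[r]][k],
                       ref[!isTi], tvPick[!isTi])

  ## class-conditional GATK metrics
  drawMetric <- function(name, a = -Inf, b = Inf) {
    m <- numeric(n)
    for (cls in c("tp", "fp")) {
      sel <- if (cls == "tp") label == 1 else label == 0
      par <- config[[cls]][[name]]
      m[sel] <- .rtnorm(sum(sel), par[1L], par[2L], a, b)
    }
    m
  }
  qd <- round(drawMetric("qd", a = 0), 3)
  mq <- round(drawMetric("mq", a = 0, b = 70), 3)
  fs <- round(drawMetric("fs", a = 0), 3)
  sor <- round(drawMetric("sor", a = 0), 3)
  dp <- pmax(1, round(drawMetric("dp", a = 1)))
  gq <- pmin(99, pmax(0, round(drawMetric("gq", a = 0, b = 99))))
  hom <- rbinom(n, 1L, config$homRate) == 1L
  drawRank <- function() round(drawMetric("rank"), 3)
  mqrs <- drawRank(); bqrs <- drawRank(); rprs <- drawRank()
  mqrs[hom] <- NA_real_; bqrs[hom] <- NA_real_; rprs[hom] <- NA_real_

  ## ancestral sequence: starts as the reference; unknown at anc-missing
  ## variants, the ALT base for a fraction of the rest
  pAncMiss <- ifelse(label == 1, config$ancMissing[["tp"]],
                     config$ancMissing[["fp"]])
  ancMiss <- rbinom(n, 1L, pAncMiss) == 1L
  ancIsAlt <- !ancMiss & rbinom(n, 1L, config$ancAltFraction) == 1L
  ancChars <- refChars
  ancChars[pos[ancMiss]] <- "N"
  ancChars[pos[ancIsAlt]] <- alt[ancIsAlt]
  ancSeq <- Biostrings::DNAStringSet(paste(ancChars, collapse = ""))
  names(ancSeq) <- ctg

  ## variation-type track gaps
  pTvMiss <- ifelse(label == 1, config$tvMissing[["tp"]],
                    config$tvMissing[["fp"]])
  tvMiss <- rbinom(n, 1L, pTvMiss) == 1L
  tvGaps <- if (any(tvMiss)) {
    GenomicRanges::reduce(GenomicRanges::GRanges(
      ctg, IRanges::IRanges(pos[tvMiss], pos[tvMiss])))
  } else GenomicRanges::GRanges()

  ## amino-acid consequences for the coding fraction
  coding <- rbinom(n, 1L, config$codingFraction) == 1L
  aaEffect <- NULL
  if (any(coding)) {
    pairs <- t(mapply(.drawAAPair, ref[coding], alt[coding]))
    aaEffect <- data.frame(chrom = ctg, pos = pos[coding],
                           ref = ref[coding], alt = alt[coding],
                           o_aa = pairs[, 1L], n_aa = pairs[, 2L],
                           stringsAsFactors = FALSE)
  }

  base <- data.frame(
    chrom = ctg, pos = pos, ref = ref, alt = alt,
    dp = dp, qd = qd, fs = fs, sor = sor, mq = mq, gq = gq,
    mq_rank_sum = mqrs, base_q_rank_sum = bqrs, read_pos_rank_sum = rprs,
    genotype = ifelse(hom, "1/1", "0/1"),
    kit = "kit1", label = label, stringsAsFactors = FALSE
  )

  ## duplicate calls from additional kits, metrics jittered
  dup <- which(runif(n) < config$duplicateRate & config$nSources > 1L)
  extras <- list()
  for (i in dup) {
    nExtra <- sample.int(config$nSources - 1L, 1L)
    for (e in seq_len(nExtra)) {
      r <- base[i, , drop = FALSE]
      jit <- function(x, s) round(x + rnorm(1L, 0, s), 3)
      r$qd <- max(0, jit(r$qd, 0.5)); r$mq <- max(0, jit(r$mq, 0.5))
      r$fs <- max(0, jit(r$fs, 0.4)); r$sor <- max(0, jit(r$sor, 0.1))
      r$dp <- max(1, round(r$dp + rnorm(1L, 0, 3)))
      r$gq <- min(99, max(0, round(r$gq + rnorm(1L, 0, 3))))
      if (r$genotype != "1/1") {
        r$mq_rank_sum <- jit(r$mq_rank_sum, 0.1)
        r$base_q_rank_sum <- jit(r$base_q_rank_sum, 0.1)
        r$read_pos_rank_sum <- jit(r$read_pos_rank_sum, 0.1)
      }
      r$kit <- paste0("kit", e + 1L)
      extras[[length(extras) + 1L]] <- r
    }
  }
  records <- rbind(base, do.call(rbind, extras))
  records <- records[order(records$pos, records$kit), , drop = FALSE]
  rownames(records) <- NULL

  tracks <- GenomeTracks(reference = refSeq, ancestral = ancSeq,
                         cpgIslands = cpg, tvGaps = tvGaps,
                         aaEffect = aaEffect)
  truthKeys <- unique(variantKey(base$chrom, base$pos, base$ref,
                                 base$alt)[base$label == 1])
  confident <- GenomicRanges::GRanges(ctg, IRanges::IRanges(1L, L))
  list(records = records, tracks = tracks, truthKeys = truthKeys,
       confidentRegions = confident, config = config)
}

## Serialize a generated call set to standard FASTA/BED/VCF/TSV fixtures.
#' @keywords internal
.writeFixtures <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    reference = file.path(dir, "reference.fa"),
    ancestral = file.path(dir, "ancestral.fa"),
    cpg = file.path(dir, "cpg_islands.bed"),
    tvGaps = file.path(dir, "tv_gaps.bed"),
    confident = file.path(dir, "confident.bed"),
    truth = file.path(dir, "truth.vcf"),
    calls = file.path(dir, "calls.vcf"),
    aaEffect = file.path(dir, "aa_effect.tsv"),
    labels = file.path(dir, "labels.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  tr <- fx$tracks
  Biostrings::writeXStringSet(tr@reference, p$reference)
  Biostrings::writeXStringSet(tr@ancestral, p$ancestral)
  writeBedRegions(tr@cpgIslands, p$cpg)
  writeBedRegions(tr@tvGaps, p$tvGaps)
  writeBedRegions(fx$confidentRegions, p$confident)
  if (!is.null(tr@aaEffect)) {
    write.table(tr@aaEffect, p$aaEffect, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write.table(fx$records[c("chrom", "pos", "ref", "alt", "kit", "label")],
              p$labels, sep = "\t", quote = FALSE, row.names = FALSE)

  ctg <- fx$config$contigName
  len <- fx$config$contigLength
  .writeCallsVcf(fx$records, ctg, len, p$calls)
  truthRec <- fx$records[!duplicated(variantKey(fx$records$chrom,
                                                fx$records$pos,
                                                fx$records$ref,
                                                fx$records$alt)) &
                           fx$records$label == 1, , drop = FALSE]
  .writeTruthVcf(truthRec, ctg, len, p$truth)
  jsonlite::write_json(
    list(seed = fx$seed, nVariants = fx$config$nVariants,
         fpFraction = fx$config$fpFraction,
         files = lapply(p, identity)),
    p$manifest, auto_unbox = TRUE, pretty = TRUE)
  p
}

#' @keywords internal
.vcfHeader <- function(contig, length, withInfo = TRUE) {
  h <- c("##fileformat=VCFv4.2",
         sprintf("##contig=<ID=%s,length=%d>", contig, length))
  if (withInfo) {
    h <- c(h,
      '##INFO=<ID=DP,Number=1,Type=Integer,Description="Approximate read depth">',
      '##INFO=<ID=QD,Number=1,Type=Float,Description="Variant call confidence normalized by depth">',
      '##INFO=<ID=FS,Number=1,Type=Float,Description="Phred-scaled strand bias p-value">',
      '##INFO=<ID=SOR,Number=1,Type=Float,Description="Symmetric odds ratio strand bias">',
      '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
      '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Rank sum test for mapping qualities">',
      '##INFO=<ID=BaseQRankSum,Number=1,Type=Float,Description="Rank sum test of REF vs ALT base qualities">',
      '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Rank sum test for read position">',
      '##INFO=<ID=KIT,Number=1,Type=String,Description="Capture kit the call originated from">')
  }
  c(h,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
}

#' @keywords internal
.writeCallsVcf <- function(records, contig, length, path) {
  fmtNum <- function(x) sub("\\.?0+$", "", sprintf("%.3f", x))
  info <- sprintf("DP=%d;QD=%s;FS=%s;SOR=%s;MQ=%s", records$dp,
                  fmtNum(records$qd), fmtNum(records$fs),
                  fmtNum(records$sor), fmtNum(records$mq))
  hasRank <- !is.na(records$mq_rank_sum)
  info[hasRank] <- paste0(info[hasRank], sprintf(
    ";MQRankSum=%s;BaseQRankSum=%s;ReadPosRankSum=%s",
    fmtNum(records$mq_rank_sum[hasRank]),
    fmtNum(records$base_q_rank_sum[hasRank]),
    fmtNum(records$read_pos_rank_sum[hasRank])))
  info <- paste0(info, ";KIT=", records$kit)
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s\tGT:GQ\t%s:%d",
                   records$chrom, records$pos, records$ref, records$alt,
                   fmtNum(records$qd * records$dp), info,
                   records$genotype, records$gq)
  writeLines(c(.vcfHeader(contig, length), lines), path)
  invisible(path)
}

#' @keywords internal
.writeTruthVcf <- function(records, contig, length, path) {
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT:GQ\t%s:%d",
                   records$chrom, records$pos, records$ref, records$alt,
                   records$genotype, records$gq)
  writeLines(c(.vcfHeader(contig, length, withInfo = FALSE), lines), path)
  invisible(path)
}

#' Build the labeled modeling dataset from a generated call set
#'
#' Runs the standard pipeline — annotate against the tracks, label against
#' the truth keys inside the confident regions, assemble the feature
#' columns — on a [generateCallset()] result (in-memory objects; use
#' [datasetFromFiles()] to exercise the file-based route).
#'
#' @param fx a [generateCallset()] result.
#' @param matrices amino-acid matrices.
#' @return labeled assembled dataset.
#' @export
datasetFromCallset <- function(fx, matrices = defaultAminoAcidMatrices()) {
  records <- fx$records[setdiff(names(fx$records), "label")]
  ann <- annotateVariants(records, fx$tracks)
  ds <- assembleDataset(records, ann, matrices)
  labelAgainstTruth(ds, fx$truthKeys, fx$confidentRegions)
}

#' Build the labeled modeling dataset from fixture files
#'
#' The file-based twin of [datasetFromCallset()]: reads the called VCF,
#' tracks and truth VCF back from disk and runs the same pipeline.
#'
#' @param paths named paths as produced by [generateCallset()] with `dir`.
#' @param matrices amino-acid matrices.
#' @return labeled assembled dataset.
#' @export
datasetFromFiles <- function(paths, matrices = defaultAminoAcidMatrices()) {
  tracks <- GenomeTracks(reference = paths$reference,
                         ancestral = paths$ancestral,
                         cpgIslands = paths$cpg,
                         tvGaps = paths$tvGaps,
                         aaEffect = if (file.exists(paths$aaEffect))
                           paths$aaEffect else NULL)
  records <- readSNVs(paths$calls)
  confident <- readBedRegions(paths$confident)
  records <- restrictToRegions(records, confident)
  truth <- readSNVs(paths$truth)
  ann <- annotateVariants(records, tracks)
  ds <- assembleDataset(records, ann, matrices)
  labelAgainstTruth(ds, truth, confident)
}
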