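test_that("reference generation respects length, GC bias and the seed", {
  allGC <- generateReference(200L, gcBias = 1, seed = 1L)
  freq <- Biostrings::letterFrequency(allGC[[1L]], c("G", "C"))
  expect_equal(sum(freq), 200)
  big <- generateReference(100000L, gcBias = 0.5, seed = 2L)
  gc <- sum(Biostrings::letterFrequency(big[[1L]], c("G", "C"))) / 100000
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
  expect_identical(as.character(generateReference(500L, 0.4, seed = 9L)),
                   as.character(generateReference(500L, 0.4, seed = 9L)))
  expect_error(generateReference(100L), "151")
})

test_that("generation is a pure function of config and seed", {
  cfg <- synthConfig(nVariants = 300L, contigLength = 5000L)
  a <- generateCallset(cfg, seed = 5L)
  b <- generateCallset(cfg, seed = 5L)
  expect_identical(a$records, b$records)
  expect_identical(a$truthKeys, b$truthKeys)
  c <- generateCallset(cfg, seed = 6L)
  expect_false(identical(a$records, c$records))
})

test_that("class balance, duplicates and homozygote structure match config", {
  cfg <- synthConfig(nVariants = 20000L, contigLength = 150000L)
  fx <- generateCallset(cfg, seed = 8L)
  base <- fx$records[fx$records$kit == "kit1", ]
  expect_lt(abs(mean(base$label == 0) - 0.27), 0.01)
  # ~10% of variant keys have multiplicity >= 2
  mult <- table(variantKey(fx$records$chrom, fx$records$pos,
                           fx$records$ref, fx$records$alt))
  expect_lt(abs(mean(mult >= 2) - 0.10), 0.01)
  # homozygotes lack all three rank sums; heterozygotes have all three
  hom <- base$genotype == "1/1"
  expect_lt(abs(mean(hom) - 0.30), 0.02)
  expect_true(all(is.na(base$mq_rank_sum[hom])))
  expect_true(all(!is.na(base$mq_rank_sum[!hom])))
  # every call sits on the generated reference
  refChars <- strsplit(as.character(fx$tracks@reference[[1L]]), "")[[1L]]
  expect_true(all(refChars[base$pos] == base$ref))
})

test_that("missingness enrichment follows the configured Bayes posterior", {
  cfg <- synthConfig(nVariants = 50000L, contigLength = 300000L)
  fx <- generateCallset(cfg, seed = 12L)
  ds <- datasetFromCallset(fx)
  base <- ds[ds$kit == "kit1", ]
  # oracle: P(FP | missing) from the configured class-conditional rates
  postFor <- function(mFP, mTP) {
    (mFP * cfg$fpFraction) /
      (mFP * cfg$fpFraction + mTP * (1 - cfg$fpFraction))
  }
  tvMissing <- base$is_tv == 0.5
  expect_lt(abs(mean(base$label[tvMissing] == 0) -
                  postFor(cfg$tvMissing[["fp"]], cfg$tvMissing[["tp"]])),
            0.03)
  ancMissing <- base$anc == "O"
  expect_lt(abs(mean(base$label[ancMissing] == 0) -
                  postFor(cfg$ancMissing[["fp"]], cfg$ancMissing[["tp"]])),
            0.03)
  # and the derived-allele indicator is missing exactly when anc is unknown
  expect_true(all((base$is_derived == 0.5) == ancMissing))
})

test_that("an all-true call set closes the loop with labeling", {
  cfg <- suppressWarnings(synthConfig(nVariants = 200L, contigLength = 4000L,
                                      fpFraction = 0))
  fx <- suppressWarnings(generateCallset(cfg, seed = 3L))
  ds <- datasetFromCallset(fx)
  expect_true(all(ds$label == 1))
  expect_setequal(unique(ds$group), fx$truthKeys)
})

test_that("file fixtures reproduce the in-memory dataset exactly", {
  cfg <- synthConfig(nVariants = 400L, contigLength = 8000L)
  dir <- tempfile("fixtures_")
  fx <- generateCallset(cfg, seed = 19L, dir = dir)
  expect_true(all(file.exists(unlist(fx$paths[c("reference", "ancestral",
                                                "cpg", "confident", "truth",
                                                "calls", "labels")]))))
  fromMem <- datasetFromCallset(fx)
  fromDisk <- datasetFromFiles(fx$paths)
  expect_equal(nrow(fromDisk), nrow(fromMem))
  for (cn in names(fromMem)) {
    expect_equal(fromDisk[[cn]], fromMem[[cn]], info = cn)
  }
})

test_that("every generated fixture satisfies its consumers' preconditions", {
  cfg <- synthConfig(nVariants = 300L, contigLength = 6000L)
  dir <- tempfile("closure_")
  fx <- generateCallset(cfg, seed = 23L, dir = dir)
  # VCFs parse as VCF 4.x with the SNV invariant
  rec <- readSNVs(fx$paths$calls)
  expect_true(all(nchar(rec$ref) == 1L & nchar(rec$alt) == 1L))
  expect_equal(attr(rec, "nSkipped"), 0L)
  truth <- readSNVs(fx$paths$truth)
  expect_gt(nrow(truth), 0L)
  # BED tracks load and merge
  conf <- readBedRegions(fx$paths$confident)
  expect_equal(GenomicRanges::start(conf), 1L)
  # truth VCF lies inside the confident regions
  expect_equal(nrow(restrictToRegions(truth, conf)), nrow(truth))
  # the label table is consistent with truth membership
  labTab <- read.table(fx$paths$labels, header = TRUE, sep = "\t")
  key <- variantKey(labTab$chrom, labTab$pos, labTab$ref, labTab$alt)
  expect_equal(labTab$label == 1, key %in% fx$truthKeys)
  # and the full pipeline reproduces those labels
  ds <- datasetFromFiles(fx$paths)
  expect_equal(ds$label[match(key, ds$group)], labTab$label)
})

test_that("scenario presets encode their advertised conditions", {
  p <- scenarioPresets()
  expect_setequal(names(p), c("imbalanced-27", "separable", "hard",
                              "shifted-test"))
  expect_equal(p[["imbalanced-27"]]$fpFraction, 0.27)
  expect_false(is.null(p[["shifted-test"]]$testShift))
  # separable preset pushes the class means far apart on QD
  expect_gt(p[["separable"]]$tp$qd[1] - p[["separable"]]$fp$qd[1],
            p[["hard"]]$tp$qd[1] - p[["hard"]]$fp$qd[1])
  # shift application moves only the named columns
  ds <- smallDataset(n = 100L, seed = 3L)
  shifted <- applyTestShift(ds, p[["shifted-test"]])
  expect_equal(shifted$qd, ds$qd + p[["shifted-test"]]$testShift[["qd"]])
  expect_equal(shifted$fs, ds$fs)
})

test_that("config validation catches impossible settings", {
  expect_error(synthConfig(nVariants = 10000L, contigLength = 5000L),
               "too small")
  expect_warning(synthConfig(fpFraction = 0), "no false positives")
  expect_error(synthConfig(fpFraction = 1.2))
})
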