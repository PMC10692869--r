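test_that("GC window fraction matches direct counting and defaults", {
  # saturated window on an all-G contig
  ref <- Biostrings::DNAStringSet(strrep("G", 400L))
  names(ref) <- "chr1"
  tr <- GenomeTracks(reference = ref)
  expect_equal(computeGC(tr, "chr1", 200L), 1.0)

  # 76 G followed by 75 A around the boundary: 76/151
  chars <- c(rep("G", 76L), rep("A", 75L), rep("T", 200L))
  ref2 <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(ref2) <- "chr1"
  tr2 <- GenomeTracks(reference = ref2)
  expect_equal(computeGC(tr2, "chr1", 76L), 76 / 151)

  # unknown contig falls back to the genome-wide default
  expect_equal(computeGC(tr2, "chrUn", 76L), 0.42)
})

test_that("GC denominator counts only informative (non-N) bases", {
  chars <- rep("N", 400L)
  chars[150:160] <- "G"
  chars[161:171] <- "A"
  ref <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(ref) <- "chr1"
  tr <- GenomeTracks(reference = ref)
  expect_equal(computeGC(tr, "chr1", 160L), 11 / 22)
  # all-N window: no informative base, default
  expect_equal(computeGC(tr, "chr1", 300L), 0.42)
})

test_that("CpG window fraction matches per-position membership counting", {
  tr <- toyTracks()  # island covers 101..130
  # window 26..176 fully covers the island: 30/151
  expect_equal(computeCpG(tr, "chr1", 101L), 30 / 151)
  # window centered so that only part of the island overlaps
  expect_equal(computeCpG(tr, "chr1", 190L),
               sum(101:130 %in% 115:265) / 151)
  # window fully inside a big island
  big <- GenomeTracks(reference = tr@reference,
                      cpgIslands = GenomicRanges::GRanges(
                        "chr1", IRanges::IRanges(1L, 400L)))
  expect_equal(computeCpG(big, "chr1", 200L), 1.0)
  # no track -> default
  none <- GenomeTracks(reference = tr@reference)
  expect_equal(computeCpG(none, "chr1", 200L), 0.02)
})

test_that("GC and CpG agree with counting oracles on random windows", {
  withr::with_seed(99, {
    for (rep in 1:25) {
      len <- 400L
      chars <- sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04))
      ref <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
      names(ref) <- "chr1"
      nIsl <- 3L
      s <- sample.int(len - 30L, nIsl)
      isl <- GenomicRanges::reduce(GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(s, s + sample.int(30L, nIsl))))
      tr <- GenomeTracks(reference = ref, cpgIslands = isl)
      pos <- sample.int(len, 5L)
      gcGot <- computeGC(tr, rep("chr1", 5L), pos)
      cpgGot <- computeCpG(tr, rep("chr1", 5L), pos)
      islPos <- unlist(mapply(seq, GenomicRanges::start(isl),
                              GenomicRanges::end(isl), SIMPLIFY = FALSE))
      for (i in seq_along(pos)) {
        win <- max(1L, pos[i] - 75L):min(len, pos[i] + 75L)
        inf <- chars[win] %in% c("A", "C", "G", "T")
        gcExp <- if (any(inf)) {
          sum(chars[win] %in% c("G", "C")) / sum(inf)
        } else 0.42
        expect_equal(gcGot[i], gcExp)
        expect_equal(cpgGot[i], sum(win %in% islPos) / length(win))
      }
    }
  })
})

test_that("transition/transversion classification is exhaustive", {
  bases <- c("A", "C", "G", "T")
  purine <- c("A", "G")
  for (r in bases) {
    for (a in setdiff(bases, r)) {
      # oracle: transversion iff the pair crosses the purine/pyrimidine line
      expected <- as.numeric((r %in% purine) != (a %in% purine))
      expect_equal(computeIsTV(r, a), expected, info = paste(r, a))
    }
  }
  expect_equal(computeIsTV("A", "G"), 0)   # purine-purine transition
  expect_equal(computeIsTV("A", "C"), 1)   # purine-pyrimidine transversion
  expect_equal(computeIsTV(NA, "C"), 0.5)
  expect_error(computeIsTV("A", "A"), "not a variant")
})

test_that("ancestral lookup normalizes case and falls back to O", {
  tr <- toyTracks()
  expect_equal(lookupAncestral(tr, "chr1", 50L), "C")   # lower-case 'c'
  expect_equal(lookupAncestral(tr, "chr1", 60L), "O")   # N
  expect_equal(lookupAncestral(tr, "chr1", 70L), "O")   # gap '-'
  expect_equal(lookupAncestral(tr, "chr1", 9999L), "O") # beyond contig
  expect_equal(lookupAncestral(tr, "chrUn", 5L), "O")   # unknown contig
  noAnc <- GenomeTracks(reference = tr@reference)
  expect_equal(lookupAncestral(noAnc, "chr1", 50L), "O")
})

test_that("derived-allele truth table covers all 20 (alt, anc) pairs", {
  for (alt in c("A", "C", "G", "T")) {
    for (anc in c("A", "C", "G", "T", "O")) {
      expected <- if (anc == "O") 0.5 else as.numeric(alt != anc)
      expect_equal(computeIsDerived(alt, anc), expected,
                   info = paste(alt, anc))
    }
  }
})

test_that("amino-acid features follow the unknown-code rule", {
  m <- defaultAminoAcidMatrices()
  uu <- aminoAcidFeatures("U", "U", m)
  expect_equal(uu$family_pair, 0)
  expect_equal(uu$transition_amino_acid, m$uValue)
  expect_equal(uu$family_transition, m$uValue)
  ku <- aminoAcidFeatures("K", "U", m)
  expect_equal(ku$family_pair, 0)
  kk <- aminoAcidFeatures("K", "K", m)
  expect_equal(kk$family_pair, 1)
  expect_equal(kk$transition_amino_acid, m$transition["K", "K"])
  expect_error(aminoAcidFeatures("K", "Z", m), "unknown amino-acid")
})

test_that("amino-acid lookups agree with an independent re-read of the config", {
  cfgPath <- tempfile(fileext = ".json")
  writeAminoAcidConfig(cfgPath)
  m <- loadAminoAcidMatrices(cfgPath)
  raw <- jsonlite::read_json(cfgPath)
  de <- aminoAcidFeatures("D", "E", m)
  expect_equal(de$transition_amino_acid, raw$transition$D$E)
  famD <- raw$familyOf$D
  famE <- raw$familyOf$E
  expect_equal(de$family_transition, raw$familyTransition[[famD]][[famE]])
  expect_equal(de$family_pair, 1)
})

test_that("annotation is deterministic and respects variation-type gaps", {
  tr <- toyTracks()
  rec <- data.frame(chrom = "chr1", pos = c(50L, 60L, 100L),
                    ref = c("C", "T", "T"), alt = c("T", "C", "G"),
                    stringsAsFactors = FALSE)
  a1 <- annotateVariants(rec, tr)
  a2 <- annotateVariants(rec, tr)
  expect_identical(a1, a2)
  expect_equal(a1$anc, c("C", "O", "T"))
  expect_equal(a1$is_derived, c(1, 0.5, 1))
  expect_equal(a1$o_aa, rep("U", 3L))

  gapped <- GenomeTracks(reference = tr@reference, ancestral = tr@ancestral,
                         cpgIslands = tr@cpgIslands,
                         tvGaps = GenomicRanges::GRanges(
                           "chr1", IRanges::IRanges(100L, 100L)))
  a3 <- annotateVariants(rec, gapped)
  expect_equal(a3$is_tv, c(0, 0, 0.5))
})
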