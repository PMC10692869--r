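# Shared fixtures, built in code at test time.

# A small hand-written VCF exercising the SNV filter: a plain SNV, a
# multiallelic A->G,T site (2 allele records), an indel, an MNP and a
# homozygous SNV without rank-sum fields -> 4 SNV records, 2 skipped.
toyVcfLines <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##INFO=<ID=QD,Number=1,Type=Float,Description="QD">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="FS">',
    '##INFO=<ID=SOR,Number=1,Type=Float,Description="SOR">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="MQ">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="MQRS">',
    '##INFO=<ID=BaseQRankSum,Number=1,Type=Float,Description="BQRS">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="RPRS">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="GQ">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("chr1", "100", ".", "A", "G", "50", ".",
          "DP=30;QD=12.5;FS=1.2;SOR=0.7;MQ=60;MQRankSum=0.5;BaseQRankSum=-0.3;ReadPosRankSum=0.1",
          "GT:GQ", "0/1:99", sep = "\t"),
    paste("chr1", "200", ".", "A", "G,T", "50", ".",
          "DP=40;QD=10;FS=2;SOR=1;MQ=59", "GT:GQ", "1/2:80", sep = "\t"),
    paste("chr1", "300", ".", "AT", "A", "50", ".",
          "DP=20;QD=5;FS=0;SOR=1;MQ=50", "GT:GQ", "0/1:50", sep = "\t"),
    paste("chr1", "400", ".", "AT", "GC", "50", ".",
          "DP=20;QD=5;FS=0;SOR=1;MQ=50", "GT:GQ", "0/1:50", sep = "\t"),
    paste("chr1", "500", ".", "C", "T", "50", ".",
          "DP=25;QD=8;FS=3;SOR=2;MQ=55", "GT:GQ", "1/1:60", sep = "\t"))
}

writeToyVcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(toyVcfLines(), path)
  path
}

# Tracks over a fully specified 400 bp contig: reference built from a fixed
# pattern, ancestral differing at selected positions.
toyTracks <- function() {
  refChars <- rep(c("A", "C", "G", "T"), length.out = 400L)
  ref <- Biostrings::DNAStringSet(paste(refChars, collapse = ""))
  names(ref) <- "chr1"
  ancChars <- refChars
  ancChars[50L] <- "c"   # lower case, must normalize
  ancChars[60L] <- "N"   # unknown
  ancChars[70L] <- "-"   # gap
  anc <- Biostrings::DNAStringSet(paste(ancChars, collapse = ""))
  names(anc) <- "chr1"
  cpg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101L, 130L))
  GenomeTracks(reference = ref, ancestral = anc, cpgIslands = cpg)
}

# A labeled dataset with controllable group structure, built directly (no
# genomics): each group g has `sizes[g]` duplicate rows sharing one label.
syntheticGroups <- function(nGroups, fpFraction = 0.3, maxDup = 3L,
                            seed = 1L) {
  withr::with_seed(seed, {
    sizes <- sample.int(maxDup, nGroups, replace = TRUE)
    labels <- rbinom(nGroups, 1L, 1 - fpFraction)
    data.frame(
      group = rep(paste0("g", seq_len(nGroups)), sizes),
      label = rep(labels, sizes),
      x = rnorm(sum(sizes))
    )
  })
}

# Small generated modeling dataset shared by training-level tests.
smallDataset <- function(n = 1200L, preset = "imbalanced-27", seed = 11L,
                         ...) {
  cfg <- scenarioPresets()[[preset]]
  cfg$nVariants <- as.integer(n)
  cfg$contigLength <- max(cfg$contigLength, n * 6L + 200L)
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- extra[[nm]]
  datasetFromCallset(generateCallset(cfg, seed = seed))
}
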