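#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))
setClassUnion("DNAStringSetOrNULL", c("DNAStringSet", "NULL"))
setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' GenomeTracks: per-position annotation sources
#'
#' Bundles the random-access sequence and interval tracks needed to annotate
#' SNVs: the reference genome, the (possibly partial) ancestral-base sequence
#' inferred from a primate multiple alignment, CpG-island intervals, optional
#' gap intervals where the variation-type (transition/transversion) track has
#' no information, and an optional per-variant amino-acid consequence table
#' (columns `chrom, pos, ref, alt, o_aa, n_aa`) standing in for a consequence
#' annotator.
#'
#' @slot reference `DNAStringSet` keyed by contig name (lookup must be total
#'   over declared contigs).
#' @slot ancestral `DNAStringSet` or `NULL`; non-ACGT letters mean "unknown".
#' @slot cpgIslands `GRanges` or `NULL` (1-based closed).
#' @slot tvGaps `GRanges` or `NULL`; variants inside get `is_tv = 0.5`.
#' @slot aaEffect `data.frame` or `NULL`.
#' @export
setClass("GenomeTracks",
  slots = c(
    reference = "DNAStringSet",
    ancestral = "DNAStringSetOrNULL",
    cpgIslands = "GRangesOrNULL",
    tvGaps = "GRangesOrNULL",
    aaEffect = "data.frameOrNULL"
  )
)

setValidity("GenomeTracks", function(object) {
  msgs <- character(0)
  if (length(object@reference) == 0L) {
    msgs <- c(msgs, "reference must contain at least one contig")
  }
  if (is.null(names(object@reference)) || anyNA(names(object@reference))) {
    msgs <- c(msgs, "reference contigs must be named")
  }
  if (!is.null(object@aaEffect)) {
    need <- c("chrom", "pos", "ref", "alt", "o_aa", "n_aa")
    if (!all(need %in% names(object@aaEffect))) {
      msgs <- c(msgs, paste("aaEffect must have columns:",
                            paste(need, collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeTracks object
#'
#' @param reference `DNAStringSet` or path to a reference FASTA.
#' @param ancestral `DNAStringSet`, path to an ancestral-base FASTA, or `NULL`.
#' @param cpgIslands `GRanges`, path to a CpG-island BED, or `NULL`.
#' @param tvGaps `GRanges`, path to a BED of variation-type track gaps, or
#'   `NULL`.
#' @param aaEffect `data.frame` or path to a TSV with columns
#'   `chrom, pos, ref, alt, o_aa, n_aa`, or `NULL`.
#' @return a [GenomeTracks-class] object.
#' @export
GenomeTracks <- function(reference, ancestral = NULL, cpgIslands = NULL,
                         tvGaps = NULL, aaEffect = NULL) {
  asSeq <- function(x) {
    if (is.character(x)) Biostrings::readDNAStringSet(x) else x
  }
  asRegions <- function(x) {
    if (is.character(x)) readBedRegions(x) else x
  }
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (is.character(ancestral)) {
    ancestral <- Biostrings::readDNAStringSet(ancestral)
    names(ancestral) <- sub("\\s.*$", "", names(ancestral))
  }
  if (is.character(aaEffect)) {
    aaEffect <- read.table(aaEffect, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  }
  new("GenomeTracks", reference = reference, ancestral = asSeq(ancestral),
      cpgIslands = asRegions(cpgIslands), tvGaps = asRegions(tvGaps),
      aaEffect = aaEffect)
}

setMethod("show", "GenomeTracks", function(object) {
  cat("GenomeTracks object\n")
  cat("  reference:", length(object@reference), "contig(s),",
      sum(as.numeric(Biostrings::width(object@reference))), "bp\n")
  cat("  ancestral:", if (is.null(object@ancestral)) "absent" else
    paste(length(object@ancestral), "contig(s)"), "\n")
  cat("  CpG islands:", if (is.null(object@cpgIslands)) "absent" else
    paste(length(object@cpgIslands), "interval(s)"), "\n")
  cat("  isTV track gaps:", if (is.null(object@tvGaps)) "absent" else
    paste(length(object@tvGaps), "interval(s)"), "\n")
  cat("  amino-acid effects:", if (is.null(object@aaEffect)) "absent" else
    paste(nrow(object@aaEffect), "variant(s)"), "\n")
})

#' FPModel: a fitted false-positive SNV classifier
#'
#' The serializable result of training: the fitted estimator, the frozen
#' categorical encodings (so prediction never re-fits on new data), the
#' feature list (20 features for the full model, fewer for a pruned compact
#' model), the decision threshold, the misclassification costs used, and the
#' cross-validation metrics of the selected hyperparameter candidate.
#'
#' @slot algorithm `"rf"`, `"dt"` or `"logistic"`.
#' @slot fit the fitted estimator (ranger, rpart or glm object).
#' @slot params hyperparameters of the selected candidate.
#' @slot featureNames character vector of model features, in order.
#' @slot encodings frequency-encoding maps for `ref`, `alt`, `anc`.
#' @slot oneHot one-hot category lists for logistic models (`NULL` otherwise).
#' @slot threshold decision threshold: predict "true variant" iff
#'   score >= threshold.
#' @slot cost numeric `c(c1, c2)` misclassification costs (FP, true variant)
#'   or `NULL` for traditional training.
#' @slot cvMetrics named numeric of the candidate's mean CV metrics.
#' @slot seed integer seed used for the final fit.
#' @slot version schema version string.
#' @export
setClass("FPModel",
  slots = c(
    algorithm = "character",
    fit = "ANY",
    params = "list",
    featureNames = "character",
    encodings = "list",
    oneHot = "ANY",
    threshold = "numeric",
    cost = "ANY",
    cvMetrics = "numeric",
    seed = "integer",
    version = "character"
  )
)

setValidity("FPModel", function(object) {
  msgs <- character(0)
  if (!object@algorithm %in% c("rf", "dt", "logistic")) {
    msgs <- c(msgs, "algorithm must be one of rf, dt, logistic")
  }
  if (length(object@featureNames) < 2L) {
    msgs <- c(msgs, "a model needs at least 2 features")
  }
  if (!all(object@featureNames %in% fpFeatureNames())) {
    msgs <- c(msgs, "featureNames must be a subset of fpFeatureNames()")
  }
  if (length(object@threshold) != 1L || object@threshold < 0 ||
      object@threshold > 1) {
    msgs <- c(msgs, "threshold must be a single value in [0, 1]")
  }
  if (!is.null(object@cost) &&
      (length(object@cost) != 2L || any(object@cost <= 0))) {
    msgs <- c(msgs, "cost must be NULL or two positive values c(c1, c2)")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "FPModel", function(object) {
  cat("FPModel (", object@algorithm,
      if (!is.null(object@cost)) ", cost-sensitive" else "", ")\n", sep = "")
  cat("  features:", length(object@featureNames),
      if (length(object@featureNames) < length(fpFeatureNames()))
        "(compact)" else "(full)", "\n")
  cat("  threshold:", format(object@threshold), "\n")
  if (!is.null(object@cost)) {
    cat("  costs: c1 =", object@cost[1L], "(FP), c2 =", object@cost[2L],
        "(true variant)\n")
  }
  if (length(object@cvMetrics)) {
    cat("  CV metrics:",
        paste(names(object@cvMetrics),
              sprintf("%.4f", object@cvMetrics), sep = "=", collapse = " "),
        "\n")
  }
})

#' @describeIn FPModel-class the algorithm identifier.
#' @param object an `FPModel`.
#' @export
setGeneric("modelAlgorithm", function(object) standardGeneric("modelAlgorithm"))
#' @export
setMethod("modelAlgorithm", "FPModel", function(object) object@algorithm)

#' @describeIn FPModel-class the ordered feature list.
#' @export
setGeneric("modelFeatures", function(object) standardGeneric("modelFeatures"))
#' @export
setMethod("modelFeatures", "FPModel", function(object) object@featureNames)

#' @describeIn FPModel-class the decision threshold.
#' @export
setGeneric("modelThreshold", function(object) standardGeneric("modelThreshold"))
#' @export
setMethod("modelThreshold", "FPModel", function(object) object@threshold)

#' @describeIn FPModel-class replace the decision threshold.
#' @param value new threshold in `[0, 1]`.
#' @export
setGeneric("modelThreshold<-",
           function(object, value) standardGeneric("modelThreshold<-"))
#' @export
setMethod("modelThreshold<-", "FPModel", function(object, value) {
  object@threshold <- as.numeric(value)
  validObject(object)
  object
})

#' @describeIn FPModel-class the frozen categorical encodings.
#' @export
setGeneric("modelEncodings", function(object) standardGeneric("modelEncodings"))
#' @export
setMethod("modelEncodings", "FPModel", function(object) object@encodings)

#' Save / load a fitted model bundle
#'
#' The bundle is written as an RDS archive holding the estimator together
#' with its frozen encodings, feature list, threshold and selection metadata,
#' plus a human-readable JSON sidecar (`<path>.json`) with everything except
#' the estimator itself.
#'
#' @param model an [FPModel-class].
#' @param path output path for the archive.
#' @return `path`, invisibly.
#' @export
saveFPModel <- function(model, path) {
  stopifnot(is(model, "FPModel"))
  saveRDS(model, path)
  meta <- list(
    algorithm = model@algorithm,
    params = model@params,
    featureNames = model@featureNames,
    encodings = lapply(model@encodings, function(e)
      list(freq = as.list(e$freq), fittedN = e$fittedN,
           unseenValue = e$unseenValue)),
    threshold = model@threshold,
    cost = model@cost,
    cvMetrics = as.list(model@cvMetrics),
    seed = model@seed,
    version = model@version
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname saveFPModel
#' @export
readFPModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "FPModel"))
  validObject(model)
  model
}
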