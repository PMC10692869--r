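## Imputation constants; they must appear bit-exactly in encoded output.
RANK_SUM_FILL <- -999

#' The canonical model feature list
#'
#' The 20 features of the full model, in their fixed, versioned order. The
#' three `*_frequency` features are the frequency-encoded Ref/Alt/Anc bases;
#' the rest are GATK quality metrics, window/track features and the
#' amino-acid transition features.
#'
#' @return character vector of length 20.
#' @export
fpFeatureNames <- function() {
  c("ref_frequency", "alt_frequency", "anc_frequency",
    "dp", "qd", "fs", "sor", "mq", "gq",
    "mq_rank_sum", "base_q_rank_sum", "read_pos_rank_sum",
    "cpg", "gc", "is_tv", "is_derived", "is_homo",
    "transition_amino_acid", "family_transition", "family_pair")
}

## Maps each model feature to the column of the assembled dataset it is
## derived from (identity except for the frequency-encoded categoricals).
#' @keywords internal
.featureSourceColumn <- function(feature) {
  src <- c(ref_frequency = "ref", alt_frequency = "alt",
           anc_frequency = "anc")
  ifelse(feature %in% names(src), src[feature], feature)
}

#' Fit a frequency encoding on training values
#'
#' Each category is mapped to its relative frequency in the training column:
#' `count(category) / number of training rows`. Categories never seen in
#' training are absent from the map and encode to `unseenValue` at prediction
#' time.
#'
#' @param values character vector of training categories (non-empty).
#' @param unseenValue value returned for unseen categories (default 0).
#' @return an encoding map: list with `freq` (named numeric), `fittedN`,
#'   `unseenValue`.
#' @export
fitFrequencyEncoding <- function(values, unseenValue = 0) {
  if (length(values) == 0L) stop("cannot fit a frequency encoding on empty input")
  tab <- table(values)
  freq <- as.numeric(tab) / length(values)
  names(freq) <- names(tab)
  list(freq = freq, fittedN = length(values), unseenValue = unseenValue)
}

#' Apply a fitted frequency encoding
#'
#' @param map encoding map from [fitFrequencyEncoding()].
#' @param values categories to encode.
#' @return numeric vector of training frequencies (`map$unseenValue` for
#'   unseen categories).
#' @export
applyFrequencyEncoding <- function(map, values) {
  out <- unname(map$freq[values])
  out[is.na(out)] <- map$unseenValue
  out
}

#' Fit a one-hot encoding on training values
#'
#' Used for the Ref/Alt/Anc bases in logistic-regression models. Categories
#' unseen at prediction time encode to an all-zero row.
#'
#' @param values character vector of training categories.
#' @return list with `levels` (sorted training categories).
#' @export
fitOneHot <- function(values) {
  if (length(values) == 0L) stop("cannot fit a one-hot encoding on empty input")
  list(levels = sort(unique(values)))
}

#' @rdname fitOneHot
#' @param encoder encoder from [fitOneHot()].
#' @param prefix column-name prefix for the indicator matrix.
#' @export
applyOneHot <- function(encoder, values, prefix = "x") {
  m <- vapply(encoder$levels, function(l) as.numeric(values == l),
              numeric(length(values)))
  if (length(values) == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- paste(prefix, encoder$levels, sep = ".")
  m
}

#' Homozygosity indicator and rank-sum imputation
#'
#' GATK's rank-sum tests need both reference and alternative reads, so all
#' three `*RankSum` metrics are absent for homozygous calls; `is_homo` is 1
#' exactly when all three are absent. Any absent rank-sum value is filled
#' with the sentinel -999; present values pass through unchanged.
#'
#' @param records SNV records from [readSNVs()].
#' @return `records` with filled `mq_rank_sum, base_q_rank_sum,
#'   read_pos_rank_sum` and a new `is_homo` column in `{0, 1}`.
#' @export
deriveIsHomo <- function(records) {
  rs <- c("mq_rank_sum", "base_q_rank_sum", "read_pos_rank_sum")
  miss <- vapply(rs, function(cn) is.na(records[[cn]]), logical(nrow(records)))
  if (nrow(records) == 1L) miss <- matrix(miss, nrow = 1L)
  records$is_homo <- as.numeric(rowSums(miss) == length(rs))
  for (cn in rs) {
    records[[cn]][is.na(records[[cn]])] <- RANK_SUM_FILL
  }
  records
}

#' Assemble the modeling dataset from records and annotations
#'
#' Joins the quality metrics with the genomic annotation, applies the
#' missing-value rules (rank-sum sentinel, `is_homo`), computes the
#' amino-acid transition features, and carries identifiers (`chrom`, `pos`,
#' raw `ref`/`alt`/`anc` categories, the group key) alongside — but never
#' inside — the feature set. Categorical encodings are *not* applied here;
#' they are fitted on training rows only (see [encodeFeatures()]).
#'
#' @param records SNV records from [readSNVs()].
#' @param annotation matching annotation from [annotateVariants()].
#' @param matrices amino-acid matrices from [loadAminoAcidMatrices()].
#' @return data.frame with identifier columns (`chrom, pos, ref, alt, anc,
#'   o_aa, n_aa, genotype, kit, group`) and the 17 numeric feature columns.
#' @export
assembleDataset <- function(records, annotation,
                            matrices = defaultAminoAcidMatrices()) {
  stopifnot(nrow(records) == nrow(annotation))
  records <- deriveIsHomo(records)
  aa <- aminoAcidFeatures(annotation$o_aa, annotation$n_aa, matrices)
  numericCols <- c("dp", "qd", "fs", "sor", "mq", "gq", "mq_rank_sum",
                   "base_q_rank_sum", "read_pos_rank_sum")
  for (cn in numericCols) {
    if (anyNA(records[[cn]])) {
      stop("unfillable missing values in required metric '", cn, "'")
    }
  }
  out <- data.frame(
    chrom = records$chrom, pos = records$pos,
    ref = records$ref, alt = records$alt, anc = annotation$anc,
    o_aa = annotation$o_aa, n_aa = annotation$n_aa,
    genotype = records$genotype,
    kit = if ("kit" %in% names(records)) records$kit else "1",
    group = variantKey(records$chrom, records$pos, records$ref, records$alt),
    records[numericCols],
    cpg = annotation$cpg, gc = annotation$gc,
    is_tv = annotation$is_tv, is_derived = annotation$is_derived,
    is_homo = records$is_homo,
    aa,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Fit the categorical encodings for a training partition
#'
#' Fits the frequency-encoding maps for `ref`, `alt` and `anc` (and the
#' one-hot category lists used by logistic models) on the given training
#' rows only, so no information from evaluation rows leaks into the
#' encoding.
#'
#' @param dataset assembled dataset rows (training portion).
#' @param unseenValue frequency assigned to categories unseen in training.
#' @return list with elements `ref`, `alt`, `anc` (encoding maps) and
#'   `oneHot` (per-column category lists).
#' @export
fitEncodings <- function(dataset, unseenValue = 0) {
  list(
    ref = fitFrequencyEncoding(dataset$ref, unseenValue),
    alt = fitFrequencyEncoding(dataset$alt, unseenValue),
    anc = fitFrequencyEncoding(dataset$anc, unseenValue),
    oneHot = list(ref = fitOneHot(dataset$ref), alt = fitOneHot(dataset$alt),
                  anc = fitOneHot(dataset$anc))
  )
}

#' Encode an assembled dataset into the model feature matrix
#'
#' Produces the fixed 20-feature matrix (or the requested subset, for
#' compact models) by applying frozen frequency encodings to the raw
#' categorical columns and passing numeric features through. A pure function
#' of its inputs: identical inputs yield an identical matrix.
#'
#' @param dataset assembled dataset from [assembleDataset()].
#' @param encodings encodings from [fitEncodings()] (fitted on training
#'   rows).
#' @param features feature subset to emit, default the full 20.
#' @return numeric data.frame with one column per requested feature, in
#'   canonical order.
#' @export
encodeFeatures <- function(dataset, encodings, features = fpFeatureNames()) {
  stopifnot(all(features %in% fpFeatureNames()))
  missingSrc <- setdiff(unique(.featureSourceColumn(features)), names(dataset))
  if (length(missingSrc)) {
    stop("dataset is missing required column(s): ",
         paste(missingSrc, collapse = ", "))
  }
  out <- lapply(features, function(f) {
    switch(f,
      ref_frequency = applyFrequencyEncoding(encodings$ref, dataset$ref),
      alt_frequency = applyFrequencyEncoding(encodings$alt, dataset$alt),
      anc_frequency = applyFrequencyEncoding(encodings$anc, dataset$anc),
      dataset[[f]]
    )
  })
  names(out) <- features
  out <- as.data.frame(out)
  bad <- names(out)[vapply(out, anyNA, logical(1))]
  if (length(bad)) {
    stop("missing values after encoding in feature(s): ",
         paste(bad, collapse = ", "))
  }
  out
}
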