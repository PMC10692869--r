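AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V")

## Radical-group families of the 20 standard amino acids.
AA_FAMILIES <- c(
  A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
  P = "nonpolar", M = "nonpolar", G = "nonpolar",
  F = "aromatic", W = "aromatic", Y = "aromatic",
  S = "polar", T = "polar", C = "polar", N = "polar", Q = "polar",
  K = "positive", R = "positive", H = "positive",
  D = "negative", E = "negative"
)

#' Default amino-acid transition matrices
#'
#' Builds a synthetic 21x21 amino-acid transition probability matrix (the 20
#' standard amino acids plus `U` for "unknown") from single-nucleotide codon
#' accessibility: the probability of replacing amino acid i with j is
#' proportional to the number of codon pairs that encode i and j and differ
#' by exactly one base (stop codons excluded), row-normalized. The family
#' transition matrix aggregates the same counts over the radical-group
#' families. The `U` row/column takes a configurable constant (default 0) so
#' variants without consequence annotation contribute a fixed, uninformative
#' value. These defaults are a self-contained stand-in for an empirically
#' fitted substitution matrix and can be replaced by any user-supplied
#' configuration via [loadAminoAcidMatrices()].
#'
#' @param uValue value used for transitions involving the unknown code `U`.
#' @return a list with elements `transition` (21x21 matrix), `familyOf`
#'   (named character), `familyTransition` (matrix over families plus `U`)
#'   and `uValue`.
#' @export
defaultAminoAcidMatrices <- function(uValue = 0) {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- gc
  counts <- matrix(0, 20, 20, dimnames = list(AA_CODES, AA_CODES))
  bases <- c("A", "C", "G", "T")
  for (ci in codons) {
    if (aa[[ci]] == "*") next
    sp <- strsplit(ci, "")[[1L]]
    for (k in 1:3) {
      for (b in setdiff(bases, sp[k])) {
        cj <- sp; cj[k] <- b
        cj <- paste(cj, collapse = "")
        if (aa[[cj]] == "*") next
        counts[aa[[ci]], aa[[cj]]] <- counts[aa[[ci]], aa[[cj]]] + 1
      }
    }
  }
  transition <- counts / rowSums(counts)
  fams <- sort(unique(AA_FAMILIES))
  famCounts <- matrix(0, length(fams), length(fams),
                      dimnames = list(fams, fams))
  for (i in AA_CODES) {
    for (j in AA_CODES) {
      famCounts[AA_FAMILIES[[i]], AA_FAMILIES[[j]]] <-
        famCounts[AA_FAMILIES[[i]], AA_FAMILIES[[j]]] + counts[i, j]
    }
  }
  familyTransition <- famCounts / rowSums(famCounts)

  addU <- function(m) {
    m <- rbind(cbind(m, U = uValue), U = uValue)
    rownames(m)[nrow(m)] <- "U"
    m
  }
  list(
    transition = addU(transition),
    familyOf = c(AA_FAMILIES, U = "U"),
    familyTransition = addU(familyTransition),
    uValue = uValue
  )
}

#' Load amino-acid transition matrices from a JSON config
#'
#' The config is an editable JSON object with fields `transition` (21x21,
#' named rows/columns including `U`), `familyOf` (amino acid to family map)
#' and `familyTransition`. [writeAminoAcidConfig()] writes the current
#' defaults in this format. Every amino-acid code must be covered; missing
#' codes are a configuration error raised at load time, not per variant.
#'
#' @param path JSON config path, or `NULL` for the built-in defaults.
#' @return a matrices list as from [defaultAminoAcidMatrices()].
#' @export
loadAminoAcidMatrices <- function(path = NULL) {
  if (is.null(path)) return(defaultAminoAcidMatrices())
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  nestedToMatrix <- function(x) {
    cols <- names(x[[1L]])
    m <- do.call(rbind, lapply(x, function(r) unlist(r)[cols]))
    dimnames(m) <- list(names(x), cols)
    m
  }
  m <- list(
    transition = nestedToMatrix(cfg$transition),
    familyOf = unlist(cfg$familyOf),
    familyTransition = nestedToMatrix(cfg$familyTransition),
    uValue = if (!is.null(cfg$uValue)) cfg$uValue else 0
  )
  need <- c(AA_CODES, "U")
  if (!all(need %in% rownames(m$transition)) ||
      !all(need %in% colnames(m$transition))) {
    stop("amino-acid transition matrix in ", path,
         " must cover all 20 amino acids plus U")
  }
  if (!all(need %in% names(m$familyOf))) {
    stop("familyOf map in ", path, " must cover all 20 amino acids plus U")
  }
  fams <- unique(m$familyOf[AA_CODES])
  if (!all(fams %in% rownames(m$familyTransition))) {
    stop("familyTransition matrix in ", path, " must cover every family")
  }
  m
}

#' @rdname loadAminoAcidMatrices
#' @param matrices a matrices list to serialize.
#' @export
writeAminoAcidConfig <- function(path, matrices = defaultAminoAcidMatrices()) {
  matrixToNested <- function(m) {
    out <- lapply(rownames(m), function(r) as.list(m[r, ]))
    names(out) <- rownames(m)
    out
  }
  jsonlite::write_json(
    list(transition = matrixToNested(matrices$transition),
         familyOf = as.list(matrices$familyOf),
         familyTransition = matrixToNested(matrices$familyTransition),
         uValue = matrices$uValue),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Amino-acid transition features for one substitution
#'
#' Maps a reference/alternative amino-acid pair to the three model features:
#' `family_pair` is 0 when either code is unknown (`U`) and 1 otherwise;
#' when 1, `transition_amino_acid` is the amino-acid transition probability
#' and `family_transition` the radical-group family transition probability;
#' when 0 both take the configured `U` value.
#'
#' @param oAA,nAA reference and alternative amino-acid one-letter codes, or
#'   `"U"` when unknown (vectorized).
#' @param matrices matrices list from [loadAminoAcidMatrices()].
#' @return data.frame with columns `transition_amino_acid`,
#'   `family_transition`, `family_pair`.
#' @export
aminoAcidFeatures <- function(oAA, nAA, matrices = defaultAminoAcidMatrices()) {
  known <- c(AA_CODES, "U")
  if (!all(oAA %in% known) || !all(nAA %in% known)) {
    stop("unknown amino-acid code(s): ",
         paste(setdiff(c(oAA, nAA), known), collapse = ", "))
  }
  pair <- as.numeric(oAA != "U" & nAA != "U")
  ta <- matrices$transition[cbind(oAA, nAA)]
  fo <- matrices$familyOf[oAA]
  fn <- matrices$familyOf[nAA]
  ft <- ifelse(pair == 1,
               matrices$familyTransition[cbind(fo, fn)],
               matrices$uValue)
  ta <- ifelse(pair == 1, ta, matrices$uValue)
  data.frame(transition_amino_acid = as.numeric(ta),
             family_transition = as.numeric(ft),
             family_pair = pair)
}
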