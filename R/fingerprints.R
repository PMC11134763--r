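## Structural similarity ground truth: fingerprints and Tanimoto.

#' Tanimoto similarity of two bit fingerprints
#'
#' `|a AND b| / |a OR b|` for equal-length binary fingerprints. Defined
#' as 0 when both fingerprints are empty.
#'
#' @param a,b Numeric or logical vectors of equal length (nonzero = bit
#'   set).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) abort("fingerprint length mismatch")
  a <- as.logical(a != 0)
  b <- as.logical(b != 0)
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Path-based fingerprints for SMILES structures
#'
#' Computes path-based (Daylight-style) binary fingerprints for a table
#' of structures using Open Babel's FP2 fingerprint (1024 bits, linear
#' fragments up to 7 atoms) via the ChemmineOB package.
#'
#' @param structures A data frame with columns `structure_key` and
#'   `smiles`, one row per unique structure.
#' @return A tibble with `structure_key` and a `fingerprint` list column
#'   of 0/1 vectors.
#' @export
structure_fingerprints <- function(structures) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort("structure_fingerprints() requires the ChemmineOB package")
  }
  structures <- tibble::as_tibble(structures)
  stopifnot(all(c("structure_key", "smiles") %in% names(structures)))
  if (anyDuplicated(structures$structure_key)) {
    abort("one fingerprint per unique structure_key: duplicates present")
  }
  fps <- lapply(structures$smiles, function(sm) {
    fp <- ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", sm, identity), "FP2")
    as.numeric(fp != 0)
  })
  tibble::tibble(structure_key = structures$structure_key, fingerprint = fps)
}

#' Pairwise Tanimoto matrix
#'
#' @param fingerprints Result of [structure_fingerprints()] (or any tibble
#'   with `structure_key` and a `fingerprint` list column).
#' @return A symmetric similarity matrix with structure keys as
#'   dimnames.
#' @export
tanimoto_matrix <- function(fingerprints) {
  F <- do.call(rbind, fingerprints$fingerprint)
  F <- F != 0
  inter <- tcrossprod(F * 1)
  ones <- rowSums(F)
  uni <- outer(ones, ones, `+`) - inter
  S <- ifelse(uni > 0, inter / uni, 0)
  dimnames(S) <- list(fingerprints$structure_key, fingerprints$structure_key)
  S
}
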