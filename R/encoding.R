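## Encoding of a (query, reference) spectrum pair into the model input:
## mass difference matrix (MDM) -> aligned token matrix.
##
## All m/z arithmetic is done on integer hundredths of a Da so that the
## nominal-mass / mass-defect split of a 2-dp value is exact.

TOKEN_PAD <- 100L
TOKEN_CLS <- 101L

hundredths <- function(mz) as.integer(round(mz * 100))

#' Neutral-loss spectrum
#'
#' Converts a fragment spectrum into its hypothetical neutral-loss
#' spectrum: each fragment at m/z \eqn{f} becomes a loss peak at
#' `precursor_mz - f` (2 dp), inheriting the fragment intensity.
#' Non-positive losses (fragments at or above the precursor) are dropped.
#'
#' @param s A single spectrum: a one-row spectra tibble or a
#'   `list(peaks =, precursor_mz =)`.
#' @return A tibble with columns `mz` (loss in Da), `intensity` and
#'   `fragment` (index of the originating fragment in the m/z-sorted
#'   input peak list), sorted ascending by loss.
#' @export
neutral_loss_spectrum <- function(s) {
  rec <- spectrum_record(s)
  if (is.na(rec$precursor_mz)) abort("precursor required for neutral loss")
  p <- rec$peaks[order(rec$peaks$mz), ]
  loss2 <- hundredths(rec$precursor_mz) - hundredths(p$mz)
  keep <- loss2 > 0L
  out <- tibble::tibble(
    mz = loss2[keep] / 100,
    intensity = p$intensity[keep],
    fragment = which(keep)
  )
  out[order(out$mz), ]
}

#' Mass difference matrix (MDM)
#'
#' The absolute m/z difference (2 dp) between every query fragment (rows)
#' and every reference fragment (columns).
#'
#' @param query,reference Single spectra (one-row spectra tibbles or
#'   `list(peaks =, precursor_mz =)`); both must have at least one peak.
#' @return An object of class `mdm`: a list with `values` (s_q x s_r
#'   matrix, Da), `query_mz`, `reference_mz`, `reference_intensity`.
#' @export
mass_difference_matrix <- function(query, reference) {
  q <- spectrum_record(query)$peaks
  r <- spectrum_record(reference)$peaks
  if (!nrow(q) || !nrow(r)) abort("cannot build MDM from an empty spectrum")
  q <- q[order(q$mz), ]
  r <- r[order(r$mz), ]
  d2 <- abs(outer(hundredths(q$mz), hundredths(r$mz), `-`))
  structure(list(
    values = d2 / 100,
    query_mz = round(q$mz, 2),
    reference_mz = round(r$mz, 2),
    reference_intensity = r$intensity
  ), class = "mdm")
}

#' @export
print.mdm <- function(x, ...) {
  cat(sprintf("<mdm> %d query x %d reference fragments\n",
              length(x$query_mz), length(x$reference_mz)))
  print(x$values, ...)
  invisible(x)
}

#' Aligned (tokenized) matrix
#'
#' Re-indexes an MDM by nominal mass: each mass difference `d < cutoff`
#' contributes a token `round(100 * (d - floor(d)))` (its mass defect in
#' hundredths, 0-99) in column `floor(d) + 1` of its query row. Columns
#' with no difference hold the PAD token (100); a CLS row of CLS tokens
#' (101) is prepended as the aggregation entry. When two reference
#' fragments land in the same (row, column) cell, the fragment with the
#' higher relative intensity wins (ties towards the smaller reference
#' m/z). `provenance` records the winning reference fragment index per
#' non-PAD cell (0 elsewhere).
#'
#' @param mdm An [mass_difference_matrix()] result.
#' @param cutoff Only differences strictly below this value (Da) are
#'   encoded.
#' @return An object of class `aligned_matrix` with integer matrices
#'   `tokens` and `provenance` of dimension `(s_q + 1) x cutoff`.
#' @export
aligned_matrix <- function(mdm, cutoff = 300) {
  stopifnot(inherits(mdm, "mdm"))
  n <- length(mdm$query_mz)
  m <- as.integer(cutoff)
  tokens <- matrix(TOKEN_PAD, n + 1L, m)
  prov <- matrix(0L, n + 1L, m)
  tokens[1L, ] <- TOKEN_CLS
  d2 <- round(mdm$values * 100)
  lim <- m * 100L
  ## collision priority: higher reference intensity, then smaller reference m/z
  prio <- order(-mdm$reference_intensity, mdm$reference_mz)
  for (i in seq_len(n)) {
    js <- prio[d2[i, prio] < lim]
    if (!length(js)) next
    cols <- d2[i, js] %/% 100L + 1L
    win <- !duplicated(cols)
    js <- js[win]; cols <- cols[win]
    tokens[i + 1L, cols] <- as.integer(d2[i, js] %% 100L)
    prov[i + 1L, cols] <- js
  }
  structure(list(
    tokens = tokens, provenance = prov,
    query_mz = mdm$query_mz, reference_mz = mdm$reference_mz,
    cutoff = m
  ), class = "aligned_matrix")
}

#' @export
print.aligned_matrix <- function(x, ...) {
  nz <- sum(x$tokens[-1L, , drop = FALSE] != TOKEN_PAD)
  cat(sprintf("<aligned_matrix> %d rows (CLS + %d fragments) x %d columns, %d filled cells\n",
              nrow(x$tokens), nrow(x$tokens) - 1L, x$cutoff, nz))
  invisible(x)
}

#' Encode a spectrum pair for the similarity model
#'
#' Builds the fragment-tower aligned matrix from the two spectra and the
#' loss-tower aligned matrix from their neutral-loss spectra
#' ([neutral_loss_spectrum()]). Both spectra should already be
#' preprocessed and must carry a precursor m/z.
#'
#' @param query,reference Single spectra (one-row spectra tibbles or
#'   `list(peaks =, precursor_mz =)`).
#' @param cutoff Nominal-mass cut-off passed to [aligned_matrix()].
#' @return An object of class `pair_encoding` with elements `fragment`
#'   and `loss` (aligned matrices), `query_loss_map` / `reference_loss_map`
#'   (loss row/column index to originating fragment index) and the m/z
#'   axes of both spectra.
#' @export
encode_pair <- function(query, reference, cutoff = 300) {
  qr <- spectrum_record(query)
  rr <- spectrum_record(reference)
  frag <- aligned_matrix(mass_difference_matrix(qr, rr), cutoff)
  qnl <- neutral_loss_spectrum(qr)
  rnl <- neutral_loss_spectrum(rr)
  if (!nrow(qnl) || !nrow(rnl)) {
    abort("no positive neutral losses; check precursor m/z")
  }
  loss <- aligned_matrix(mass_difference_matrix(
    list(peaks = qnl[c("mz", "intensity")]),
    list(peaks = rnl[c("mz", "intensity")])
  ), cutoff)
  structure(list(
    fragment = frag, loss = loss,
    query_loss_map = qnl$fragment, reference_loss_map = rnl$fragment,
    query_mz = frag$query_mz, reference_mz = frag$reference_mz,
    query_id = qr$spectrum_id, reference_id = rr$spectrum_id
  ), class = "pair_encoding")
}

#' @export
print.pair_encoding <- function(x, ...) {
  cat(sprintf("<pair_encoding> %d query x %d reference fragments (%d x %d losses)\n",
              length(x$query_mz), length(x$reference_mz),
              nrow(x$loss$tokens) - 1L, length(x$loss$reference_loss_map %||% x$reference_loss_map)))
  invisible(x)
}
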