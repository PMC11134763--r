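## Spectral library search and classical cosine baselines.

#' Search a spectral library with the similarity model
#'
#' Scores one query spectrum against every reference spectrum (query in
#' the query role) and returns the ranking, ties broken by reference id.
#'
#' @param model A trained `ms2sim_model`.
#' @param query A single spectrum (one-row spectra tibble).
#' @param library Spectra tibble of reference spectra (non-empty).
#' @param top_n Number of hits to return (default: full ranking).
#' @param batch_size Pairs per forward batch.
#' @return A tibble `query_id`, `reference_id`, `y_sim`, `rank`.
#' @export
library_search <- function(model, query, library, top_n = Inf,
                           batch_size = 256L) {
  library <- as_ms2_spectra(library)
  if (!nrow(library)) abort("empty spectral library")
  qrec <- spectrum_record(query)
  enc <- lapply(seq_len(nrow(library)), function(i) {
    enc <- encode_pair(qrec, library[i, ], cutoff = model$config$n_columns)
    list(fragment = list(tokens = enc$fragment$tokens),
         loss = list(tokens = enc$loss$tokens))
  })
  scores <- predict_encoded(model, enc, batch_size)
  out <- tibble::tibble(
    query_id = qrec$spectrum_id,
    reference_id = library$spectrum_id,
    y_sim = scores
  )
  out <- out[order(-out$y_sim, out$reference_id), ]
  out$rank <- seq_len(nrow(out))
  head(out, n = if (is.finite(top_n)) top_n else nrow(out))
}

#' Cosine and modified cosine spectral similarity
#'
#' Classical intensity-weighted cosine similarity with greedy one-to-one
#' peak matching. In `"plain"` mode peaks match when their m/z agree
#' within `tol`; `"modified"` mode additionally allows matches shifted by
#' the precursor mass difference. Candidate matches are taken greedily in
#' order of decreasing intensity product (ties towards the smaller m/z
#' deviation), each peak used at most once; the score is the matched
#' intensity-product sum over the product of the spectrum norms.
#'
#' @param a,b Single spectra (one-row spectra tibbles or
#'   `list(peaks =, precursor_mz =)`).
#' @param tol Peak-match tolerance in Da.
#' @param mode `"plain"` or `"modified"`.
#' @return Similarity in `[0, 1]`; symmetric in its arguments.
#' @export
cosine_score <- function(a, b, tol = 0.02, mode = c("plain", "modified")) {
  mode <- match.arg(mode)
  ra <- spectrum_record(a)
  rb <- spectrum_record(b)
  pa <- ra$peaks; pb <- rb$peaks
  if (!nrow(pa) || !nrow(pb)) abort("cannot score an empty spectrum")
  shift <- 0
  if (mode == "modified") {
    if (is.na(ra$precursor_mz) || is.na(rb$precursor_mz)) {
      abort("modified cosine requires precursor m/z on both spectra")
    }
    shift <- ra$precursor_mz - rb$precursor_mz
  }
  dmz <- outer(pa$mz, pb$mz, `-`)
  ok <- abs(dmz) <= tol + 1e-9
  if (mode == "modified") ok <- ok | abs(dmz - shift) <= tol + 1e-9
  idx <- which(ok, arr.ind = TRUE)
  if (!nrow(idx)) return(0)
  prod <- pa$intensity[idx[, 1L]] * pb$intensity[idx[, 2L]]
  dev <- pmin(abs(dmz[idx]), abs(dmz[idx] - if (mode == "modified") shift else Inf))
  o <- order(-prod, dev, idx[, 1L], idx[, 2L])
  used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
  total <- 0
  for (r in o) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- used_b[j] <- TRUE
      total <- total + prod[r]
    }
  }
  total / (sqrt(sum(pa$intensity^2)) * sqrt(sum(pb$intensity^2)))
}

#' Score labelled pairs with model and baselines
#'
#' Convenience wrapper producing the scored-pair table consumed by
#' [evaluate_pairs()]: predicts `y_sim` for every pair and optionally
#' adds cosine / modified-cosine baseline columns.
#'
#' @param model A trained `ms2sim_model`.
#' @param pairs Tibble with `query_id`, `reference_id` and (optionally)
#'   `label`.
#' @param spectra Spectra tibble covering all ids in `pairs`.
#' @param baselines Character vector among `"cosine"`,
#'   `"modified_cosine"`.
#' @param batch_size Pairs per forward batch.
#' @return `pairs` with added score columns.
#' @export
score_pairs <- function(model, pairs, spectra,
                        baselines = character(), batch_size = 256L) {
  spectra <- as_ms2_spectra(spectra)
  enc <- encode_pairs_cached(pairs, spectra, new.env(parent = emptyenv()),
                             model$config$n_columns)
  pairs$y_sim <- predict_encoded(model, enc, batch_size)
  qi <- match(pairs$query_id, spectra$spectrum_id)
  ri <- match(pairs$reference_id, spectra$spectrum_id)
  if ("cosine" %in% baselines) {
    pairs$cosine <- purrr::map2_dbl(qi, ri, function(i, j)
      cosine_score(spectra[i, ], spectra[j, ], mode = "plain"))
  }
  if ("modified_cosine" %in% baselines) {
    pairs$modified_cosine <- purrr::map2_dbl(qi, ri, function(i, j)
      cosine_score(spectra[i, ], spectra[j, ], mode = "modified"))
  }
  pairs
}
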