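## Balanced pair sampling over structural-similarity bins.

#' Pair-sampling configuration
#'
#' Equal-width binning of the structural-similarity range `[0, 1]` used
#' both for balanced training-pair sampling and for test-pair
#' construction. Bins are `[l, u)` with the final bin closed at 1.
#'
#' @param n_bins Number of equal-width bins (default 10).
#' @param max_test_pairs_per_bin Per test spectrum, at most this many
#'   pairs are drawn from each bin (default 3).
#' @param seed Integer seed for test-pair construction.
#' @return A `pair_sampling_config` list.
#' @export
pair_sampling_config <- function(n_bins = 10L, max_test_pairs_per_bin = 3L,
                                 seed = 0L) {
  stopifnot(n_bins >= 1L, max_test_pairs_per_bin >= 1L)
  structure(list(n_bins = as.integer(n_bins),
                 max_test_pairs_per_bin = as.integer(max_test_pairs_per_bin),
                 seed = as.integer(seed)),
            class = "pair_sampling_config")
}

## Bin index in 1..n_bins for similarity values in [0, 1]; the last bin
## is closed so a similarity of exactly 1 falls in bin n_bins.
similarity_bin <- function(x, n_bins = 10L) {
  pmin(floor(x * n_bins) + 1L, n_bins)
}

#' Sample one epoch of balanced training pairs
#'
#' For every spectrum and every similarity bin that contains at least one
#' partner, samples one partner uniformly at random, yielding at most
#' `n_bins` pairs per spectrum per epoch. Self-pairs are excluded; empty
#' bins are skipped. Deterministic given `epoch_seed`.
#'
#' @param spectrum_ids Character vector of spectrum identifiers.
#' @param sim Similarity matrix (rows/columns follow `spectrum_ids`) with
#'   entries in `[0, 1]`.
#' @param cfg A [pair_sampling_config()].
#' @param epoch_seed Integer seed for this epoch.
#' @return A tibble with columns `query_id`, `reference_id`, `label`.
#' @export
sample_epoch_pairs <- function(spectrum_ids, sim, cfg = pair_sampling_config(),
                               epoch_seed = 0L) {
  n <- length(spectrum_ids)
  stopifnot(nrow(sim) == n, ncol(sim) == n)
  if (n < 2L) abort("need at least two spectra to sample pairs")
  withr::with_seed(as.integer(epoch_seed), {
    qs <- vector("list", n)
    for (i in seq_len(n)) {
      s <- sim[i, ]
      cand <- setdiff(seq_len(n), i)
      bins <- similarity_bin(s[cand], cfg$n_bins)
      pick <- vapply(split(cand, bins), function(js) {
        if (length(js) == 1L) js else sample(js, 1L)
      }, integer(1))
      if (length(pick)) {
        qs[[i]] <- tibble::tibble(
          query_id = spectrum_ids[i],
          reference_id = spectrum_ids[pick],
          label = s[pick]
        )
      }
    }
    dplyr::bind_rows(qs)
  })
}

#' Construct labelled test pairs
#'
#' Pairs every test spectrum with reference spectra, drawing at most
#' `cfg$max_test_pairs_per_bin` partners without replacement from each
#' similarity bin. Test and reference sets must be disjoint in structure
#' (no shared structure keys), otherwise an information-leakage error is
#' raised.
#'
#' @param test,reference Spectra tibbles with `spectrum_id` and
#'   `structure_key`.
#' @param sim_fun Function of two structure keys returning similarity in
#'   `[0, 1]` (vectorised over the second argument, or scalar).
#' @param cfg A [pair_sampling_config()]; its `seed` fixes the draw.
#' @return A tibble with `query_id`, `reference_id`, `label`.
#' @export
make_test_pairs <- function(test, reference, sim_fun,
                            cfg = pair_sampling_config()) {
  test <- as_ms2_spectra(test)
  reference <- as_ms2_spectra(reference)
  shared <- intersect(stats::na.omit(test$structure_key),
                      stats::na.omit(reference$structure_key))
  if (length(shared)) {
    abort(sprintf("information leakage: %d structure keys shared between test and reference sets",
                  length(shared)))
  }
  withr::with_seed(cfg$seed, {
    out <- vector("list", nrow(test))
    for (i in seq_len(nrow(test))) {
      s <- vapply(reference$structure_key,
                  function(k) sim_fun(test$structure_key[i], k), double(1))
      bins <- similarity_bin(s, cfg$n_bins)
      pick <- unlist(lapply(split(seq_along(s), bins), function(js) {
        if (length(js) <= cfg$max_test_pairs_per_bin) js
        else sample(js, cfg$max_test_pairs_per_bin)
      }), use.names = FALSE)
      if (length(pick)) {
        out[[i]] <- tibble::tibble(
          query_id = test$spectrum_id[i],
          reference_id = reference$spectrum_id[pick],
          label = unname(s[pick])
        )
      }
    }
    dplyr::bind_rows(out)
  })
}
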