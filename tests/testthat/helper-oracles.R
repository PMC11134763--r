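# Independent brute-force oracles and small fixture generators used
# across the test files. All oracles are deliberately written on a
# different representation (plain doubles, explicit loops) than the
# implementation they check.

random_peaks <- function(n, mz_range = c(20, 400)) {
  tibble::tibble(
    mz = sort(round(runif(n, mz_range[1], mz_range[2]), 2)),
    intensity = runif(n, 1, 100)
  )
}

random_spectrum <- function(n, precursor = NULL, mz_range = c(20, 400)) {
  pk <- random_peaks(n, mz_range)
  pk <- pk[!duplicated(pk$mz), ]
  list(peaks = pk,
       precursor_mz = precursor %||% round(max(pk$mz) + runif(1, 1, 60), 2))
}

spectra_tbl <- function(...) {
  specs <- list(...)
  as_ms2_spectra(tibble::tibble(
    spectrum_id = sprintf("S%02d", seq_along(specs)),
    precursor_mz = vapply(specs, function(s) s$precursor_mz %||% NA_real_, 1),
    peaks = lapply(specs, function(s) s$peaks)
  ))
}

# Greedy 3-Da window denoising, written as repeated extraction of the
# globally highest remaining peak and deletion of its neighbourhood.
oracle_window_denoise <- function(mz, intensity, window = 3) {
  keep_mz <- numeric(0); keep_int <- numeric(0)
  while (length(mz)) {
    top <- which(intensity == max(intensity))
    top <- top[which.min(mz[top])]
    keep_mz <- c(keep_mz, mz[top]); keep_int <- c(keep_int, intensity[top])
    far <- abs(mz - mz[top]) > window / 2
    mz <- mz[far]; intensity <- intensity[far]
  }
  o <- order(keep_mz)
  list(mz = keep_mz[o], intensity = keep_int[o])
}

# Triple-loop aligned-matrix builder on plain doubles.
oracle_aligned <- function(qmz, rmz, rint, cutoff = 300) {
  n <- length(qmz); m <- cutoff
  tokens <- matrix(100L, n + 1L, m)
  tokens[1L, ] <- 101L
  prov <- matrix(0L, n + 1L, m)
  for (i in seq_len(n)) {
    for (col in 0:(m - 1L)) {
      best <- 0L
      for (j in seq_along(rmz)) {
        d <- round(abs(qmz[i] - rmz[j]), 2)
        if (d >= cutoff) next
        if (floor(d + 1e-9) != col) next
        if (best == 0L ||
            rint[j] > rint[best] ||
            (rint[j] == rint[best] && rmz[j] < rmz[best])) {
          best <- j
        }
      }
      if (best > 0L) {
        d <- round(abs(qmz[i] - rmz[best]), 2)
        tokens[i + 1L, col + 1L] <- as.integer(round((d - floor(d + 1e-9)) * 100))
        prov[i + 1L, col + 1L] <- best
      }
    }
  }
  list(tokens = tokens, prov = prov)
}

# Exhaustive optimal-assignment cosine: maximises the matched
# intensity-product sum over all one-to-one assignments of admissible
# peak pairs (feasible only for tiny spectra).
oracle_cosine <- function(pa, pb, tol = 0.02, shift = NULL) {
  ok <- function(i, j) {
    d <- pa$mz[i] - pb$mz[j]
    abs(d) <= tol + 1e-9 || (!is.null(shift) && abs(d - shift) <= tol + 1e-9)
  }
  best <- 0
  rec <- function(i, used_b, acc) {
    if (i > nrow(pa)) { best <<- max(best, acc); return(invisible()) }
    rec(i + 1L, used_b, acc)
    for (j in seq_len(nrow(pb))) {
      if (!used_b[j] && ok(i, j)) {
        used_b[j] <- TRUE
        rec(i + 1L, used_b, acc + pa$intensity[i] * pb$intensity[j])
        used_b[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nrow(pb)), 0)
  best / (sqrt(sum(pa$intensity^2)) * sqrt(sum(pb$intensity^2)))
}

# Direct confusion-matrix precision/recall at a threshold.
oracle_pr <- function(score, label, cutoff, threshold) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(score)) {
    pos <- label[i] > cutoff
    pred <- score[i] >= threshold
    if (pred && pos) tp <- tp + 1L
    if (pred && !pos) fp <- fp + 1L
    if (!pred && pos) fn <- fn + 1L
  }
  c(precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn))
}

# Union-find connected components of an edge list.
oracle_components <- function(edges, nodes) {
  parent <- setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges$source[r]); b <- find(edges$target[r])
    if (a != b) parent[[a]] <- b
  }
  vapply(nodes, find, character(1))
}

# A tiny model configuration used wherever the full-size architecture
# would be wasteful (unit tests of mechanics, not of the default model).
tiny_config <- function(seed = 0L) {
  model_config(embed_dim = 4L, block_heads = c(10L, 5L), hidden_dim = 8L,
               tx_layers = 1L, tx_heads = 2L, tx_ffn_dim = 16L,
               n_columns = 20L, seed = seed)
}
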