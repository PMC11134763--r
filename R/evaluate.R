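## Evaluation battery: precision-recall at structural-similarity
## cut-offs, per-bin squared error, Pearson correlation; molecular
## network edge export.

#' Evaluate scored pairs against structural-similarity labels
#'
#' For each Tanimoto cut-off `c`, pairs with `label > c` are the
#' positives and the score threshold is swept over the sorted unique
#' scores, giving one precision/recall point per threshold (precision is
#' defined as 1 when nothing is predicted positive). Additionally
#' computes the squared-error distribution per equal-width label bin and
#' the Pearson correlation between scores and labels (0, with a warning,
#' when either side has zero variance).
#'
#' @param pairs Tibble with a score column (`score_col`) and a `label`
#'   column in `[0, 1]`.
#' @param cutoffs Structural-similarity cut-offs defining positives.
#' @param n_bins Number of equal-width label bins.
#' @param score_col Name of the score column (default `"y_sim"`).
#' @return An object of class `ms2sim_eval`: list with tibbles
#'   `pr_curves` (`cutoff`, `threshold`, `precision`, `recall`),
#'   `per_bin` (`bin`, `lower`, `upper`, `n`, `mse`, `se_q25`,
#'   `se_median`, `se_q75`; `mse` is `NA` for empty bins) and scalar
#'   `pearson_r`.
#' @export
evaluate_pairs <- function(pairs, cutoffs = c(0.6, 0.7, 0.8, 0.9),
                           n_bins = 10L, score_col = "y_sim") {
  pairs <- tibble::as_tibble(pairs)
  if (!nrow(pairs)) abort("no labelled pairs to evaluate")
  if (!score_col %in% names(pairs) || !"label" %in% names(pairs)) {
    abort(sprintf("pairs need '%s' and 'label' columns", score_col))
  }
  y <- pairs[[score_col]]
  t <- pairs$label
  if (anyNA(y) || anyNA(t)) abort("scores/labels contain NA")

  pr <- lapply(cutoffs, function(co) {
    pos <- t > co
    thr <- sort(unique(y))
    res <- lapply(thr, function(tt) {
      pred <- y >= tt
      tp <- sum(pred & pos)
      fp <- sum(pred & !pos)
      tibble::tibble(
        cutoff = co, threshold = tt,
        precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
        recall = if (sum(pos) == 0L) NA_real_ else tp / sum(pos)
      )
    })
    dplyr::bind_rows(res)
  })
  pr <- dplyr::bind_rows(pr)

  bins <- similarity_bin(t, n_bins)
  per_bin <- lapply(seq_len(n_bins), function(b) {
    se <- (y[bins == b] - t[bins == b])^2
    tibble::tibble(
      bin = b, lower = (b - 1) / n_bins, upper = b / n_bins,
      n = length(se),
      mse = if (length(se)) mean(se) else NA_real_,
      se_q25 = if (length(se)) unname(quantile(se, 0.25)) else NA_real_,
      se_median = if (length(se)) unname(quantile(se, 0.5)) else NA_real_,
      se_q75 = if (length(se)) unname(quantile(se, 0.75)) else NA_real_
    )
  })
  per_bin <- dplyr::bind_rows(per_bin)

  r <- if (stats::sd(y) == 0 || stats::sd(t) == 0) {
    warn("zero variance in scores or labels; Pearson r reported as 0")
    0
  } else {
    cor(y, t)
  }
  structure(list(pr_curves = pr, per_bin = per_bin, pearson_r = r,
                 n_pairs = nrow(pairs)),
            class = "ms2sim_eval")
}

#' @export
print.ms2sim_eval <- function(x, ...) {
  cat(sprintf("<ms2sim_eval> %d pairs, Pearson r = %.3f\n", x$n_pairs, x$pearson_r))
  occ <- x$per_bin[x$per_bin$n > 0L, ]
  cat(sprintf("  per-bin MSE over %d occupied bins: %.4f (max %.4f)\n",
              nrow(occ), mean(occ$mse), max(occ$mse)))
  invisible(x)
}

#' Molecular-network edges from pairwise similarity scores
#'
#' Builds the edge list of a molecular network: scores are symmetrised
#' (mean of both orientations when both are present), edges at or below
#' `threshold` are removed, each node keeps at most its `top_k` strongest
#' edges (an edge survives only if it is in the top-k of both
#' endpoints), and connected components larger than `max_family_size`
#' are split by repeatedly removing their weakest edge. Deterministic:
#' ties are broken lexicographically on the (sorted) endpoint ids.
#'
#' @param scores Tibble with `source`, `target`, `score` (or a symmetric
#'   score matrix with dimnames).
#' @param threshold Minimum (exclusive) score for an edge.
#' @param top_k Maximum retained edges per node.
#' @param max_family_size Maximum connected-component size.
#' @return A tibble `source`, `target`, `score` with `source < target`.
#' @export
network_edges <- function(scores, threshold = 0.6, top_k = 10L,
                          max_family_size = 100L) {
  if (is.matrix(scores)) {
    stopifnot(!is.null(rownames(scores)))
    idx <- which(upper.tri(scores), arr.ind = TRUE)
    sym <- (scores[idx] + t(scores)[idx]) / 2
    scores <- tibble::tibble(source = rownames(scores)[idx[, 1L]],
                             target = colnames(scores)[idx[, 2L]],
                             score = sym)
  }
  scores <- tibble::as_tibble(scores)
  stopifnot(all(c("source", "target", "score") %in% names(scores)))
  ## canonical orientation + symmetrisation by averaging duplicates
  a <- pmin(scores$source, scores$target)
  b <- pmax(scores$source, scores$target)
  keep <- a != b
  ed <- tibble::tibble(source = a[keep], target = b[keep],
                       score = scores$score[keep])
  ed <- dplyr::summarise(dplyr::group_by(ed, .data$source, .data$target),
                         score = mean(.data$score), .groups = "drop")
  ed <- ed[ed$score > threshold, ]
  ed <- ed[order(-ed$score, ed$source, ed$target), ]
  if (!nrow(ed)) return(ed)
  ## top-k per node: keep an edge only if it ranks within top_k for both
  nodes <- c(ed$source, ed$target)
  keep_tab <- tapply(rep(seq_len(nrow(ed)), 2L), nodes, function(is) is[seq_len(min(top_k, length(is)))])
  cnt <- table(unlist(keep_tab))
  keep_edge <- as.integer(names(cnt)[cnt == 2L])
  ed <- ed[sort(keep_edge), ]
  ## split oversized families by removing weakest edges
  repeat {
    if (!nrow(ed)) break
    g <- igraph::graph_from_data_frame(ed[, c("source", "target")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    big <- which(comp$csize > max_family_size)
    if (!length(big)) break
    victims <- names(comp$membership)[comp$membership == big[1L]]
    in_big <- ed$source %in% victims & ed$target %in% victims
    cand <- which(in_big)
    drop <- cand[order(ed$score[cand], -xtfrm(ed$source[cand]),
                       -xtfrm(ed$target[cand]))][1L]
    ed <- ed[-drop, ]
  }
  ed
}
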