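## Post-hoc explanation: propagate relevance from the predicted score
## back to (query fragment, reference fragment) pairs.
##
## The rule is gradient-weighted attention relevance in the
## transformer-LRP style: per encoder layer the head-averaged,
## positively clamped elementwise product of the attention map and its
## gradient (plus identity for the residual path, rows renormalised) is
## composed across layers; the CLS row of the composition distributes the
## tower's relevance over the data rows. Each data row's relevance is
## then spread over its non-PAD aligned-matrix cells proportionally to
## the input-gradient magnitude at that cell and mapped to the reference
## fragment recorded in the cell's provenance. Fragment-tower cells map
## directly to fragment pairs; loss-tower cells map through the
## loss-to-fragment correspondence of both spectra. The final relevance
## matrix is the sum of the two tower contributions, weighted by each
## tower's share of the fusion head's positive input-gradient mass.

#' Fragment-pair relevance for a predicted similarity
#'
#' @param model A trained `ms2sim_model`.
#' @param pair A full [encode_pair()] encoding (with provenance).
#' @return An object of class `relevance_matrix`: list with `scores`
#'   (s_q x s_r, nonnegative), `query_mz`, `reference_mz`, per-tower
#'   components `fragment` and `loss`, and the predicted score `y_sim`.
#' @export
relevance <- function(model, pair) {
  stopifnot(inherits(model, "ms2sim_model"), inherits(pair, "pair_encoding"))
  tape <- ad_tape()
  fw <- model_forward(tape, model, list(pair), train = FALSE, keep_attn = TRUE)
  y_sim <- as.vector(fw$pred$value)
  ## keep what the propagation below reads back after the sweep
  for (nd in list(fw$frag$cls, fw$loss$cls)) nd$retain <- TRUE
  ad_backward(tape, fw$pred, matrix(1, 1L, 1L))

  ## tower shares from grad x input on the two CLS embeddings
  share <- vapply(list(fw$frag$cls, fw$loss$cls), function(nd) {
    sum(pmax(nd$grad * nd$value, 0))
  }, double(1))
  if (sum(share) <= 0) share <- c(0.5, 0.5) else share <- share / sum(share)

  sq <- length(pair$query_mz)
  sr <- length(pair$reference_mz)
  out <- matrix(0, sq, sr)
  comp <- list()
  for (w in c("fragment", "loss")) {
    tower <- if (w == "fragment") fw$frag else fw$loss
    al <- pair[[w]]
    n_rows <- nrow(al$tokens)
    rowrel <- attention_rollout(tower$attn, n_rows)
    cellrel <- distribute_row_relevance(rowrel, tower$embedded$cell_grad_norm, al)
    M <- matrix(0, sq, sr)
    if (w == "fragment") {
      qmap <- seq_len(sq)
      rmap <- seq_len(sr)
    } else {
      qmap <- pair$query_loss_map
      rmap <- pair$reference_loss_map
    }
    nz <- which(cellrel$prov > 0L, arr.ind = TRUE)
    for (k in seq_len(nrow(nz))) {
      i <- qmap[nz[k, 1L]]
      j <- rmap[cellrel$prov[nz[k, 1L], nz[k, 2L]]]
      M[i, j] <- M[i, j] + cellrel$rel[nz[k, 1L], nz[k, 2L]]
    }
    tw_share <- share[if (w == "fragment") 1L else 2L]
    s <- sum(M)
    if (s > 0) M <- M / s * tw_share
    comp[[w]] <- M
    out <- out + M
  }
  structure(list(scores = out, query_mz = pair$query_mz,
                 reference_mz = pair$reference_mz,
                 fragment = comp$fragment, loss = comp$loss,
                 y_sim = y_sim), class = "relevance_matrix")
}

## Compose gradient-weighted attention maps across layers and return the
## relevance of each data row seen from the CLS row (vector over data
## rows, CLS entry dropped).
attention_rollout <- function(attn_nodes, n_rows) {
  C <- diag(n_rows)
  for (nd in attn_nodes) {
    A <- nd$attn[[1L]]          # heads x L x L
    G <- nd$attn_grad[[1L]]
    Abar <- apply(pmax(A * G, 0), c(2L, 3L), mean)
    Abar <- Abar + diag(n_rows)
    rs <- rowSums(Abar)
    Abar <- Abar / ifelse(rs > 0, rs, 1)
    C <- Abar %*% C
  }
  r <- C[1L, -1L]
  pmax(r, 0)
}

## Spread each data row's relevance over its non-PAD cells, weighting by
## the L2 norm of the output gradient at that cell's embedded input
## (recorded by the fused embedding block during the backward sweep).
distribute_row_relevance <- function(rowrel, cell_grad_norm, aligned) {
  n_data <- nrow(aligned$tokens) - 1L
  m <- ncol(aligned$tokens)
  rel <- matrix(0, n_data, m)
  prov <- aligned$provenance[-1L, , drop = FALSE]
  cellmag <- cell_grad_norm[-1L, , drop = FALSE]   # drop CLS row
  for (i in seq_len(n_data)) {
    cells <- which(prov[i, ] > 0L)
    if (!length(cells)) next
    wts <- cellmag[i, cells]
    if (sum(wts) <= 0) wts <- rep(1, length(cells))
    rel[i, cells] <- rowrel[i] * wts / sum(wts)
  }
  list(rel = rel, prov = prov)
}

#' Top query-reference fragment associations
#'
#' Ranks query fragments by their total relevance (row sums; ties broken
#' towards the higher m/z), keeps the top `q`, and reports for each the
#' `k` most relevant reference fragments (ties towards the smaller
#' absolute mass shift, then the smaller reference m/z) together with
#' the signed mass shift `reference_mz - query_mz`.
#'
#' @param rel A [relevance()] result.
#' @param q Maximum number of query fragments reported.
#' @param k Associations per query fragment.
#' @return An object of class `ms2sim_explanation`: a tibble with
#'   columns `rank`, `query_mz`, `assoc_rank`, `reference_mz`, `shift`,
#'   `relevance`.
#' @export
top_associations <- function(rel, q = 20L, k = 3L) {
  stopifnot(inherits(rel, "relevance_matrix"))
  rs <- rowSums(rel$scores)
  ord <- order(-rs, -rel$query_mz)
  ord <- ord[seq_len(min(q, length(ord)))]
  rows <- lapply(seq_along(ord), function(rk) {
    i <- ord[rk]
    shift <- round(rel$reference_mz - rel$query_mz[i], 2)
    jord <- order(-rel$scores[i, ], abs(shift), rel$reference_mz)
    jord <- jord[seq_len(min(k, length(jord)))]
    tibble::tibble(
      rank = rk, query_mz = rel$query_mz[i],
      assoc_rank = seq_along(jord),
      reference_mz = rel$reference_mz[jord],
      shift = shift[jord],
      relevance = rel$scores[i, jord]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ms2sim_explanation", class(out))
  out
}

#' Write an explanation report: heatmap image + TSV twin
#'
#' @param report A [top_associations()] result (non-empty).
#' @param image_path Output image path (png).
#' @param tsv_path Output TSV path; defaults to `image_path` with a
#'   `.tsv` extension.
#' @param ... Passed to [ggplot2::ggsave()].
#' @return Invisibly, a list with both paths.
#' @export
render_heatmap <- function(report, image_path, tsv_path = NULL, ...) {
  stopifnot(inherits(report, "ms2sim_explanation"))
  if (!nrow(report)) abort("empty explanation report")
  if (is.null(tsv_path)) tsv_path <- sub("\\.[A-Za-z]+$", ".tsv", image_path)
  df <- as.data.frame(report)
  df$relevance <- round(df$relevance, 6)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- autoplot.ms2sim_explanation(report)
  ggplot2::ggsave(image_path, p, width = 7, height = 5, dpi = 150, ...)
  invisible(list(image = image_path, tsv = tsv_path))
}
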