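## broom-style tidiers.

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted similarity model's training history
#'
#' @param x A trained `ms2sim_model`.
#' @param ... Ignored.
#' @return A tibble with one row per epoch.
#' @method tidy ms2sim_model
#' @export
tidy.ms2sim_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), train_mse = double(),
                          val_mse = double(), seconds = double()))
  }
  x$history
}

#' One-row model summary
#'
#' @param x A `ms2sim_model`.
#' @param ... Ignored.
#' @return A tibble with parameter count, configuration highlights and
#'   (if trained) the best validation MSE.
#' @method glance ms2sim_model
#' @export
glance.ms2sim_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(vapply(x$params, length, double(1))),
    hidden_dim = x$config$hidden_dim,
    tx_layers = x$config$tx_layers,
    trained = isTRUE(x$trained),
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    best_val_mse = if (is.null(x$history) || all(is.na(x$history$val_mse)))
      NA_real_ else min(x$history$val_mse, na.rm = TRUE)
  )
}

#' Tidy an evaluation: one row per PR point
#'
#' @param x An [evaluate_pairs()] result.
#' @param ... Ignored.
#' @method tidy ms2sim_eval
#' @export
tidy.ms2sim_eval <- function(x, ...) x$pr_curves

#' One-row evaluation summary
#'
#' @param x An [evaluate_pairs()] result.
#' @param ... Ignored.
#' @method glance ms2sim_eval
#' @export
glance.ms2sim_eval <- function(x, ...) {
  occ <- x$per_bin[x$per_bin$n > 0L, ]
  tibble::tibble(
    n_pairs = x$n_pairs,
    pearson_r = x$pearson_r,
    mean_bin_mse = mean(occ$mse),
    max_bin_mse = max(occ$mse),
    occupied_bins = nrow(occ)
  )
}

#' Tidy a relevance matrix into long format
#'
#' @param x A [relevance()] result.
#' @param ... Ignored.
#' @return A tibble `query_mz`, `reference_mz`, `shift`, `relevance`.
#' @method tidy relevance_matrix
#' @export
tidy.relevance_matrix <- function(x, ...) {
  idx <- expand.grid(i = seq_along(x$query_mz), j = seq_along(x$reference_mz))
  tibble::tibble(
    query_mz = x$query_mz[idx$i],
    reference_mz = x$reference_mz[idx$j],
    shift = round(x$reference_mz[idx$j] - x$query_mz[idx$i], 2),
    relevance = x$scores[cbind(idx$i, idx$j)]
  )
}

#' @export
print.relevance_matrix <- function(x, ...) {
  cat(sprintf("<relevance_matrix> %d query x %d reference fragments, y_sim = %.3f\n",
              length(x$query_mz), length(x$reference_mz), x$y_sim))
  invisible(x)
}
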