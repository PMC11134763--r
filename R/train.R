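## Structure-supervised training of the similarity model.

#' Training configuration
#'
#' Optimiser and schedule settings. The defaults follow the reference
#' configuration (Adam with learning rate 1e-4, no weight decay, batch
#' size 64); epoch count and early-stopping patience are this package's
#' own defaults.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay Decoupled weight decay (0 disables).
#' @param batch_size Pairs per gradient step.
#' @param max_epochs Maximum training epochs.
#' @param patience Early stopping: stop after this many epochs without
#'   validation-MSE improvement. `Inf` disables early stopping.
#' @param seed Integer; seeds epoch pair resampling and dropout.
#' @param symmetrize Also use every sampled pair with roles swapped.
#' @param validate_every Evaluate the validation MSE every this many
#'   epochs (patience counts validation evaluations).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 0,
                         batch_size = 64L, max_epochs = 100L, patience = 10L,
                         seed = 0L, symmetrize = FALSE, validate_every = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1L, validate_every >= 1L)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = patience,
                 seed = as.integer(seed), symmetrize = isTRUE(symmetrize),
                 validate_every = as.integer(validate_every)),
            class = "train_config")
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, wd = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    upd <- (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
    if (wd > 0) upd <- upd + wd * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = st)
}

## Encoding cache: pair encodings keyed by "query_id|reference_id".
## Spectra must carry unique ids; lookup tables are built once.
encode_pairs_cached <- function(pairs_tbl, spectra, cache, cutoff) {
  recs <- lapply(seq_len(nrow(pairs_tbl)), function(r) {
    key <- paste0(pairs_tbl$query_id[r], "\r", pairs_tbl$reference_id[r])
    enc <- cache[[key]]
    if (is.null(enc)) {
      qi <- match(pairs_tbl$query_id[r], spectra$spectrum_id)
      ri <- match(pairs_tbl$reference_id[r], spectra$spectrum_id)
      enc <- encode_pair(spectra[qi, ], spectra[ri, ], cutoff = cutoff)
      ## keep only what the forward pass needs; provenance etc. stays out
      enc <- list(fragment = list(tokens = enc$fragment$tokens),
                  loss = list(tokens = enc$loss$tokens))
      cache[[key]] <- enc
    }
    enc
  })
  recs
}

#' Train the similarity model
#'
#' Supervised training against structural-similarity labels. Each epoch
#' resamples a balanced pair set ([sample_epoch_pairs()], seeded by
#' `train_cfg$seed + epoch`), minimises the mean squared error between
#' the predicted score and the label with Adam, and evaluates the MSE on
#' a fixed validation pair set. The parameters with the best validation
#' MSE are returned. Training aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param model An [init_model()] result.
#' @param spectra Preprocessed spectra tibble (training spectra only),
#'   with `structure_key` set.
#' @param sim Structural-similarity matrix over `spectra` rows (e.g.
#'   [tanimoto_matrix()] entries matched to spectra, or
#'   [similarity_matrix()] for synthetic libraries).
#' @param train_cfg A [train_config()].
#' @param sampling_cfg A [pair_sampling_config()].
#' @param validation Optional tibble of fixed validation pairs with
#'   columns `query_id`, `reference_id`, `label`; query spectra must be
#'   supplied in `validation_spectra`.
#' @param validation_spectra Spectra tibble covering all ids used in
#'   `validation` (may include the training spectra).
#' @param verbose Print per-epoch progress.
#' @return The input model with trained parameters and a `history`
#'   tibble (`epoch`, `train_mse`, `val_mse`, `seconds`).
#' @export
train_similarity_model <- function(model, spectra, sim,
                                   train_cfg = train_config(),
                                   sampling_cfg = pair_sampling_config(),
                                   validation = NULL,
                                   validation_spectra = NULL,
                                   verbose = FALSE) {
  stopifnot(inherits(model, "ms2sim_model"))
  spectra <- as_ms2_spectra(spectra)
  cfg <- model$config
  params <- model$params
  st <- adam_state(params)
  cache <- new.env(parent = emptyenv())
  if (!is.null(validation)) {
    if (is.null(validation_spectra)) abort("validation pairs need validation_spectra")
    validation_spectra <- as_ms2_spectra(validation_spectra)
    ## leakage guard: validation query structures must not be trained on
    vq <- validation_spectra$structure_key[
      match(unique(validation$query_id), validation_spectra$spectrum_id)]
    shared <- intersect(stats::na.omit(vq), stats::na.omit(spectra$structure_key))
    if (length(shared)) {
      abort(sprintf("information leakage: %d validation structures present in training set",
                    length(shared)))
    }
    all_val_spectra <- dplyr::bind_rows(
      validation_spectra,
      spectra[!spectra$spectrum_id %in% validation_spectra$spectrum_id, ]
    )
    val_enc <- encode_pairs_cached(validation, all_val_spectra,
                                   new.env(parent = emptyenv()), cfg$n_columns)
  }
  history <- vector("list", train_cfg$max_epochs)
  best <- list(val = Inf, params = params, epoch = 0L)
  stall <- 0L
  for (epoch in seq_len(train_cfg$max_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    pairs_tbl <- sample_epoch_pairs(spectra$spectrum_id, sim, sampling_cfg,
                                    epoch_seed = train_cfg$seed + epoch)
    if (train_cfg$symmetrize) {
      pairs_tbl <- dplyr::bind_rows(
        pairs_tbl,
        dplyr::rename(pairs_tbl, query_id = "reference_id", reference_id = "query_id"))
    }
    enc <- encode_pairs_cached(pairs_tbl, spectra, cache, cfg$n_columns)
    n <- nrow(pairs_tbl)
    epoch_loss <- 0
    withr::with_seed(train_cfg$seed * 10000L + epoch, {
      ord <- sample.int(n)
      nb <- 0L
      batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
      for (bi in batches) {
        tape <- ad_tape()
        mdl <- list(config = cfg, params = params)
        fw <- model_forward(tape, mdl, enc[bi], train = TRUE)
        y <- pairs_tbl$label[bi]
        resid <- as.vector(fw$pred$value) - y
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          abort(sprintf("non-finite training loss at epoch %d (batch of %d)",
                        epoch, length(bi)))
        }
        epoch_loss <- epoch_loss + loss * length(bi)
        ad_backward(tape, fw$pred, matrix(2 * resid / length(bi), ncol = 1L))
        grads <- lapply(fw$params, function(nd) nd$grad)
        stp <- adam_step(params, grads, st, train_cfg$learning_rate,
                         train_cfg$weight_decay)
        params <- stp$params
        st <- stp$state
        nb <- nb + 1L
        if (nb %% 4L == 0L) gc(FALSE)
      }
    })
    train_mse <- epoch_loss / n
    val_mse <- NA_real_
    if (!is.null(validation) && epoch %% train_cfg$validate_every == 0L) {
      mdl <- list(config = cfg, params = params)
      class(mdl) <- "ms2sim_model"
      pv <- predict_encoded(mdl, val_enc)
      val_mse <- mean((pv - validation$label)^2)
      if (val_mse < best$val - 1e-6) {
        best <- list(val = val_mse, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
    }
    secs <- proc.time()[["elapsed"]] - t0
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_mse = train_mse,
                                       val_mse = val_mse, seconds = secs)
    if (verbose) {
      message(sprintf("epoch %3d  train MSE %.4f  val MSE %s  (%.1fs, %d pairs)",
                      epoch, train_mse,
                      ifelse(is.na(val_mse), "-", sprintf("%.4f", val_mse)), secs, n))
    }
    if (!is.null(validation) && is.finite(train_cfg$patience) &&
        stall >= train_cfg$patience) break
  }
  out <- model
  out$params <- if (!is.null(validation)) best$params else params
  out$history <- dplyr::bind_rows(history[!vapply(history, is.null, logical(1))])
  out$best_epoch <- if (!is.null(validation)) best$epoch else nrow(out$history)
  out$trained <- TRUE
  out
}

## Forward-only scoring of pre-encoded pairs.
predict_encoded <- function(model, enc, batch_size = 64L) {
  out <- numeric(length(enc))
  idx <- split(seq_along(enc), ceiling(seq_along(enc) / batch_size))
  done <- 0L
  for (ii in idx) {
    tape <- ad_tape()
    fw <- model_forward(tape, model, enc[ii], train = FALSE)
    out[ii] <- as.vector(fw$pred$value)
    rm(tape, fw)
    done <- done + 1L
    if (done %% 8L == 0L) gc(FALSE)
  }
  out
}
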