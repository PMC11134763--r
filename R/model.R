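## The two-tower transformer similarity model.
##
## Each tower (fragment, neutral loss) maps an aligned token matrix to a
## single embedding: a row encoder (token embedding -> flatten -> stack of
## head-split blocks -> linear projection) applied identically to every
## row, followed by a standard post-norm transformer encoder over the rows
## (no positional encoding; rows are an unordered set of fragments). The
## CLS-row output of each tower is retained, the two embeddings are
## concatenated and a small fully connected head with a sigmoid produces
## the similarity score in [0, 1].

#' Model configuration
#'
#' Hyper-parameters of the similarity model. The defaults are the
#' reference configuration: a 32-dimensional mass-defect embedding, two
#' row-encoder blocks with 100 and 20 heads, hidden dimension 128,
#' dropout 0.1 everywhere, and a 2-layer transformer encoder with 4
#' attention heads and a 256-unit feed-forward inner layer.
#'
#' @param embed_dim Mass-defect embedding dimension.
#' @param block_heads Integer vector: number of heads per row-encoder
#'   block (one entry per block).
#' @param hidden_dim Output width of each block's shared affine map and
#'   of the row embedding.
#' @param row_dropout Dropout rate inside row-encoder blocks.
#' @param tx_layers,tx_heads,tx_ffn_dim,tx_dropout Transformer encoder
#'   depth, attention heads, feed-forward inner width and dropout.
#' @param n_columns Number of nominal-mass columns (aligned-matrix width).
#' @param seed Integer seed for deterministic parameter initialisation.
#' @return A `model_config` list.
#' @export
model_config <- function(embed_dim = 32L, block_heads = c(100L, 20L),
                         hidden_dim = 128L, row_dropout = 0.1,
                         tx_layers = 2L, tx_heads = 4L, tx_ffn_dim = 256L,
                         tx_dropout = 0.1, n_columns = 300L, seed = 0L) {
  cfg <- list(
    embed_dim = as.integer(embed_dim),
    block_heads = as.integer(block_heads),
    hidden_dim = as.integer(hidden_dim),
    row_dropout = row_dropout,
    tx_layers = as.integer(tx_layers),
    tx_heads = as.integer(tx_heads),
    tx_ffn_dim = as.integer(tx_ffn_dim),
    tx_dropout = tx_dropout,
    n_columns = as.integer(n_columns),
    vocab_size = 102L,          # 0-99 mass defects, 100 PAD, 101 CLS
    activation = "relu",
    seed = as.integer(seed)
  )
  width <- cfg$n_columns * cfg$embed_dim
  units <- cfg$n_columns          # independent sub-vectors making up a row
  for (i in seq_along(cfg$block_heads)) {
    k <- cfg$block_heads[i]
    if (width %% k != 0L) {
      abort(sprintf("row width %d is not divisible by block %d head count %d",
                    width, i, k))
    }
    if (units %% k != 0L) {
      abort(sprintf("block %d head count %d does not evenly tile the %d input units",
                    i, k, units))
    }
    width <- k * cfg$hidden_dim
    units <- k
  }
  if (cfg$hidden_dim %% cfg$tx_heads != 0L) {
    abort(sprintf("hidden dimension %d is not divisible by %d attention heads",
                  cfg$hidden_dim, cfg$tx_heads))
  }
  structure(cfg, class = "model_config")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

tower_param_spec <- function(cfg, prefix) {
  p <- list()
  p[[paste0(prefix, ".emb")]] <- function() matrix(rnorm(cfg$vocab_size * cfg$embed_dim, sd = 0.1),
                                                   cfg$vocab_size, cfg$embed_dim)
  width <- cfg$n_columns * cfg$embed_dim
  for (i in seq_along(cfg$block_heads)) {
    k <- cfg$block_heads[i]
    hd <- width %/% k
    p[[sprintf("%s.block%d.W", prefix, i)]] <- local({
      hd0 <- hd
      function() glorot(hd0, cfg$hidden_dim)
    })
    p[[sprintf("%s.block%d.b", prefix, i)]] <- function() numeric(cfg$hidden_dim)
    width <- k * cfg$hidden_dim
  }
  p[[paste0(prefix, ".proj.W")]] <- local({
    w0 <- width
    function() glorot(w0, cfg$hidden_dim)
  })
  p[[paste0(prefix, ".proj.b")]] <- function() numeric(cfg$hidden_dim)
  d <- cfg$hidden_dim
  for (l in seq_len(cfg$tx_layers)) {
    base <- sprintf("%s.tx%d.", prefix, l)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      p[[paste0(base, nm)]] <- function() glorot(d, d)
    }
    for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(base, nm)]] <- function() numeric(d)
    p[[paste0(base, "ln1.g")]] <- function() rep(1, d)
    p[[paste0(base, "ln1.b")]] <- function() numeric(d)
    p[[paste0(base, "ffn.W1")]] <- function() glorot(d, cfg$tx_ffn_dim)
    p[[paste0(base, "ffn.b1")]] <- function() numeric(cfg$tx_ffn_dim)
    p[[paste0(base, "ffn.W2")]] <- function() glorot(cfg$tx_ffn_dim, d)
    p[[paste0(base, "ffn.b2")]] <- function() numeric(d)
    p[[paste0(base, "ln2.g")]] <- function() rep(1, d)
    p[[paste0(base, "ln2.b")]] <- function() numeric(d)
  }
  p
}

#' Initialise a similarity model
#'
#' Creates the two tower encoders and the fusion head with parameters
#' drawn deterministically from `config$seed` (Glorot-uniform affine
#' maps, Gaussian token embeddings, unit layer-norm gains).
#'
#' @param config A [model_config()].
#' @return An object of class `ms2sim_model` holding the configuration
#'   and a named list of parameter matrices.
#' @export
init_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  spec <- c(tower_param_spec(config, "frag"), tower_param_spec(config, "loss"))
  d <- config$hidden_dim
  spec[["fusion.W1"]] <- function() glorot(2L * d, d)
  spec[["fusion.b1"]] <- function() numeric(d)
  spec[["fusion.W2"]] <- function() glorot(d, 1L)
  spec[["fusion.b2"]] <- function() numeric(1L)
  params <- withr::with_seed(config$seed, lapply(spec, function(f) f()))
  structure(list(config = config, params = params), class = "ms2sim_model")
}

#' @export
print.ms2sim_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, double(1)))
  cat(sprintf("<ms2sim_model> two-tower transformer, %s parameters (seed %d)\n",
              format(np, big.mark = ","), x$config$seed))
  invisible(x)
}

## ---- forward pass -------------------------------------------------------

## Stack the token matrices of one tower for a list of pair encodings.
## Returns ids ((sum lens) x n_columns), lens, and the CLS row index of
## every sequence in the stack.
stack_tower <- function(pairs, which) {
  mats <- lapply(pairs, function(p) p[[which]]$tokens)
  lens <- vapply(mats, nrow, integer(1))
  ids <- do.call(rbind, mats)
  list(ids = ids, lens = lens, cls = c(0L, cumsum(lens))[seq_along(lens)] + 1L)
}

## Forward through one tower; returns list(cls = node (B x d), extras).
tower_forward <- function(tape, pars, cfg, prefix, stacked, train,
                          keep_attn = FALSE) {
  P <- function(nm) pars[[paste0(prefix, ".", nm)]]
  R <- nrow(stacked$ids)
  x <- ad_embed_block(tape, P("emb"), P("block1.W"), P("block1.b"),
                      stacked$ids, drop_p = cfg$row_dropout, train = train,
                      keep_input_grad = keep_attn)
  embedded <- x
  units <- cfg$block_heads[1L]
  for (i in seq_along(cfg$block_heads)[-1L]) {
    k <- cfg$block_heads[i]
    x <- ad_unit_block(tape, x, P(sprintf("block%d.W", i)),
                       P(sprintf("block%d.b", i)), R = R, g = units %/% k,
                       drop_p = cfg$row_dropout, train = train, relu = TRUE)
    units <- k
  }
  x <- ad_unit_block(tape, x, P("proj.W"), P("proj.b"), R = R, g = units,
                     drop_p = 0, train = train, relu = FALSE)
  blk <- mha_block_info(stacked$lens)
  attn_nodes <- vector("list", cfg$tx_layers)
  for (l in seq_len(cfg$tx_layers)) {
    base <- sprintf("tx%d.", l)
    h <- ad_mha(tape, x,
                P(paste0(base, "Wq")), P(paste0(base, "bq")),
                P(paste0(base, "Wk")), P(paste0(base, "bk")),
                P(paste0(base, "Wv")), P(paste0(base, "bv")),
                P(paste0(base, "Wo")), P(paste0(base, "bo")),
                blk = blk, n_heads = cfg$tx_heads,
                p_drop = cfg$tx_dropout, train = train,
                keep_attn = keep_attn)
    attn_nodes[[l]] <- h
    x <- ad_layernorm(tape, ad_add(tape, x, ad_dropout(tape, h, cfg$tx_dropout, train)),
                      P(paste0(base, "ln1.g")), P(paste0(base, "ln1.b")))
    f <- ad_add_bias(tape, ad_mm(tape, x, P(paste0(base, "ffn.W1"))),
                     P(paste0(base, "ffn.b1")))
    f <- ad_relu(tape, f)
    f <- ad_add_bias(tape, ad_mm(tape, f, P(paste0(base, "ffn.W2"))),
                     P(paste0(base, "ffn.b2")))
    x <- ad_layernorm(tape, ad_add(tape, x, ad_dropout(tape, f, cfg$tx_dropout, train)),
                      P(paste0(base, "ln2.g")), P(paste0(base, "ln2.b")))
  }
  list(cls = ad_rows(tape, x, stacked$cls), embedded = embedded,
       attn = attn_nodes)
}

## Full forward for a list of pair encodings. Returns the prediction node
## (B x 1) plus everything the explanation pass needs.
model_forward <- function(tape, model, pairs, train = FALSE, keep_attn = FALSE) {
  cfg <- model$config
  pars <- lapply(model$params, function(v) ad_leaf(tape, v))
  frag_in <- stack_tower(pairs, "fragment")
  loss_in <- stack_tower(pairs, "loss")
  tf <- tower_forward(tape, pars, cfg, "frag", frag_in, train, keep_attn)
  tl <- tower_forward(tape, pars, cfg, "loss", loss_in, train, keep_attn)
  z <- ad_cbind(tape, tf$cls, tl$cls)
  z <- ad_add_bias(tape, ad_mm(tape, z, pars[["fusion.W1"]]), pars[["fusion.b1"]])
  z <- ad_relu(tape, z)
  z <- ad_dropout(tape, z, cfg$tx_dropout, train)
  pred <- ad_sigmoid(tape, ad_add_bias(tape, ad_mm(tape, z, pars[["fusion.W2"]]),
                                       pars[["fusion.b2"]]))
  list(pred = pred, params = pars, frag = tf, loss = tl,
       frag_in = frag_in, loss_in = loss_in)
}

#' Row encoder output
#'
#' Applies one tower's row encoder (embedding, head-split blocks and the
#' final projection, without the transformer encoder) to an aligned
#' matrix, mapping each row independently to a `hidden_dim`-dimensional
#' embedding. Mainly useful for inspection and testing; dropout is off.
#'
#' @param model A [init_model()] result.
#' @param aligned An [aligned_matrix()].
#' @param tower `"frag"` or `"loss"`.
#' @return A numeric matrix with one row per aligned-matrix row.
#' @export
row_encode <- function(model, aligned, tower = c("frag", "loss")) {
  tower <- match.arg(tower)
  stopifnot(inherits(model, "ms2sim_model"), inherits(aligned, "aligned_matrix"))
  cfg <- model$config
  if (any(aligned$tokens < 0L | aligned$tokens >= cfg$vocab_size)) {
    abort("token outside vocabulary")
  }
  tape <- ad_tape()
  pars <- lapply(model$params, function(v) ad_leaf(tape, v))
  P <- function(nm) pars[[paste0(tower, ".", nm)]]
  R <- nrow(aligned$tokens)
  x <- ad_embed_block(tape, P("emb"), P("block1.W"), P("block1.b"),
                      aligned$tokens, drop_p = 0, train = FALSE)
  units <- cfg$block_heads[1L]
  for (i in seq_along(cfg$block_heads)[-1L]) {
    k <- cfg$block_heads[i]
    x <- ad_unit_block(tape, x, P(sprintf("block%d.W", i)),
                       P(sprintf("block%d.b", i)), R = R, g = units %/% k,
                       drop_p = 0, train = FALSE, relu = TRUE)
    units <- k
  }
  x <- ad_unit_block(tape, x, P("proj.W"), P("proj.b"), R = R, g = units,
                     drop_p = 0, train = FALSE, relu = FALSE)
  x$value
}

#' Predict spectral similarity for encoded pairs
#'
#' Runs the model in evaluation mode (dropout off). Scores are
#' deterministic for fixed parameters and invariant to the order of peaks
#' within each spectrum.
#'
#' @param model A (possibly trained) `ms2sim_model`.
#' @param pairs A single `pair_encoding` or a list of them.
#' @param batch_size Number of pairs per forward batch (kept moderate
#'   so the stacked row-encoder intermediates stay memory-friendly).
#' @return A numeric vector of similarity scores in `[0, 1]`.
#' @export
predict_similarity <- function(model, pairs, batch_size = 64L) {
  stopifnot(inherits(model, "ms2sim_model"))
  if (inherits(pairs, "pair_encoding")) pairs <- list(pairs)
  check_tokens(model, pairs)
  out <- numeric(length(pairs))
  idx <- split(seq_along(pairs), ceiling(seq_along(pairs) / batch_size))
  for (ii in idx) {
    tape <- ad_tape()
    fw <- model_forward(tape, model, pairs[ii], train = FALSE)
    out[ii] <- as.vector(fw$pred$value)
    rm(tape, fw)
    gc(FALSE)
  }
  out
}

check_tokens <- function(model, pairs) {
  V <- model$config$vocab_size
  m <- model$config$n_columns
  for (p in pairs) {
    for (w in c("fragment", "loss")) {
      tk <- p[[w]]$tokens
      if (ncol(tk) != m) abort(sprintf("aligned matrix has %d columns, model expects %d",
                                       ncol(tk), m))
      if (any(tk < 0L | tk >= V)) abort("token outside vocabulary")
    }
  }
  invisible(TRUE)
}
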