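## Minimal reverse-mode automatic differentiation on dense matrices.
##
## A tape records nodes (environments holding a value, a gradient slot and
## a backward closure) in execution order; ad_backward() walks it in
## reverse. Operations are matrix-level so almost all arithmetic lands in
## BLAS. Only what the similarity model needs is implemented.

## N identical rows of v, built through BLAS (much faster than rep()).
const_rows <- function(v, N) tcrossprod(rep(1, N), v)

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

## Leaf holding a parameter (or constant); gradients accumulate in $grad.
ad_leaf <- function(tape, value) ad_node(tape, value)

## Reverse sweep. Nodes are processed children-first, so once a node's
## backward has run nothing downstream needs its value, gradient or
## closure any more; they are released immediately (set nd$retain to
## keep a node's slots, e.g. for post-hoc inspection of input
## gradients).
ad_backward <- function(tape, node, seed) {
  node$grad <- seed
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backward)) {
      if (!is.null(nd$grad)) nd$backward(nd)
      if (!isTRUE(nd$retain)) {
        nd$value <- NULL
        nd$grad <- NULL
      }
      nd$backward <- NULL
    }
  }
  invisible(NULL)
}

ad_mm <- function(tape, a, b) {
  out <- ad_node(tape, a$value %*% b$value)
  out$backward <- function(nd) {
    ad_accum(a, nd$grad %*% t(b$value))
    ad_accum(b, crossprod(a$value, nd$grad))
  }
  out
}

## x (n x p) + row vector b (length p), recycled down rows
ad_add_bias <- function(tape, x, b) {
  out <- ad_node(tape, x$value + rep(b$value, each = nrow(x$value)))
  out$backward <- function(nd) {
    ad_accum(x, nd$grad)
    ad_accum(b, colSums(nd$grad))
  }
  out
}

ad_add <- function(tape, a, b) {
  out <- ad_node(tape, a$value + b$value)
  out$backward <- function(nd) {
    ad_accum(a, nd$grad)
    ad_accum(b, nd$grad)
  }
  out
}

ad_relu <- function(tape, x) {
  mask <- x$value > 0
  out <- ad_node(tape, x$value * mask)
  out$backward <- function(nd) ad_accum(x, nd$grad * mask)
  out
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  out <- ad_node(tape, s)
  out$backward <- function(nd) ad_accum(x, nd$grad * s * (1 - s))
  out
}

## Inverted dropout; identity when train = FALSE or p = 0.
ad_dropout <- function(tape, x, p, train) {
  if (!train || p <= 0) return(x)
  mask <- (runif(length(x$value)) >= p) / (1 - p)
  dim(mask) <- dim(x$value)
  out <- ad_node(tape, x$value * mask)
  out$backward <- function(nd) ad_accum(x, nd$grad * mask)
  out
}

## First row-encoder block, fused with the token embedding. Conceptually:
## embed tokens (R x P -> R x P x E), flatten position-major to R x (P*E),
## split each row into k heads of g = P/k consecutive positions, apply a
## shared affine (P*E/k -> d) + ReLU per head. Because the affine only
## ever sees embeddings of V distinct tokens, emb %*% W can be
## precomputed per position slot (g tables of V x d) and the whole block
## reduces to g table lookups and adds - no large matmul, no reshape.
## Dropout acts at token granularity: a dropped token's embedding is
## zeroed for this pass. Output: (R*k) x d with row order (r, h), r
## fastest. With keep_input_grad, the backward additionally records the
## L2 norm of the loss gradient w.r.t. each token's embedding
## ($cell_grad_norm, R x P).
ad_embed_block <- function(tape, emb, W, b, ids, drop_p = 0, train = FALSE,
                           keep_input_grad = FALSE) {
  R <- nrow(ids); P <- ncol(ids); E <- ncol(emb$value)
  V <- nrow(emb$value)
  d <- ncol(W$value)
  g <- nrow(W$value) %/% E             # positions per head
  k <- P %/% g
  Wj <- lapply(seq_len(g), function(j) {
    W$value[((j - 1L) * E + 1L):(j * E), , drop = FALSE]
  })
  Tj <- lapply(Wj, function(w) emb$value %*% w)

  ## Aligned-matrix rows are overwhelmingly PAD, and CLS rows are all-CLS:
  ## head outputs for those are batch-constant, so only (row, head) cells
  ## touching a real mass-defect token need gathering. Token dropout acts
  ## on those real tokens only (dropping a constant PAD/CLS filler would
  ## regularise nothing and would break the constant rows).
  is_cls_row <- rowSums(ids == 101L) == P
  np <- ids != 100L
  np[is_cls_row, ] <- FALSE
  dim(np) <- c(R, g, k)
  special <- matrix(FALSE, R, k)
  for (j in seq_len(g)) special <- special | np[, j, ]
  sp <- which(special)                               # Z-row indices (r, h)
  r_sp <- (sp - 1L) %% R + 1L
  h_sp <- (sp - 1L) %/% R + 1L
  S <- length(sp)

  pad_const <- b$value
  cls_const <- b$value
  for (j in seq_len(g)) {
    pad_const <- pad_const + Tj[[j]][101L, ]
    cls_const <- cls_const + Tj[[j]][102L, ]
  }
  Z <- const_rows(pad_const, R * k)
  clsz <- as.vector(outer(which(is_cls_row), R * (seq_len(k) - 1L), `+`))
  if (length(clsz)) Z[clsz, ] <- const_rows(cls_const, length(clsz))

  ## Special cells go through the affine explicitly so that dropout can
  ## act element-wise on the embedded features of real mass-defect
  ## tokens (filler PAD/CLS embeddings are never dropped - they carry no
  ## information and dropping them would break the constant rows).
  tok_j <- vector("list", g)
  Msp <- NULL
  mask <- NULL
  if (S) {
    Msp <- matrix(0, S, g * E)
    for (j in seq_len(g)) {
      tk <- ids[cbind(r_sp, (h_sp - 1L) * g + j)]
      tok_j[[j]] <- tk
      Msp[, ((j - 1L) * E + 1L):(j * E)] <- emb$value[tk + 1L, , drop = FALSE]
    }
    if (train && drop_p > 0) {
      mask <- matrix(1, S, g * E)
      for (j in seq_len(g)) {
        real <- which(tok_j[[j]] < 100L)
        if (length(real)) {
          cols <- ((j - 1L) * E + 1L):(j * E)
          mask[real, cols] <- (runif(length(real) * E) >= drop_p) / (1 - drop_p)
        }
      }
      Msp <- Msp * mask
    }
    Z[sp, ] <- Msp %*% W$value + const_rows(b$value, S)
  }
  act <- Z > 0
  out <- ad_node(tape, Z * act)
  ## row classes let later blocks skip work on constant rows:
  ## 0 = informative, 1 = all-PAD constant, 2 = CLS constant
  rcl <- rep.int(1L, R * k)
  rcl[clsz] <- 2L
  rcl[sp] <- 0L
  out$row_class <- rcl
  out$const_pad <- pmax(pad_const, 0)
  out$const_cls <- pmax(cls_const, 0)
  out$backward <- function(nd) {
    dZ <- nd$grad * act
    ad_accum(b, colSums(dZ))
    colS_all <- colSums(dZ)
    colS_cls <- if (length(clsz)) colSums(dZ[clsz, , drop = FALSE]) else numeric(d)
    dZsp <- if (S) dZ[sp, , drop = FALSE] else NULL
    colS_sp <- if (S) colSums(dZsp) else numeric(d)
    pad_base <- colS_all - colS_sp - colS_cls
    gW <- matrix(0, nrow(W$value), d)
    gE <- matrix(0, V, E)
    cgn <- if (keep_input_grad) matrix(0, R, P) else NULL
    dMsp <- NULL
    if (S) {
      dMsp <- dZsp %*% t(W$value)
      if (!is.null(mask)) dMsp <- dMsp * mask
      gW <- crossprod(Msp, dZsp)
    }
    for (j in seq_len(g)) {
      ## filler (PAD/CLS) contributions from the constant rows
      dT <- matrix(0, V, d)
      dT[101L, ] <- pad_base
      dT[102L, ] <- colS_cls
      gW[((j - 1L) * E + 1L):(j * E), ] <-
        gW[((j - 1L) * E + 1L):(j * E), , drop = FALSE] +
        crossprod(emb$value, dT)
      gE <- gE + dT %*% t(Wj[[j]])
      if (S) {
        cols <- ((j - 1L) * E + 1L):(j * E)
        dMj <- dMsp[, cols, drop = FALSE]
        if (keep_input_grad) {
          cgn[cbind(r_sp, (h_sp - 1L) * g + j)] <- sqrt(rowSums(dMj * dMj))
        }
        agg <- rowsum(dMj, group = tok_j[[j]], reorder = TRUE)
        rws <- as.integer(rownames(agg)) + 1L
        gE[rws, ] <- gE[rws, , drop = FALSE] + agg
      }
    }
    if (keep_input_grad) nd$cell_grad_norm <- cgn
    ad_accum(W, gW)
    ad_accum(emb, gE)
  }
  out
}

## Later row-encoder block (and, with relu = FALSE and g = units, the
## final row projection): input x is (R*u) x w in (r, unit) row order; k =
## u/g output heads each see g consecutive units, mapped by a shared
## affine (g*w -> d). Unit-granular dropout. Output (R*k) x d, (r, head)
## row order.
##
## When the input carries row classes (from ad_embed_block) and dropout
## is inactive, constant input rows produce constant outputs: the affine
## is evaluated once per constant class and only informative rows go
## through the matmuls. The backward sweep stays dense (each constant
## row still receives its own gradient).
ad_unit_block <- function(tape, x, W, b, R, g, drop_p = 0, train = FALSE,
                          relu = TRUE) {
  w <- ncol(x$value)
  u <- nrow(x$value) %/% R
  k <- u %/% g
  d <- ncol(W$value)
  idx <- lapply(seq_len(g), function(j) {
    as.vector(outer(seq_len(R), R * ((seq_len(k) - 1L) * g + j - 1L), `+`))
  })
  mvec <- NULL
  if (train && drop_p > 0) mvec <- (runif(R * u) >= drop_p) / (1 - drop_p)
  use_skip <- !is.null(x$row_class) && is.null(mvec)

  Wrows <- function(j) W$value[((j - 1L) * w + 1L):(j * w), , drop = FALSE]
  Xj <- vector("list", g)        # dense path: full inputs; skip path: special rows
  spo <- NULL
  out_cl <- NULL
  if (use_skip) {
    cl <- matrix(x$row_class, R, u)
    maxc <- minc <- matrix(cl[, seq.int(1L, by = g, length.out = k)], R, k)
    if (g > 1L) for (j in 2L:g) {
      cj <- cl[, seq.int(j, by = g, length.out = k), drop = FALSE]
      maxc <- pmax(maxc, cj); minc <- pmin(minc, cj)
    }
    out_cl <- ifelse(maxc == 2L, 2L, ifelse(minc == 1L, 1L, 0L))
    dim(out_cl) <- NULL
    spo <- which(out_cl == 0L)
    pad_pre <- b$value; cls_pre <- b$value
    for (j in seq_len(g)) {
      pad_pre <- pad_pre + as.vector(x$const_pad %*% Wrows(j))
      cls_pre <- cls_pre + as.vector(x$const_cls %*% Wrows(j))
    }
    Z <- const_rows(pad_pre, R * k)
    clso <- which(out_cl == 2L)
    if (length(clso)) Z[clso, ] <- const_rows(cls_pre, length(clso))
    if (length(spo)) {
      Zs <- const_rows(b$value, length(spo))
      for (j in seq_len(g)) {
        Xj[[j]] <- x$value[idx[[j]][spo], , drop = FALSE]
        Zs <- Zs + Xj[[j]] %*% Wrows(j)
      }
      Z[spo, ] <- Zs
    }
  } else {
    Z <- const_rows(b$value, R * k)
    for (j in seq_len(g)) {
      Xj[[j]] <- x$value[idx[[j]], , drop = FALSE]
      if (!is.null(mvec)) Xj[[j]] <- Xj[[j]] * mvec[idx[[j]]]
      Z <- Z + Xj[[j]] %*% Wrows(j)
    }
  }
  act <- if (relu) Z > 0 else NULL
  out <- ad_node(tape, if (relu) Z * act else Z)
  if (use_skip) {
    out$row_class <- out_cl
    out$const_pad <- if (relu) pmax(pad_pre, 0) else pad_pre
    out$const_cls <- if (relu) pmax(cls_pre, 0) else cls_pre
  }
  out$backward <- function(nd) {
    dZ <- if (relu) nd$grad * act else nd$grad
    ad_accum(b, colSums(dZ))
    gW <- matrix(0, nrow(W$value), d)
    gX <- matrix(0, nrow(x$value), w)
    if (use_skip) {
      pado <- which(out_cl == 1L); clso <- which(out_cl == 2L)
      colS_pad <- if (length(pado)) colSums(dZ[pado, , drop = FALSE]) else numeric(d)
      colS_cls <- if (length(clso)) colSums(dZ[clso, , drop = FALSE]) else numeric(d)
      dZs <- if (length(spo)) dZ[spo, , drop = FALSE] else NULL
      for (j in seq_len(g)) {
        rows <- ((j - 1L) * w + 1L):(j * w)
        gWj <- outer(x$const_pad, colS_pad) + outer(x$const_cls, colS_cls)
        if (!is.null(dZs)) gWj <- gWj + crossprod(Xj[[j]], dZs)
        gW[rows, ] <- gWj
        gX[idx[[j]], ] <- dZ %*% t(W$value[rows, , drop = FALSE])
      }
    } else {
      for (j in seq_len(g)) {
        rows <- ((j - 1L) * w + 1L):(j * w)
        gW[rows, ] <- crossprod(Xj[[j]], dZ)
        dXj <- dZ %*% t(W$value[rows, , drop = FALSE])
        if (!is.null(mvec)) dXj <- dXj * mvec[idx[[j]]]
        gX[idx[[j]], ] <- dXj      # unit index sets partition the rows
      }
    }
    ad_accum(W, gW)
    ad_accum(x, gX)
  }
  out
}

## Per-row layer normalisation with learnable gain/offset.
ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  g <- rep(gamma$value, each = nrow(xv))
  out <- ad_node(tape, xhat * g + rep(beta$value, each = nrow(xv)))
  out$backward <- function(nd) {
    dxhat <- nd$grad * g
    ad_accum(gamma, colSums(nd$grad * xhat))
    ad_accum(beta, colSums(nd$grad))
    ad_accum(x, (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv)
  }
  out
}

## Row selection (gather); idx into rows of x.
ad_rows <- function(tape, x, idx) {
  out <- ad_node(tape, x$value[idx, , drop = FALSE])
  out$backward <- function(nd) {
    g <- matrix(0, nrow(x$value), ncol(x$value))
    g[idx, ] <- nd$grad
    ad_accum(x, g)
  }
  out
}

ad_cbind <- function(tape, a, b) {
  na <- ncol(a$value)
  out <- ad_node(tape, cbind(a$value, b$value))
  out$backward <- function(nd) {
    ad_accum(a, nd$grad[, seq_len(na), drop = FALSE])
    ad_accum(b, nd$grad[, -seq_len(na), drop = FALSE])
  }
  out
}

## Reusable block-diagonal structure for a stack of sequence lengths:
## additive mask (0 within a sequence's block, -Inf-like outside) and the
## linear indices of the within-block cells.
mha_block_info <- function(lens) {
  N <- sum(lens)
  seq_of <- rep.int(seq_along(lens), lens)
  off <- matrix(-1e30, N, N)
  inb <- outer(seq_of, seq_of, `==`)
  off[inb] <- 0
  list(off = off, idx = which(inb), N = N,
       offs = c(0L, cumsum(lens)))
}

## Multi-head self-attention over a stack of variable-length sequences.
## x: (sum(lens)) x d node; sequences are contiguous row blocks described
## by `blk` (from mha_block_info()). Attention is computed densely over
## the stack with an additive block mask, so cross-sequence cells get
## zero probability; no positional encoding - rows are an unordered set.
## Dropout on attention probabilities is drawn only for within-block
## cells. When keep_attn = TRUE the node records, per sequence, the
## head-resolved attention maps ($attn) and, after backward, their
## gradients ($attn_grad) - lists of (heads x L x L) arrays.
ad_mha <- function(tape, x, Wq, bq, Wk, bk, Wv, bv, Wo, bo,
                   blk, n_heads, p_drop = 0, train = FALSE,
                   keep_attn = FALSE) {
  d <- ncol(x$value)
  dh <- d %/% n_heads
  scale <- 1 / sqrt(dh)
  N <- blk$N
  B <- length(blk$offs) - 1L

  Q <- x$value %*% Wq$value + rep(bq$value, each = N)
  K <- x$value %*% Wk$value + rep(bk$value, each = N)
  V <- x$value %*% Wv$value + rep(bv$value, each = N)

  ctx <- matrix(0, N, d)
  P_store <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) * scale +
      blk$off
    S <- S - S[cbind(seq_len(N), max.col(S, ties.method = "first"))]
    P <- exp(S)
    P <- P / rowSums(P)
    mask <- NULL
    Pd <- P
    if (train && p_drop > 0) {
      mask <- rep(1, length(blk$idx))
      mask[runif(length(blk$idx)) < p_drop] <- 0
      mask <- mask / (1 - p_drop)
      Pd <- P
      Pd[blk$idx] <- Pd[blk$idx] * mask
    }
    P_store[[h]] <- list(P = P, mask = mask)
    ctx[, cols] <- Pd %*% V[, cols, drop = FALSE]
  }
  outv <- ctx %*% Wo$value + rep(bo$value, each = N)
  out <- ad_node(tape, outv)
  if (keep_attn) {
    out$attn <- lapply(seq_len(B), function(b) {
      rows <- (blk$offs[b] + 1L):blk$offs[b + 1L]
      arr <- array(0, c(n_heads, length(rows), length(rows)))
      for (h in seq_len(n_heads)) arr[h, , ] <- P_store[[h]]$P[rows, rows]
      arr
    })
  }
  out$backward <- function(nd) {
    g <- nd$grad
    ad_accum(Wo, crossprod(ctx, g))
    ad_accum(bo, colSums(g))
    dctx <- g %*% t(Wo$value)
    dQ <- matrix(0, N, d); dK <- dQ; dV <- dQ
    dP_keep <- if (keep_attn) vector("list", n_heads) else NULL
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      st <- P_store[[h]]
      P <- st$P
      Pd <- P
      if (!is.null(st$mask)) Pd[blk$idx] <- Pd[blk$idx] * st$mask
      dO <- dctx[, cols, drop = FALSE]
      dPd <- tcrossprod(dO, V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(Pd, dO)
      dP <- dPd
      if (!is.null(st$mask)) dP[blk$idx] <- dP[blk$idx] * st$mask
      if (keep_attn) dP_keep[[h]] <- dP
      dS <- P * (dP - rowSums(dP * P)) * scale
      dQ[, cols] <- dS %*% K[, cols, drop = FALSE]
      dK[, cols] <- crossprod(dS, Q[, cols, drop = FALSE])
    }
    if (keep_attn) {
      nd$attn_grad <- lapply(seq_len(B), function(b) {
        rows <- (blk$offs[b] + 1L):blk$offs[b + 1L]
        arr <- array(0, c(n_heads, length(rows), length(rows)))
        for (h in seq_len(n_heads)) arr[h, , ] <- dP_keep[[h]][rows, rows]
        arr
      })
    }
    ad_accum(Wq, crossprod(x$value, dQ)); ad_accum(bq, colSums(dQ))
    ad_accum(Wk, crossprod(x$value, dK)); ad_accum(bk, colSums(dK))
    ad_accum(Wv, crossprod(x$value, dV)); ad_accum(bv, colSums(dV))
    ad_accum(x, dQ %*% t(Wq$value) + dK %*% t(Wk$value) + dV %*% t(Wv$value))
  }
  out
}
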