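# The reverse-mode engine behind the model: every operation is checked
# against finite differences or a dense reference implementation.

fd_grad <- function(f, x, ix, eps = 1e-6) {
  xp <- x; xp[ix] <- xp[ix] + eps
  xm <- x; xm[ix] <- xm[ix] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

test_that("core matrix ops backpropagate exact gradients", {
  set.seed(31)
  A <- matrix(rnorm(12), 3, 4)
  B <- matrix(rnorm(20), 4, 5)
  bias <- rnorm(5)
  gamma <- runif(5, 0.5, 1.5)
  beta <- rnorm(5) * 0.1
  tgt <- matrix(rnorm(15), 3, 5)
  run <- function(Av, Bv, bv, gv, bev) {
    tape <- ms2sim:::ad_tape()
    a <- ms2sim:::ad_leaf(tape, Av); b <- ms2sim:::ad_leaf(tape, Bv)
    bb <- ms2sim:::ad_leaf(tape, bv)
    g <- ms2sim:::ad_leaf(tape, gv); be <- ms2sim:::ad_leaf(tape, bev)
    z <- ms2sim:::ad_add_bias(tape, ms2sim:::ad_mm(tape, a, b), bb)
    z <- ms2sim:::ad_relu(tape, z)
    z <- ms2sim:::ad_layernorm(tape, z, g, be)
    z <- ms2sim:::ad_sigmoid(tape, z)
    list(tape = tape, leaves = list(A = a, B = b, bias = bb, gamma = g, beta = be),
         out = z)
  }
  r <- run(A, B, bias, gamma, beta)
  loss_seed <- 2 * (r$out$value - tgt)
  ms2sim:::ad_backward(r$tape, r$out, loss_seed)
  lossfn <- function(Av = A, Bv = B, bv = bias, gv = gamma, bev = beta) {
    sum((run(Av, Bv, bv, gv, bev)$out$value - tgt)^2)
  }
  for (ix in c(1, 5, 9)) {
    expect_equal(r$leaves$A$grad[ix],
                 fd_grad(function(x) lossfn(Av = x), A, ix), tolerance = 1e-5)
    expect_equal(r$leaves$B$grad[ix],
                 fd_grad(function(x) lossfn(Bv = x), B, ix), tolerance = 1e-5)
  }
  for (ix in c(1, 3)) {
    expect_equal(r$leaves$gamma$grad[ix],
                 fd_grad(function(x) lossfn(gv = x), gamma, ix), tolerance = 1e-5)
    expect_equal(r$leaves$beta$grad[ix],
                 fd_grad(function(x) lossfn(bev = x), beta, ix), tolerance = 1e-5)
  }
})

test_that("block-diagonal attention matches finite differences", {
  set.seed(32)
  d <- 8L; nh <- 2L
  lens <- c(3L, 5L, 2L)
  blk <- ms2sim:::mha_block_info(lens)
  N <- sum(lens)
  params <- list(X = matrix(rnorm(N * d), N, d))
  for (nm in c("Wq", "Wk", "Wv", "Wo")) params[[nm]] <- matrix(rnorm(d * d) * 0.3, d, d)
  for (nm in c("bq", "bk", "bv", "bo")) params[[nm]] <- rnorm(d) * 0.1
  tgt <- matrix(rnorm(N * d), N, d)
  run <- function(p) {
    tape <- ms2sim:::ad_tape()
    lv <- lapply(p, function(v) ms2sim:::ad_leaf(tape, v))
    out <- ms2sim:::ad_mha(tape, lv$X, lv$Wq, lv$bq, lv$Wk, lv$bk,
                           lv$Wv, lv$bv, lv$Wo, lv$bo, blk, nh)
    list(tape = tape, leaves = lv, out = out)
  }
  r <- run(params)
  ms2sim:::ad_backward(r$tape, r$out, 2 * (r$out$value - tgt))
  for (nm in c("X", "Wq", "Wv", "Wo", "bv")) {
    for (ix in sample(length(params[[nm]]), 3)) {
      fd <- fd_grad(function(x) {
        p2 <- params; p2[[nm]] <- x
        sum((run(p2)$out$value - tgt)^2)
      }, params[[nm]], ix)
      expect_equal(r$leaves[[nm]]$grad[ix], fd, tolerance = 1e-4)
    }
  }
})

test_that("attention is confined to each sequence's block", {
  set.seed(33)
  d <- 8L; nh <- 2L
  lens <- c(4L, 3L)
  blk <- ms2sim:::mha_block_info(lens)
  params <- lapply(c(Wq = 1, Wk = 1, Wv = 1, Wo = 1),
                   function(.) matrix(rnorm(d * d) * 0.3, d, d))
  bz <- rnorm(d) * 0.1
  X <- matrix(rnorm(sum(lens) * d), sum(lens), d)
  run <- function(Xv) {
    tape <- ms2sim:::ad_tape()
    lv <- lapply(params, function(v) ms2sim:::ad_leaf(tape, v))
    bb <- ms2sim:::ad_leaf(tape, bz)
    x <- ms2sim:::ad_leaf(tape, Xv)
    ms2sim:::ad_mha(tape, x, lv$Wq, bb, lv$Wk, bb, lv$Wv, bb, lv$Wo, bb,
                    blk, nh)$value
  }
  base <- run(X)
  X2 <- X
  X2[6, ] <- X2[6, ] + 1   # perturb a row of sequence 2
  pert <- run(X2)
  expect_equal(pert[1:4, ], base[1:4, ])          # sequence 1 untouched
  expect_false(isTRUE(all.equal(pert[5:7, ], base[5:7, ])))
})

test_that("the fused embedding block equals its dense reference", {
  set.seed(34)
  V <- 102L; E <- 4L; P <- 20L; g <- 2L; d <- 8L; R <- 7L
  ids <- matrix(100L, R, P)
  ids[2, ] <- 101L                                   # a CLS row
  for (r in setdiff(1:R, 2)) {
    nn <- sample(0:6, 1)
    if (nn) ids[r, sample(P, nn)] <- sample(0:99, nn, TRUE)
  }
  emb <- matrix(rnorm(V * E) * 0.5, V, E)
  W <- matrix(rnorm(g * E * d) * 0.3, g * E, d)
  b <- rnorm(d) * 0.1
  k <- P %/% g
  Zref <- matrix(rep(b, each = R * k), R * k, d)
  for (j in 1:g) {
    idsj <- as.vector(ids[, seq.int(j, by = g, length.out = k)])
    Zref <- Zref + (emb %*% W[((j - 1) * E + 1):(j * E), ])[idsj + 1L, ]
  }
  Zref <- Zref * (Zref > 0)
  tape <- ms2sim:::ad_tape()
  lv <- list(emb = ms2sim:::ad_leaf(tape, emb),
             W = ms2sim:::ad_leaf(tape, W),
             b = ms2sim:::ad_leaf(tape, b))
  out <- ms2sim:::ad_embed_block(tape, lv$emb, lv$W, lv$b, ids)
  expect_equal(out$value, Zref)
  gZ <- matrix(rnorm(R * k * d), R * k, d)
  ms2sim:::ad_backward(tape, out, gZ)
  dZ <- gZ * (Zref > 0)
  gWref <- matrix(0, g * E, d)
  gEref <- matrix(0, V, E)
  for (j in 1:g) {
    idsj <- as.vector(ids[, seq.int(j, by = g, length.out = k)])
    agg <- rowsum(dZ, idsj, reorder = TRUE)
    dT <- matrix(0, V, d); dT[as.integer(rownames(agg)) + 1L, ] <- agg
    gWref[((j - 1) * E + 1):(j * E), ] <- crossprod(emb, dT)
    gEref <- gEref + dT %*% t(W[((j - 1) * E + 1):(j * E), ])
  }
  expect_equal(lv$W$grad, gWref)
  expect_equal(lv$emb$grad, gEref)
  expect_equal(lv$b$grad, colSums(dZ))
})

test_that("the unit block (later row-encoder stages) matches finite differences", {
  set.seed(35)
  R <- 4L; u <- 10L; w <- 5L; g <- 2L; d <- 6L
  params <- list(X = matrix(rnorm(R * u * w), R * u, w),
                 W = matrix(rnorm(g * w * d) * 0.3, g * w, d),
                 b = rnorm(d) * 0.1)
  tgt <- matrix(rnorm(R * (u / g) * d), R * (u / g), d)
  run <- function(p) {
    tape <- ms2sim:::ad_tape()
    lv <- lapply(p, function(v) ms2sim:::ad_leaf(tape, v))
    out <- ms2sim:::ad_unit_block(tape, lv$X, lv$W, lv$b, R = R, g = g)
    list(tape = tape, leaves = lv, out = out)
  }
  r <- run(params)
  ms2sim:::ad_backward(r$tape, r$out, 2 * (r$out$value - tgt))
  for (nm in names(params)) {
    for (ix in sample(length(params[[nm]]), 3)) {
      fd <- fd_grad(function(x) {
        p2 <- params; p2[[nm]] <- x
        sum((run(p2)$out$value - tgt)^2)
      }, params[[nm]], ix)
      expect_equal(r$leaves[[nm]]$grad[ix], fd, tolerance = 1e-4)
    }
  }
})

test_that("inverted dropout is unbiased in expectation and off in eval mode", {
  set.seed(36)
  x <- matrix(1, 200, 50)
  tape <- ms2sim:::ad_tape()
  nx <- ms2sim:::ad_leaf(tape, x)
  expect_identical(ms2sim:::ad_dropout(tape, nx, 0.3, train = FALSE), nx)
  dr <- ms2sim:::ad_dropout(tape, nx, 0.3, train = TRUE)
  expect_equal(mean(dr$value), 1, tolerance = 0.05)
  expect_true(all(dr$value %in% c(0, 1 / 0.7)))
})
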