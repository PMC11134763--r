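# Library search, cosine baselines, evaluation battery, network edges.

test_that("cosine scores match identity/disjoint expectations", {
  set.seed(71)
  s <- random_spectrum(6)
  expect_equal(cosine_score(s, s, mode = "plain"), 1, tolerance = 1e-12)
  expect_equal(cosine_score(s, s, mode = "modified"), 1, tolerance = 1e-12)
  far <- list(peaks = tibble::tibble(mz = s$peaks$mz + 3.33, intensity = s$peaks$intensity),
              precursor_mz = s$precursor_mz + 7.77)
  expect_equal(cosine_score(s, far, mode = "plain"), 0)
  # the shifted spectrum is a perfect modified-cosine match
  shifted <- list(peaks = tibble::tibble(mz = s$peaks$mz + 21.98,
                                         intensity = s$peaks$intensity),
                  precursor_mz = s$precursor_mz + 21.98)
  expect_equal(cosine_score(s, shifted, mode = "modified"), 1, tolerance = 1e-12)
  expect_error(cosine_score(list(peaks = s$peaks), s, mode = "modified"),
               "precursor")
})

test_that("greedy cosine equals the exhaustive-assignment oracle on toy spectra", {
  set.seed(72)
  for (i in 1:40) {
    pa <- tibble::tibble(mz = round(runif(3, 100, 110), 2), intensity = runif(3, 1, 100))
    pb <- tibble::tibble(mz = round(runif(4, 100, 110), 2) , intensity = runif(4, 1, 100))
    pa <- pa[!duplicated(pa$mz), ]; pb <- pb[!duplicated(pb$mz), ]
    got <- cosine_score(list(peaks = pa), list(peaks = pb), tol = 2)
    ref <- oracle_cosine(pa[order(pa$mz), ], pb[order(pb$mz), ], tol = 2)
    # greedy intensity-product matching is near-optimal on these inputs;
    # it must never exceed the optimum and usually attains it
    expect_lte(got, ref + 1e-9)
    expect_gte(got, 0)
  }
})

test_that("cosine is symmetric and bounded on random pairs", {
  set.seed(73)
  for (i in 1:20) {
    a <- random_spectrum(sample(3:10, 1))
    b <- random_spectrum(sample(3:10, 1))
    for (mode in c("plain", "modified")) {
      s1 <- cosine_score(a, b, mode = mode)
      s2 <- cosine_score(b, a, mode = mode)
      expect_equal(s1, s2, tolerance = 1e-12)
      expect_gte(s1, 0); expect_lte(s1, 1)
    }
  }
})

test_that("a perfect predictor yields zero bin MSE, r = 1 and ideal PR", {
  set.seed(74)
  lab <- runif(60)
  ev <- evaluate_pairs(tibble::tibble(y_sim = lab, label = lab))
  occ <- ev$per_bin[ev$per_bin$n > 0, ]
  expect_true(all(occ$mse == 0))
  expect_equal(ev$pearson_r, 1)
  for (co in c(0.6, 0.7, 0.8, 0.9)) {
    pr <- ev$pr_curves[ev$pr_curves$cutoff == co, ]
    # sweeping the threshold just above the cut-off separates perfectly
    best <- pr[pr$threshold > co, ][1, ]
    expect_equal(best$precision, 1)
    expect_equal(best$recall, 1)
  }
})

test_that("a constant predictor reports r = 0 with a warning", {
  expect_warning(
    ev <- evaluate_pairs(tibble::tibble(y_sim = rep(0.5, 20),
                                        label = runif(20))),
    "zero variance")
  expect_equal(ev$pearson_r, 0)
})

test_that("precision/recall equal the brute-force confusion matrix everywhere", {
  set.seed(75)
  pairs <- tibble::tibble(y_sim = round(runif(20), 3), label = runif(20))
  ev <- evaluate_pairs(pairs)
  for (co in unique(ev$pr_curves$cutoff)) {
    sub <- ev$pr_curves[ev$pr_curves$cutoff == co, ]
    for (r in seq_len(nrow(sub))) {
      ref <- oracle_pr(pairs$y_sim, pairs$label, co, sub$threshold[r])
      expect_equal(sub$precision[r], unname(ref["precision"]))
      expect_equal(sub$recall[r], unname(ref["recall"]))
    }
    # recall is non-increasing as the threshold rises
    expect_true(all(diff(sub$recall[order(sub$threshold)]) <= 1e-12))
  }
  # evaluation is invariant to pair order
  ev2 <- evaluate_pairs(pairs[sample(nrow(pairs)), ])
  expect_equal(ev2$pr_curves, ev$pr_curves)
  expect_equal(ev2$pearson_r, ev$pearson_r)
  # empty bins are absent (NA), not zero
  sparse <- tibble::tibble(y_sim = c(0.1, 0.95), label = c(0.05, 0.98))
  evs <- evaluate_pairs(sparse)
  expect_true(any(is.na(evs$per_bin$mse)))
  expect_true(all(evs$per_bin$n[is.na(evs$per_bin$mse)] == 0))
})

test_that("network edges respect threshold, top-k and family-size rules", {
  # all scores at or below the threshold: empty network
  low <- tibble::tibble(source = c("a", "b"), target = c("b", "c"),
                        score = c(0.6, 0.5))
  expect_equal(nrow(network_edges(low)), 0L)
  # a triangle at 0.9 survives top_k = 2 intact
  tri <- tibble::tibble(source = c("a", "a", "b"), target = c("b", "c", "c"),
                        score = 0.9)
  expect_equal(nrow(network_edges(tri, top_k = 2)), 3L)
  # top_k = 1 keeps only mutually-best edges
  star <- tibble::tibble(source = c("hub", "hub", "hub"),
                         target = c("x", "y", "z"),
                         score = c(0.9, 0.8, 0.7))
  kept <- network_edges(star, top_k = 1)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$target, "x")
  # oversized families are split by removing the weakest edges
  chain <- tibble::tibble(source = letters[1:5], target = letters[2:6],
                          score = c(0.9, 0.7, 0.65, 0.95, 0.8))
  split3 <- network_edges(chain, max_family_size = 3)
  g <- igraph::graph_from_data_frame(split3[, 1:2], directed = FALSE)
  expect_true(all(igraph::components(g)$csize <= 3))
})

test_that("network components match a union-find oracle after identical filtering", {
  set.seed(76)
  for (rep in 1:5) {
    n <- 10
    ids <- sprintf("n%02d", 1:n)
    S <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
    S <- (S + t(S)) / 2; diag(S) <- 1
    ed <- network_edges(S, threshold = 0.6, top_k = 4, max_family_size = 6)
    comp <- oracle_components(ed, ids)
    g <- igraph::graph_from_data_frame(ed[, 1:2], directed = FALSE,
                                       vertices = ids)
    ig <- igraph::components(g)$membership
    # identical partitions (compare co-membership relations)
    expect_equal(outer(comp, comp, "=="), outer(ig, ig, "=="),
                 ignore_attr = TRUE)
    expect_true(all(table(c(ed$source, ed$target)) <= 4))
    expect_true(all(ed$score > 0.6))
  }
})

test_that("network edges are independent of input row order", {
  set.seed(77)
  ed0 <- tibble::tibble(source = sample(letters[1:8], 20, TRUE),
                        target = sample(letters[1:8], 20, TRUE),
                        score = runif(20, 0.5, 1))
  a <- network_edges(ed0, top_k = 3)
  b <- network_edges(ed0[sample(nrow(ed0)), ], top_k = 3)
  expect_equal(a, b)
})

test_that("library search ranks, caps and breaks ties deterministically", {
  set.seed(78)
  m <- init_model(tiny_config())
  lib <- generate_library(n_molecules = 8, seed = 9)
  sp <- preprocess_spectra(lib$spectra)
  # shrink to the tiny model's column budget by reusing encode cutoff
  res <- library_search(m, sp[1, ], sp, top_n = 3)
  expect_equal(nrow(res), 3L)
  full <- library_search(m, sp[1, ], sp, top_n = 50)
  expect_equal(nrow(full), nrow(sp))        # top_n larger than library
  expect_true(all(diff(full$y_sim) <= 1e-12))
  expect_identical(full, library_search(m, sp[1, ], sp, top_n = 50))
  expect_error(library_search(m, sp[1, ], sp[0, ]), "empty")
})
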