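# Mass-difference-matrix and aligned-matrix encoding.

test_that("neutral losses are precursor minus fragment, positives only", {
  s <- list(peaks = tibble::tibble(mz = c(150, 180.1), intensity = c(50, 100)),
            precursor_mz = 200)
  nl <- neutral_loss_spectrum(s)
  expect_equal(nl$mz, c(19.9, 50))            # sorted ascending by loss
  expect_equal(nl$fragment, c(2L, 1L))        # loss 19.9 came from fragment 180.1
  # a fragment at the precursor gives loss 0 and is dropped
  s2 <- list(peaks = tibble::tibble(mz = c(163.06, 180.1), intensity = c(100, 20)),
             precursor_mz = 180.1)
  nl2 <- neutral_loss_spectrum(s2)
  expect_equal(nl2$mz, 17.04)
  expect_error(neutral_loss_spectrum(list(peaks = s$peaks)), "precursor required")
})

test_that("MDM holds absolute 2-dp differences with query rows", {
  one_peak <- function(mz) list(peaks = tibble::tibble(mz = mz, intensity = 100))
  expect_equal(mass_difference_matrix(one_peak(145.06), one_peak(161.05))$values,
               matrix(15.99, 1, 1))
  expect_equal(mass_difference_matrix(one_peak(163.06), one_peak(161.05))$values,
               matrix(2.01, 1, 1))
  s <- list(peaks = random_peaks(6))
  expect_equal(diag(mass_difference_matrix(s, s)$values), rep(0, 6))
  expect_error(mass_difference_matrix(one_peak(100),
                                      list(peaks = random_peaks(0))),
               "empty")
})

test_that("aligned matrix splits differences into nominal column and defect token", {
  one <- function(mz) list(peaks = tibble::tibble(mz = mz, intensity = 100))
  al <- aligned_matrix(mass_difference_matrix(one(145.06), one(161.05)))
  expect_equal(dim(al$tokens), c(2L, 300L))
  expect_true(all(al$tokens[1, ] == 101L))              # CLS row
  expect_equal(al$tokens[2, 16], 99L)                   # 15.99 -> column 15, defect 99
  expect_true(all(al$tokens[2, -16] == 100L))           # PAD elsewhere
  # zero difference -> token 0 in column 0
  al0 <- aligned_matrix(mass_difference_matrix(one(100), one(100)))
  expect_equal(al0$tokens[2, 1], 0L)
  # cut-off is strict: a 300.00 difference places no token
  al3 <- aligned_matrix(mass_difference_matrix(one(400), one(100)))
  expect_true(all(al3$tokens[2, ] == 100L))
})

test_that("worked example: 157.13 vs 171.15 lands at nominal 14, defect 2", {
  q <- list(peaks = tibble::tibble(mz = 157.13, intensity = 100))
  r <- list(peaks = tibble::tibble(mz = 171.15, intensity = 100))
  mdm <- mass_difference_matrix(q, r)
  expect_equal(mdm$values[1, 1], 14.02)
  al <- aligned_matrix(mdm)
  expect_equal(al$tokens[2, 15], 2L)       # column for nominal mass 14
  expect_equal(al$provenance[2, 15], 1L)
})

test_that("collisions keep the most intense reference fragment, ties to lower m/z", {
  q <- list(peaks = tibble::tibble(mz = 100, intensity = 100))
  # both references differ from the query by 10.xx -> same nominal column
  r <- list(peaks = tibble::tibble(mz = c(110.20, 110.80), intensity = c(30, 90)))
  al <- aligned_matrix(mass_difference_matrix(q, r))
  expect_equal(al$tokens[2, 11], 80L)       # 10.80 from the 90-intensity peak
  expect_equal(al$provenance[2, 11], 2L)
  r2 <- list(peaks = tibble::tibble(mz = c(110.20, 110.80), intensity = c(70, 70)))
  al2 <- aligned_matrix(mass_difference_matrix(q, r2))
  expect_equal(al2$tokens[2, 11], 20L)      # tie -> smaller reference m/z
  expect_equal(al2$provenance[2, 11], 1L)
})

test_that("aligned matrix agrees with the triple-loop oracle on random pairs", {
  set.seed(21)
  for (i in 1:100) {
    q <- random_peaks(sample(2:30, 1))
    r <- random_peaks(sample(2:30, 1))
    r <- r[!duplicated(r$mz), ]
    mdm <- mass_difference_matrix(list(peaks = q), list(peaks = r))
    al <- aligned_matrix(mdm)
    ref <- oracle_aligned(mdm$query_mz, mdm$reference_mz, mdm$reference_intensity)
    expect_identical(al$tokens, ref$tokens)
    expect_identical(al$provenance, ref$prov)
  }
})

test_that("every non-PAD token reconstructs its MDM entry exactly", {
  set.seed(22)
  for (i in 1:100) {
    q <- random_peaks(sample(2:30, 1))
    r <- random_peaks(sample(2:30, 1))
    mdm <- mass_difference_matrix(list(peaks = q), list(peaks = r))
    al <- aligned_matrix(mdm)
    for (row in which(rowSums(al$tokens[-1, , drop = FALSE] != 100L) > 0)) {
      cols <- which(al$tokens[row + 1L, ] != 100L)
      rebuilt <- (cols - 1L) + al$tokens[row + 1L, cols] / 100
      expect_true(all(round(rebuilt, 2) %in% round(mdm$values[row, ], 2)))
    }
  }
})

test_that("tokens are invariant to reference order and equivariant to query order", {
  set.seed(23)
  q <- random_peaks(8)
  r <- random_peaks(10)
  base <- aligned_matrix(mass_difference_matrix(list(peaks = q), list(peaks = r)))
  perm <- sample(nrow(r))
  shuf <- aligned_matrix(mass_difference_matrix(list(peaks = q),
                                                list(peaks = r[perm, ])))
  expect_identical(base$tokens, shuf$tokens)   # mz-sorted internally
  qperm <- sample(nrow(q))
  shufq <- aligned_matrix(mass_difference_matrix(list(peaks = q[qperm, ]),
                                                 list(peaks = r)))
  expect_identical(base$tokens, shufq$tokens)
})

test_that("encode_pair assembles both towers with the loss-fragment maps", {
  set.seed(24)
  q <- random_spectrum(5)
  enc <- encode_pair(q, q)
  # identity pair: token 0 at column 0 in every data row of the fragment tower
  expect_true(all(enc$fragment$tokens[-1, 1] == 0L))
  expect_equal(nrow(enc$fragment$tokens), 6L)  # CLS + 5
  expect_equal(length(enc$query_loss_map), nrow(enc$loss$tokens) - 1L)
  # analog pair differing by one +14.02 moiety shows token 2 at column 14
  q2 <- list(peaks = tibble::tibble(mz = c(157.13, 213.16), intensity = c(80, 100)),
             precursor_mz = 240.2)
  r2 <- list(peaks = tibble::tibble(mz = c(171.15, 213.16), intensity = c(70, 100)),
             precursor_mz = 254.22)
  enc2 <- encode_pair(q2, r2)
  expect_true(any(enc2$fragment$tokens[-1, 15] == 2L))
})
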