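# Nonlinear measures: oracle agreement, known-dynamics behaviour, and the
# conventions of the fixed-recurrence-rate analysis.

test_that("sample entropy matches the brute-force template counter", {
  set.seed(11)
  for (i in 1:15) {
    n <- sample(50:400, 1)
    x <- rnorm(n)
    m <- sample(1:3, 1)
    r <- runif(1, 0.1, 0.4) * sd(x)
    expect_equal(sample_entropy(x, m = m, r = r), oracle_sampen(x, m, r),
                 tolerance = 1e-12)
  }
})

test_that("sample entropy limits: constant and periodic series", {
  expect_identical(sample_entropy(rep(3, 100)), 0)
  alt <- rep(c(1, -1), 5000)
  expect_lte(sample_entropy(alt), 0.01)
  expect_equal(sample_entropy(alt), oracle_sampen(alt), tolerance = 1e-12)
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "at least")
})

test_that("correlation dimension separates limit cycles from noise", {
  t <- seq(0, 50, length.out = 5000)
  cd_sine <- correlation_dimension(sin(2 * pi * t))
  expect_gte(cd_sine, 0.8)
  expect_lte(cd_sine, 1.2)
  set.seed(3)
  expect_gte(correlation_dimension(rnorm(5000)), 3)
  expect_error(correlation_dimension(rep(1, 500)), "constant")
})

test_that("DFA recovers theoretical exponents and their ordering", {
  set.seed(2)
  w <- rnorm(8192)
  a_white <- dfa(w)
  a_walk <- dfa(cumsum(w))
  expect_gte(a_white, 0.45)
  expect_lte(a_white, 0.55)
  expect_gte(a_walk, 1.4)
  expect_lte(a_walk, 1.6)
  # pink-like noise sits between white noise and a random walk
  set.seed(4)
  z <- rnorm(8192)
  pink <- Re(fft(fft(z) / sqrt(pmax(1, seq_along(z) - 1)), inverse = TRUE))
  a_pink <- dfa(pink)
  expect_true(a_white < a_pink && a_pink < a_walk)
  expect_error(dfa(rnorm(32)), "at least")
})

test_that("fixed-RR recurrence plots attain the target rate", {
  set.seed(5)
  x <- rnorm(600)
  rp <- recurrence_matrix(x)
  expect_gte(rp$attained_rr, 0.045)
  expect_lte(rp$attained_rr, 0.055)
  expect_true(isSymmetric(rp$matrix * 1))
  expect_error(recurrence_matrix(rep(2, 100)), "constant")
})

test_that("recurrence matrix equals brute-force embedded thresholding", {
  set.seed(6)
  x <- rnorm(50)
  cfg <- embedding_config(emb_dim = 3, delay = 1, recurrence_rate = 0.1)
  rp <- recurrence_matrix(x, cfg)
  ne <- 50 - 2
  emb <- cbind(x[1:ne], x[2:(ne + 1)], x[3:(ne + 2)])
  dm <- as.matrix(dist(emb))
  manual <- dm <= rp$epsilon
  expect_identical(unname(rp$matrix), unname(manual))
})

test_that("RQA and vertical-line measures equal run-length enumeration", {
  for (s in 1:20) {
    n <- sample(15:40, 1)
    mat <- random_rp_matrix(n, p = runif(1, 0.1, 0.5), seed = 100 + s)
    rp <- new_recurrence_plot(mat)
    got <- c(rqa_measures(rp), vertical_line_measures(rp))
    want <- oracle_rqa(mat)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
})

test_that("saturated and empty plots hit the documented conventions", {
  ones <- matrix(TRUE, 20, 20)
  rp1 <- new_recurrence_plot(ones)
  m1 <- rqa_measures(rp1)
  # the two corner diagonals have length 1 < lmin, so DET is 1 - 2/(N(N-1))
  expect_equal(m1[["DET"]], 1 - 2 / (20 * 19))
  expect_equal(m1[["LAM"]], 1)
  expect_equal(m1[["Lmax"]], 19)  # longest off-identity diagonal
  expect_equal(vertical_line_measures(rp1)[["AvgVertWhiteLen"]], 0)

  loi_only <- diag(20) > 0
  rp0 <- new_recurrence_plot(loi_only)
  m0 <- rqa_measures(rp0)
  expect_equal(unname(m0[c("DET", "LAM", "TT", "Lentr")]), c(0, 0, 0, 0))

  checker <- outer(1:20, 1:20, function(i, j) (i + j) %% 2 == 0)
  rpc <- new_recurrence_plot(checker)
  vm <- vertical_line_measures(rpc)
  expect_equal(vm[["AvgVertWhiteLen"]], 1)
})

test_that("streaming recurrence path equals the materialized-plot path", {
  set.seed(7)
  for (n in c(200, 500)) {
    x <- rnorm(n)
    rp <- recurrence_matrix(x)
    slow <- c(rqa_measures(rp), vertical_line_measures(rp))
    fast <- eegdyn:::rqa_measures_fast(x)
    expect_equal(fast[names(slow)], slow, tolerance = 1e-10)
  }
})

test_that("RQA values are invariant under affine rescaling of the input", {
  set.seed(8)
  x <- rnorm(400)
  a <- c(rqa_measures(recurrence_matrix(x)),
         vertical_line_measures(recurrence_matrix(x)))
  y <- 7.3 * x - 2.1
  b <- c(rqa_measures(recurrence_matrix(y)),
         vertical_line_measures(recurrence_matrix(y)))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("determinism of a periodic signal exceeds shuffled surrogates", {
  set.seed(9)
  t <- seq(0, 4, length.out = 500)
  x <- sin(2 * pi * 6 * t) + 0.3 * rnorm(500)
  det_x <- rqa_measures(recurrence_matrix(x))[["DET"]]
  lam_x <- rqa_measures(recurrence_matrix(x))[["LAM"]]
  worse <- vapply(1:20, function(i) {
    xs <- sample(x)
    rqa_measures(recurrence_matrix(xs))[["DET"]]
  }, numeric(1))
  expect_true(all(worse < det_x))
  expect_true(lam_x >= 0 && lam_x <= 1)
})

test_that("extract_features yields 12 measures per channel and band", {
  set.seed(10)
  rec <- eeg_recording(matrix(rnorm(3 * 800), 3), fs = 500,
                       channel_labels = c("Fp1", "Cz", "O2"),
                       participant_id = "T1", age_code = 5L)
  ft <- extract_features(rec)
  expect_equal(nrow(ft), 3 * 6 * 12)
  expect_equal(sort(unique(ft$measure)), sort(eegdyn_measures()))
  counts <- table(ft$channel, ft$band)
  expect_true(all(counts == 12))
  expect_true(all(is.finite(ft$value)))
  # determinism
  ft2 <- extract_features(rec)
  expect_identical(ft, ft2)
})

test_that("degenerate recordings are flagged missing, not zeroed", {
  rec <- eeg_recording(matrix(0, 2, 600), fs = 500,
                       channel_labels = c("a", "b"))
  ft <- extract_features(rec)
  expect_true(all(is.na(ft$value)))
  ml <- attr(ft, "missing_log")
  expect_equal(nrow(ml), 2 * 6)
  expect_true(all(grepl("degenerate", ml$reason)))
})
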