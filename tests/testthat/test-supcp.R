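# Supervised CP factorization: ground-truth recovery, EM ascent, marginal
# likelihood against a dense Gaussian oracle, and factor reporting.

test_that("noiseless rank-3 tensors are recovered to high congruence", {
  spec <- tensor_sim_spec(40, c(8, 6, 4), 3, noise_sd = 0, score_sd = 1,
                          seed = 11)
  sim <- simulate_supcp_tensor(spec)
  fit <- fit_supcp(sim$tensor, sim$supervision, R = 3, seed = 2)
  W_true <- eegdyn:::build_w(sim$truth$factor_matrices)
  truth <- tcrossprod(sim$truth$scores, W_true)
  W_fit <- eegdyn:::build_w(fit$factor_matrices)
  fitted <- tcrossprod(fit$scores, W_fit)
  expect_lt(norm(fitted - truth, "F") / norm(truth, "F"), 1e-3)
  for (k in 1:3) {
    cong <- factor_congruence(fit$factor_matrices[[k]],
                              sim$truth$factor_matrices[[k]])
    expect_gt(min(cong), 0.99)
  }
})

test_that("the EM log-likelihood ascends on every fit", {
  for (s in 1:12) {
    spec <- tensor_sim_spec(12 + (s %% 4) * 5, c(5, 4, 3), 1 + s %% 3,
                            noise_sd = 0.2 + 0.05 * (s %% 5),
                            score_sd = 0.5 + 0.1 * (s %% 3), seed = 100 + s)
    sim <- simulate_supcp_tensor(spec)
    fit <- fit_supcp(sim$tensor, sim$supervision, R = spec$rank, seed = s)
    tr <- fit$loglik_trace
    expect_true(all(diff(tr) > -1e-8 * pmax(abs(tr[-1]), 1)),
                info = paste("spec", s))
  }
})

test_that("the noise variance is recovered within 20%", {
  spec <- tensor_sim_spec(100, c(8, 6, 4), 3, noise_sd = 0.5, score_sd = 1,
                          seed = 5)
  sim <- simulate_supcp_tensor(spec)
  fit <- fit_supcp(sim$tensor, sim$supervision, R = 3, seed = 6)
  expect_lt(abs(fit$noise_var - 0.25) / 0.25, 0.2)
})

test_that("marginal likelihood equals the dense Gaussian oracle", {
  set.seed(42)
  for (case in 1:8) {
    dims <- sample(2:3, 3, replace = TRUE)
    R <- sample(1:2, 1)
    spec <- tensor_sim_spec(12, dims, R, noise_sd = 0.3, seed = 200 + case)
    sim <- simulate_supcp_tensor(spec)
    fit <- fit_supcp(sim$tensor, sim$supervision, R = R, seed = case,
                     max_iter = 50)
    flat <- matrix(sim$tensor$array, nrow = 12)
    for (i in c(1, 7)) {
      got <- marginal_log_likelihood(fit, flat[i, ], sim$supervision[i, ])
      want <- oracle_marginal_ll(fit, flat[i, ], sim$supervision[i, ])
      expect_equal(got, want, tolerance = 1e-8)
      expect_true(is.finite(exp(got)) && exp(got) >= 0)
    }
  }
})

test_that("jointly permuting factor order leaves the likelihood unchanged", {
  spec <- tensor_sim_spec(15, c(4, 3, 3), 3, noise_sd = 0.4, seed = 33)
  sim <- simulate_supcp_tensor(spec)
  fit <- fit_supcp(sim$tensor, sim$supervision, R = 3, seed = 3,
                   max_iter = 40)
  flat <- matrix(sim$tensor$array, nrow = 15)
  ll0 <- marginal_log_likelihood(fit, flat[2, ], sim$supervision[2, ])
  perm <- c(3, 1, 2)
  fit2 <- fit
  fit2$factor_matrices <- lapply(fit$factor_matrices,
                                 function(V) V[, perm, drop = FALSE])
  fit2$coeff_matrix <- fit$coeff_matrix[, perm, drop = FALSE]
  fit2$score_var <- fit$score_var[perm]
  expect_equal(marginal_log_likelihood(fit2, flat[2, ],
                                       sim$supervision[2, ]), ll0,
               tolerance = 1e-10)
})

test_that("dimension mismatches and infeasible ranks error", {
  spec <- tensor_sim_spec(10, c(3, 3, 2), 2, seed = 1)
  sim <- simulate_supcp_tensor(spec)
  fit <- fit_supcp(sim$tensor, sim$supervision, R = 2, seed = 1,
                   max_iter = 20)
  expect_error(marginal_log_likelihood(fit, rnorm(5), c(1, 0)), "entries")
  expect_error(fit_supcp(sim$tensor, sim$supervision, R = 100), "infeasible")
  expect_error(fit_supcp(sim$tensor, sim$supervision[1:3, , drop = FALSE],
                         R = 2), "rows")
})

test_that("with a lone intercept column B reduces to per-factor means", {
  spec <- tensor_sim_spec(60, c(6, 5, 4), 2, noise_sd = 0.3, seed = 8)
  sim <- simulate_supcp_tensor(spec)
  fit <- fit_supcp(sim$tensor, matrix(1, 60, 1), R = 2, seed = 2,
                   add_intercept = FALSE)
  expect_equal(as.numeric(fit$coeff_matrix), colMeans(fit$scores),
               tolerance = 1e-3)
})

test_that("refitting with different seeds recovers the same factor set", {
  spec <- tensor_sim_spec(30, c(6, 5, 4), 2, noise_sd = 0, seed = 21)
  sim <- simulate_supcp_tensor(spec)
  fa <- fit_supcp(sim$tensor, sim$supervision, R = 2, seed = 1)
  fb <- fit_supcp(sim$tensor, sim$supervision, R = 2, seed = 99)
  for (k in 1:3) {
    expect_gt(min(factor_congruence(fa$factor_matrices[[k]],
                                    fb$factor_matrices[[k]])), 0.99)
  }
})

test_that("factor reports rank by |association| and apply the 0.2 rule", {
  spec <- tensor_sim_spec(40, c(5, 4, 3), 2, noise_sd = 0.2, seed = 14)
  sim <- simulate_supcp_tensor(spec)
  fit <- fit_supcp(sim$tensor, sim$supervision, R = 2, seed = 4,
                   max_iter = 60)
  # outcome identical to one factor's participant weights: |r| = 1, rank 1
  outcome <- fit$scores[, 2]
  rep_ <- extract_factor_report(fit, outcome)
  expect_equal(rep_$factor[1], 2)
  expect_equal(abs(rep_$r[1]), 1, tolerance = 1e-12)
  expect_identical(rep_$rank, 1:2)
  expect_true(all(abs(rep_$r[rep_$retained]) > 0.2))
  expect_true(all(abs(rep_$r[!rep_$retained]) <= 0.2))
  # constant outcome flags rather than erroring
  rep0 <- extract_factor_report(fit, rep(1, 40))
  expect_true(all(rep0$flag == "constant weights" | rep0$r == 0))
})

test_that("model serialization round-trips", {
  spec <- tensor_sim_spec(12, c(4, 3, 2), 2, noise_sd = 0.3, seed = 17)
  sim <- simulate_supcp_tensor(spec)
  fit <- fit_supcp(sim$tensor, sim$supervision, R = 2, seed = 2,
                   max_iter = 30)
  path <- file.path(tempdir(), "model")
  write_supcp_model(fit, path)
  back <- read_supcp_model(path)
  expect_equal(back$coeff_matrix, fit$coeff_matrix, ignore_attr = TRUE)
  expect_equal(back$score_var, fit$score_var)
  expect_equal(back$noise_var, fit$noise_var)
  flat <- matrix(sim$tensor$array, nrow = 12)
  expect_equal(marginal_log_likelihood(back, flat[1, ], sim$supervision[1, ]),
               marginal_log_likelihood(fit, flat[1, ], sim$supervision[1, ]))
})
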