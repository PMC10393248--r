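# Synthetic-data generators: generative identities, seed contracts, and the
# configured age/group effects measured through the real feature pipeline.

mean_measure_by_participant <- function(ft, measure) {
  agg <- aggregate(value ~ participant, ft[ft$measure == measure, ], mean)
  stats::setNames(agg$value, agg$participant)
}

test_that("noiseless tensor simulation is exactly the rank-R model", {
  spec <- tensor_sim_spec(12, c(6, 5, 4), 3, noise_sd = 0, score_sd = 0,
                          seed = 3)
  sim <- simulate_supcp_tensor(spec)
  flat <- matrix(sim$tensor$array, nrow = 12)
  expect_equal(max(abs(flat - sim$truth$signal)), 0)
  # multilinear rank: the (R+1)-th singular value of every unfolding is null
  arr <- sim$tensor$array
  for (k in 2:4) {
    perm <- c(k, setdiff(1:4, k))
    unf <- matrix(aperm(arr, perm), nrow = dim(arr)[k])
    sv <- svd(unf)$d
    expect_lt(sv[4] / sv[1], 1e-10)
  }
})

test_that("tensor simulation honours the seed contract", {
  spec <- tensor_sim_spec(10, c(4, 3, 3), 2, noise_sd = 0.3, seed = 9)
  a <- simulate_supcp_tensor(spec)
  b <- simulate_supcp_tensor(spec)
  expect_identical(a$tensor$array, b$tensor$array)
  expect_identical(a$supervision, b$supervision)
  spec2 <- tensor_sim_spec(10, c(4, 3, 3), 2, noise_sd = 0.3, seed = 10)
  c_ <- simulate_supcp_tensor(spec2)
  expect_false(identical(a$tensor$array, c_$tensor$array))
})

test_that("the generated noise field has the requested spread", {
  spec <- tensor_sim_spec(200, c(8, 6, 4), 3, noise_sd = 0.5, seed = 21)
  sim <- simulate_supcp_tensor(spec)
  flat <- matrix(sim$tensor$array, nrow = 200)
  noise <- flat - sim$truth$signal
  expect_lt(abs(sd(noise) - 0.5) / 0.5, 0.05)
})

test_that("infeasible tensor specs are rejected", {
  expect_error(simulate_supcp_tensor(tensor_sim_spec(10, c(4, 3, 3), 5)),
               "exceeds")
  expect_error(tensor_sim_spec(10, c(4, 3), 2, noise_sd = -1))
})

test_that("cohort recordings have the configured shape", {
  spec <- cohort_sim_spec(group_sizes = c(healthy_control = 2), ages = c(3L, 5L),
                          fs = 500, duration = 30, n_channels = 19, seed = 4)
  coh <- simulate_eeg_cohort(spec)
  expect_length(coh$recordings, 2)
  expect_equal(dim(coh$recordings[[1]]$data), c(19, 15000))
  expect_identical(coh$recordings[[1]]$channel_labels, eegdyn_1020_labels())
  expect_setequal(names(coh$participants),
                  c("id", "group", "age_code", "sex", "birthweight",
                    "age_initial", "det_weight"))
  expect_error(cohort_sim_spec(group_sizes = c(healthy_control = 2),
                               duration = 0), "duration")
  expect_error(cohort_sim_spec(group_sizes = c(healthy_control = 2),
                               n_channels = 0), "channel")
})

test_that("cohort generation honours the seed contract", {
  spec <- cohort_sim_spec(group_sizes = c(healthy_control = 2),
                          duration = 2, n_channels = 3, seed = 12)
  a <- simulate_eeg_cohort(spec)
  b <- simulate_eeg_cohort(spec)
  expect_identical(a$recordings[[1]]$data, b$recordings[[1]]$data)
  expect_identical(a$participants, b$participants)
  spec2 <- cohort_sim_spec(group_sizes = c(healthy_control = 2),
                           duration = 2, n_channels = 3, seed = 13)
  expect_false(identical(a$recordings[[1]]$data,
                         simulate_eeg_cohort(spec2)$recordings[[1]]$data))
})

test_that("a null cohort shows no sample-entropy trend across ages", {
  spec <- cohort_sim_spec(group_sizes = c(healthy_control = 50),
                          age_effect = 0, group_effect = 0, n_channels = 4,
                          fs = 500, duration = 4, seed = 101)
  coh <- simulate_eeg_cohort(spec)
  ft <- compute_cohort_features(coh$recordings, start_s = 0.5,
                                duration_s = 1.25)
  se <- mean_measure_by_participant(ft, "SampE")
  r <- cor(se[coh$participants$id], coh$participants$age_code,
           method = "spearman")
  expect_lt(abs(r), 0.2)
})

test_that("a positive age effect raises sample entropy with age", {
  spec <- cohort_sim_spec(group_sizes = c(healthy_control = 48),
                          age_effect = 1, group_effect = 0, n_channels = 4,
                          fs = 500, duration = 4, seed = 102)
  coh <- simulate_eeg_cohort(spec)
  ft <- compute_cohort_features(coh$recordings, start_s = 0.5,
                                duration_s = 1.25)
  se <- mean_measure_by_participant(ft, "SampE")
  r <- cor(se[coh$participants$id], coh$participants$age_code,
           method = "spearman")
  expect_gt(r, 0)
})

test_that("the determinism gap between groups grows with the group effect", {
  gaps <- vapply(c(0.2, 0.5, 1.0), function(ge) {
    spec <- cohort_sim_spec(group_sizes = c(healthy_control = 20,
                                            anxiety = 20),
                            ages = rep(5L, 40), age_effect = 0.5,
                            group_effect = ge, n_channels = 4, fs = 500,
                            duration = 4, seed = 103)
    coh <- simulate_eeg_cohort(spec)
    ft <- compute_cohort_features(coh$recordings, start_s = 0.5,
                                  duration_s = 1.25)
    dt <- mean_measure_by_participant(ft, "DET")
    grp <- stats::setNames(coh$participants$group, coh$participants$id)
    mean(dt[grp[names(dt)] == "anxiety"]) -
      mean(dt[grp[names(dt)] == "healthy_control"])
  }, numeric(1))
  expect_true(all(diff(gaps) >= 0))
  expect_gt(gaps[3], 0)
})

test_that("recordings and participant tables round-trip as text", {
  spec <- cohort_sim_spec(group_sizes = c(healthy_control = 1, anxiety = 1),
                          duration = 2, n_channels = 3, seed = 30)
  coh <- simulate_eeg_cohort(spec)
  path <- file.path(tempdir(), "participants.tsv")
  write_participant_table(coh$participants, path)
  back <- read_participant_table(path)
  expect_equal(back$id, coh$participants$id)
  expect_equal(back$birthweight, coh$participants$birthweight)
  rp <- file.path(tempdir(), "cohort_rec.edf")
  write_recording(coh$recordings[[1]], rp)
  rec <- read_recording(rp)
  expect_equal(dim(rec$data), dim(coh$recordings[[1]]$data))
})
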