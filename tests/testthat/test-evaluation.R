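# Bayes-rule posteriors, AUROC/Brier scoring, stratified cross-validation
# mechanics (fold rule, leakage), and the age-regression suite.

# small synthetic feature tensor with a planted group shift: case
# participants shifted by +delta on a fixed random pattern
planted_tensor <- function(n_per = 10, dims = c(6, 4, 3), delta = 2,
                           groups = c("healthy_control", "anxiety"),
                           seed = 1) {
  n <- n_per * length(groups)
  withr::with_seed(seed, {
    pattern <- array(rnorm(prod(dims)), dims)
    pattern <- pattern / sqrt(sum(pattern^2))
    arr <- array(rnorm(n * prod(dims), sd = 1), c(n, dims))
    shift <- c(healthy_control = 0, anxiety = delta, externalizing = -delta)
    grp <- rep(groups, each = n_per)
    for (i in seq_len(n)) {
      arr[i, , , ] <- arr[i, , , ] + shift[grp[i]] * pattern
    }
    ids <- sprintf("Q%03d", seq_len(n))
    axes <- list(participant = ids,
                 measure = paste0("m", seq_len(dims[1])),
                 channel = paste0("c", seq_len(dims[2])),
                 band = paste0("b", seq_len(dims[3])))
    list(tensor = feature_tensor(arr, axes),
         participants = data.frame(id = ids, group = grp,
                                   sex = rep(0:1, length.out = n),
                                   birthweight = round(rnorm(n, 3541, 701)),
                                   stringsAsFactors = FALSE))
  })
}

test_that("posteriors follow Bayes rule and normalize", {
  p <- posterior_class_probs(c(a = -10, b = -10), c(0.5, 0.5))
  expect_equal(as.numeric(p), c(0.5, 0.5))
  expect_equal(attr(p, "predicted"), 1)  # tie goes to the first class
  p2 <- posterior_class_probs(c(a = -5, b = -3), c(0.5, 0.5))
  expect_equal(sum(p2), 1)
  expect_true(all(p2 >= 0 & p2 <= 1))
  expect_equal(attr(p2, "predicted"), 2)
  # matches a directly computed Bayes ratio
  expect_equal(p2[["b"]], exp(-3) / (exp(-5) + exp(-3)))
  # priors shift the posterior
  p3 <- posterior_class_probs(c(a = -5, b = -5), c(0.9, 0.1))
  expect_equal(as.numeric(p3), c(0.9, 0.1))
  expect_error(posterior_class_probs(c(-Inf, -Inf), c(0.5, 0.5)), "-Inf")
  expect_error(posterior_class_probs(c(-1, -2), c(0.7, 0.7)), "sum to 1")
})

test_that("AUROC equals pair counting and is rank-invariant", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  s <- c(0.1, 0.4, 0.35, 0.8)
  l <- c(0, 0, 1, 1)
  expect_equal(auroc(s, l), oracle_auroc(s, l))
  set.seed(6)
  for (i in 1:10) {
    sc <- rnorm(30)
    lb <- rbinom(30, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(auroc(sc, lb), oracle_auroc(sc, lb), tolerance = 1e-12)
    expect_equal(auroc(exp(2 * sc) + 5, lb), auroc(sc, lb))
  }
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("Brier score is the mean squared probability error", {
  expect_equal(brier(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0)
  expect_equal(brier(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.25)
  probs <- c(0.9, 0.2, 0.6, 0.4, 0.75)
  labs <- c(1, 0, 1, 0, 0)
  expect_equal(brier(probs, labs), mean((probs - labs)^2))
})

test_that("a planted group difference is classified almost perfectly", {
  pl <- planted_tensor(n_per = 10, delta = 5, seed = 2)
  cfg <- covariate_config(contrast = c("anxiety", "healthy_control"))
  cv <- crossval_classify(pl$tensor, pl$participants, cfg, R = 5, k = 5,
                          seed = 3)
  expect_gte(cv$auroc, 0.9)
  expect_lte(cv$brier, 0.15)
  # pipeline metrics equal recomputation from the posterior table
  expect_equal(cv$auroc, auroc(cv$table$posterior_case, cv$table$label))
  expect_equal(cv$brier, brier(cv$table$posterior_case, cv$table$label))
  # every participant held out exactly once, posteriors normalized
  expect_true(all(table(cv$table$id) == 1))
  expect_equal(cv$table$posterior_case + cv$table$posterior_control,
               rep(1, nrow(cv$table)), tolerance = 1e-10)
})

test_that("the n-fold rule engages when the minority group is small", {
  pl <- planted_tensor(n_per = 10, delta = 2, seed = 4)
  keep <- c(1:10, 11:13)  # 10 controls, 3 cases
  arr <- eegdyn:::slice_participants(pl$tensor$array, keep)
  tens <- feature_tensor(arr, c(list(participant =
                                       pl$tensor$axes$participant[keep]),
                                pl$tensor$axes[-1]))
  cfg <- covariate_config(contrast = c("anxiety", "healthy_control"))
  cv <- crossval_classify(tens, pl$participants[keep, ], cfg, R = 3, k = 5,
                          seed = 5)
  expect_equal(cv$k, 3)
  expect_equal(length(cv$fold_sizes), 3)
})

test_that("held-out participants do not influence the fitted fold model", {
  pl <- planted_tensor(n_per = 6, delta = 2, seed = 7)
  cfg <- covariate_config(contrast = c("anxiety", "healthy_control"))
  folds <- list(c(1, 2, 7, 8), c(3, 4, 9, 10), c(5, 6, 11, 12))
  cv_full <- crossval_classify(pl$tensor, pl$participants, cfg, R = 3,
                               seed = 9, folds = folds)
  # remove test participant 1 from the study entirely: the training sets of
  # every fold are unchanged, so shared held-out posteriors must be identical
  keep <- 2:12
  arr <- eegdyn:::slice_participants(pl$tensor$array, keep)
  tens2 <- feature_tensor(arr, c(list(participant =
                                        pl$tensor$axes$participant[keep]),
                                 pl$tensor$axes[-1]))
  folds2 <- lapply(folds, function(f) setdiff(f, 1) - 1L)
  cv_drop <- crossval_classify(tens2, pl$participants[keep, ], cfg, R = 3,
                               seed = 9, folds = folds2)
  # only fold 1 keeps an unchanged training set (the removed participant was
  # held out there); its remaining test participants must score identically
  shared <- intersect(cv_full$table$id[cv_full$table$fold == 1],
                      cv_drop$table$id[cv_drop$table$fold == 1])
  expect_gt(length(shared), 0)
  for (id in shared) {
    expect_equal(cv_full$table$posterior_case[cv_full$table$id == id],
                 cv_drop$table$posterior_case[cv_drop$table$id == id],
                 tolerance = 1e-10)
  }
})

test_that("merging groups with opposing signatures degrades the AUROC", {
  pl <- planted_tensor(n_per = 8, delta = 2.5,
                       groups = c("healthy_control", "anxiety",
                                  "externalizing"), seed = 11)
  cfg_anx <- covariate_config(contrast = c("anxiety", "healthy_control"))
  cfg_ext <- covariate_config(contrast = c("externalizing",
                                           "healthy_control"))
  auc_anx <- crossval_classify(pl$tensor, pl$participants, cfg_anx, R = 4,
                               seed = 13)$auroc
  auc_ext <- crossval_classify(pl$tensor, pl$participants, cfg_ext, R = 4,
                               seed = 13)$auroc
  pt_comb <- pl$participants
  pt_comb$group[pt_comb$group %in% c("anxiety", "externalizing")] <-
    "anxiety"  # pooled "atypical" class under one label
  cfg_comb <- covariate_config(contrast = c("anxiety", "healthy_control"))
  auc_comb <- crossval_classify(pl$tensor, pt_comb, cfg_comb, R = 4,
                                seed = 13)$auroc
  expect_lt(auc_comb, min(auc_anx, auc_ext))
})

test_that("cross-validation refuses leaky or degenerate setups", {
  pl <- planted_tensor(n_per = 6, seed = 15)
  cfg <- covariate_config(contrast = c("anxiety", "healthy_control"))
  std <- standardize_tensor(pl$tensor)
  expect_error(crossval_classify(std, pl$participants, cfg), "raw tensor")
  expect_error(crossval_classify(pl$tensor, pl$participants,
                                 covariate_config()), "contrast")
})

test_that("age regression is exact in the noiseless linear limit", {
  set.seed(20)
  ages <- rep(c(1, 3, 5, 7), each = 8)
  lat <- cbind(f1 = ages * 0.5 - 1, f2 = ages * -0.25 + 2)
  ar <- age_regression(lat, ages, k = 5, seed = 1, regressors = "linear")
  expect_gte(ar$r[1], 0.99)
  expect_lte(ar$mae[1], 0.1)
  expect_error(age_regression(lat[, integer(0)], ages), "retained")
  expect_error(age_regression(cbind(rep(1, 32)), ages), "constant")
})

test_that("the regression suite reports every requested regressor", {
  set.seed(21)
  ages <- rep(c(1, 3, 5, 7), each = 10)
  lat <- cbind(ages + rnorm(40, sd = 0.8), rnorm(40))
  ar <- age_regression(lat, ages, k = 5, seed = 2)
  expect_setequal(ar$regressor,
                  c("linear", "knn", "random_forest", "svm_rbf"))
  expect_true(all(is.finite(ar$r)))
  expect_equal(ar$r_squared, ar$r^2)
  preds <- attr(ar, "predictions")
  expect_equal(dim(preds), c(40, 4))
})
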