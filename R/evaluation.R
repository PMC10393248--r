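# Probabilistic classification with Bayes rule over SupCP marginal
# likelihoods, stratified cross-validation, AUROC / Brier scoring, and the
# age-regression suite over retained latent factors.

#' Posterior class probabilities by Bayes rule
#'
#' Softmax of log-likelihood plus log prior per class. The predicted label is
#' the class with the highest posterior; exact ties resolve to the first
#' class in the supplied (canonical) order.
#'
#' @param logliks Named numeric vector of per-class log-likelihoods, or a
#'   matrix (participants x classes).
#' @param priors Prior probabilities, same length/order as the classes; must
#'   sum to 1.
#' @return For a vector input, a named numeric vector of posteriors summing
#'   to 1 with attribute `predicted`; for a matrix, a matrix of posteriors
#'   with attribute `predicted` (a vector).
#' @export
posterior_class_probs <- function(logliks, priors) {
  if (abs(sum(priors) - 1) > 1e-8) stop("posterior_class_probs: priors must",
                                        " sum to 1")
  one <- function(ll) {
    if (all(!is.finite(ll) & ll < 0)) {
      stop("posterior_class_probs: all class log-likelihoods are -Inf")
    }
    z <- ll + log(priors)
    z <- z - max(z)
    p <- exp(z) / sum(exp(z))
    structure(p, predicted = unname(which.max(p)))
  }
  if (is.matrix(logliks)) {
    post <- t(apply(logliks, 1, function(ll) as.numeric(one(ll))))
    colnames(post) <- colnames(logliks)
    structure(post, predicted = apply(post, 1, which.max))
  } else {
    one(logliks)
  }
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive case receives a higher score
#' than a randomly chosen negative case, ties counted one half (the
#' Mann-Whitney statistic; computed through pROC with the positive-direction
#' convention fixed, so 1 = perfect ranking and 0 = perfectly inverted).
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels 0/1 (or two-level) outcome.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(factor(labels)) - 1
  if (length(unique(labels)) < 2) {
    stop("auroc: both classes must be present")
  }
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Brier score
#'
#' Mean squared difference between the predicted probability of the positive
#' class and the 0/1 outcome.
#'
#' @param probs Predicted positive-class probabilities in `[0, 1]`.
#' @param labels 0/1 (or two-level) outcome.
#' @return Brier score in `[0, 1]`; lower is better.
#' @export
brier <- function(probs, labels) {
  labels <- as.numeric(factor(labels)) - 1
  stopifnot(all(probs >= 0 & probs <= 1))
  mean((probs - labels)^2)
}

# stratified fold assignment (list of test-index vectors), seeded
make_stratified_folds <- function(labels, k, seed) {
  with_seed(seed, caret::createFolds(factor(labels), k = k,
                                     list = TRUE, returnTrain = FALSE))
}

#' Cross-validated probabilistic classification
#'
#' Stratified k-fold cross-validation of the SupCP classifier. Within each
#' fold the per-cell standardization constants and the factorization are
#' computed from the training participants only; each held-out participant
#' is scored by the marginal likelihood of their tensor slice under each
#' candidate class (with their known covariates fixed), converted to
#' posteriors by Bayes rule. Folds are reduced to the minority-class size
#' when that is below `k` (n-fold rule).
#'
#' @param tensor A raw (unstandardized) `feature_tensor`.
#' @param participant_table Data frame with `id`, `group` and any covariates
#'   the configuration needs; rows for every tensor participant.
#' @param config A [covariate_config()] with a two-group contrast.
#' @param R Factorization rank (default 30).
#' @param k Requested number of folds (default 5).
#' @param seed Seed for fold assignment and factorization initialization.
#' @param priors `"proportions"` (training-fold class frequencies) or
#'   `"uniform"`.
#' @param folds Optional explicit list of test-index vectors (overrides the
#'   stratified assignment).
#' @param tol,max_iter Passed to [fit_supcp()].
#' @param average_folds Report the mean of per-fold AUROCs instead of the
#'   pooled-score AUROC (default FALSE: pooled).
#' @return Object of class `crossval_result`: `table` (per-participant fold,
#'   posterior for each class, predicted and true label), `auroc`, `brier`,
#'   `k`, `fold_sizes`, `fold_logliks`.
#' @export
crossval_classify <- function(tensor, participant_table, config, R = 30,
                              k = 5, seed = 1, priors = c("proportions",
                                                          "uniform"),
                              folds = NULL, tol = 1e-6, max_iter = 200,
                              average_folds = FALSE) {
  stopifnot(inherits(tensor, "feature_tensor"),
            inherits(config, "covariate_config"))
  priors <- match.arg(priors)
  if (is.null(config$contrast)) {
    stop("crossval_classify: configuration must define a two-group contrast")
  }
  if (!is.null(tensor$normalization)) {
    stop("crossval_classify: pass a raw tensor; standardization is done ",
         "per training fold to avoid leakage")
  }
  ids <- tensor$axes$participant
  pt <- participant_table[match(ids, participant_table$id), , drop = FALSE]
  if (anyNA(pt$id)) stop("crossval_classify: participant table incomplete")
  keep <- which(pt$group %in% config$contrast)
  if (length(keep) < length(ids)) {
    arr <- slice_participants(tensor$array, keep)
    tensor <- feature_tensor(arr, c(list(participant = ids[keep]),
                                    tensor$axes[-1]))
    pt <- pt[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  labels <- as.numeric(pt$group == config$contrast[1])  # case = 1
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < 2)) {
    stop("crossval_classify: both contrast groups need at least 2 members")
  }
  k_eff <- min(k, min(counts))
  if (is.null(folds)) {
    folds <- make_stratified_folds(labels, k_eff, seed)
  } else {
    k_eff <- length(folds)
  }

  covars <- config$covariates
  Ycov <- if (length(covars)) {
    encode_covariates(pt, covariate_config(covariates = covars))
  } else {
    NULL
  }

  n <- length(ids)
  post <- matrix(NA_real_, n, 2, dimnames = list(ids, config$contrast[2:1]))
  fold_id <- integer(n)
  fold_ll <- numeric(length(folds))
  arr <- tensor$array

  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    if (length(unique(labels[train])) < 2) {
      stop("crossval_classify: a class is empty in training fold ", f)
    }
    st <- tensor_cell_stats(arr, rows = train)
    arr_std <- apply_standardization(arr, st)
    Xtr <- slice_participants(arr_std, train)
    Ytr <- cbind(class = labels[train])
    if (!is.null(Ycov)) Ytr <- cbind(Ytr, Ycov[train, , drop = FALSE])
    fit <- fit_supcp(Xtr, Ytr, R = R, tol = tol, max_iter = max_iter,
                     seed = seed + f)
    fold_ll[f] <- tail(fit$loglik_trace, 1)
    pr <- if (priors == "proportions") {
      c(mean(labels[train] == 0), mean(labels[train] == 1))
    } else {
      c(0.5, 0.5)
    }
    flat_std <- matrix(arr_std, nrow = n)
    for (i in test) {
      ll <- vapply(c(0, 1), function(cl) {
        y_star <- c(class = cl)
        if (!is.null(Ycov)) y_star <- c(y_star, Ycov[i, ])
        marginal_log_likelihood(fit, flat_std[i, ], y_star)
      }, numeric(1))
      p <- posterior_class_probs(stats::setNames(ll, c("0", "1")), pr)
      post[i, ] <- as.numeric(p)
      fold_id[i] <- f
    }
  }

  predicted <- ifelse(post[, 2] > post[, 1], config$contrast[1],
                      config$contrast[2])
  tbl <- data.frame(id = ids, fold = fold_id, group = pt$group,
                    label = labels,
                    posterior_control = post[, 1], posterior_case = post[, 2],
                    predicted = predicted, stringsAsFactors = FALSE)
  # explicit fold lists may leave participants without a held-out prediction
  tbl <- tbl[tbl$fold > 0, , drop = FALSE]
  rownames(tbl) <- NULL
  auc_val <- if (average_folds) {
    mean(vapply(seq_along(folds), function(f) {
      sel <- tbl$fold == f
      auroc(tbl$posterior_case[sel], tbl$label[sel])
    }, numeric(1)))
  } else {
    auroc(tbl$posterior_case, tbl$label)
  }
  structure(list(table = tbl, auroc = auc_val,
                 brier = brier(tbl$posterior_case, tbl$label),
                 k = k_eff, fold_sizes = lengths(folds),
                 fold_logliks = fold_ll, contrast = config$contrast,
                 covariates = covars, R = R, seed = seed),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf(paste0("crossval_result: %s vs %s, %d folds, AUROC %.3f, ",
                     "Brier %.3f\n"), x$contrast[1], x$contrast[2], x$k,
              x$auroc, x$brier))
  invisible(x)
}

# first-mode subsetting that keeps remaining dims
slice_participants <- function(arr, rows) {
  d <- dim(arr)
  flat <- matrix(arr, nrow = d[1])[rows, , drop = FALSE]
  array(flat, c(length(rows), d[-1]))
}

#' Write per-participant posteriors and a JSON summary of a CV run
#'
#' @param cv A `crossval_result`.
#' @param path Path prefix; writes `<path>.tsv` (posterior table) and
#'   `<path>.json` (AUROC, Brier, fold sizes).
#' @export
write_crossval_result <- function(cv, path) {
  stopifnot(inherits(cv, "crossval_result"))
  utils::write.table(cv$table, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(auroc = cv$auroc, brier = cv$brier, k = cv$k,
                            fold_sizes = as.numeric(cv$fold_sizes),
                            contrast = cv$contrast,
                            covariates = cv$covariates, rank = cv$R),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Cross-validated age regression over latent factors
#'
#' Feeds retained latent-factor scores to a suite of standard regressors
#' (linear model, k-nearest neighbours, random forest, radial-kernel SVM) and
#' reports cross-validated correlation, coefficient of determination (r^2)
#' and mean absolute error per regressor. This stage is thin glue around
#' stock regressors; the information content lives in the latent factors.
#'
#' @param latent_features Numeric matrix (participants x retained factors).
#' @param ages Numeric outcome (age per participant).
#' @param k Number of CV folds.
#' @param seed Fold-assignment seed.
#' @param regressors Subset of `c("linear", "knn", "random_forest",
#'   "svm_rbf")`.
#' @return Data frame with one row per regressor: `regressor`, `r`,
#'   `r_squared`, `mae`; attribute `predictions` holds the per-regressor
#'   cross-validated predictions.
#' @export
age_regression <- function(latent_features, ages, k = 5, seed = 1,
                           regressors = c("linear", "knn", "random_forest",
                                          "svm_rbf")) {
  X <- as.matrix(latent_features)
  if (ncol(X) == 0) {
    stop("age_regression: no retained latent factors; lower the |r| ",
         "threshold or strengthen supervision")
  }
  if (any(apply(X, 2, stats::sd) < 1e-12)) {
    stop("age_regression: constant latent feature column; factors carry no ",
         "information")
  }
  ages <- as.numeric(ages)
  stopifnot(nrow(X) == length(ages))
  regressors <- match.arg(regressors, several.ok = TRUE)
  folds <- with_seed(seed, caret::createFolds(ages, k = k, list = TRUE,
                                              returnTrain = FALSE))
  preds <- matrix(NA_real_, nrow(X), length(regressors),
                  dimnames = list(NULL, regressors))
  for (f in folds) {
    tr <- setdiff(seq_len(nrow(X)), f)
    dtr <- data.frame(y = ages[tr], X[tr, , drop = FALSE])
    dte <- data.frame(X[f, , drop = FALSE])
    names(dtr)[-1] <- paste0("f", seq_len(ncol(X)))
    names(dte) <- paste0("f", seq_len(ncol(X)))
    for (m in regressors) {
      preds[f, m] <- switch(
        m,
        linear = {
          fit <- stats::lm(y ~ ., data = dtr)
          unname(stats::predict(fit, dte))
        },
        knn = {
          fit <- caret::knnreg(dtr[-1], dtr$y, k = min(5, length(tr)))
          unname(stats::predict(fit, dte))
        },
        random_forest = with_seed(seed + 7, {
          # coded ages have few unique values; the forest's regression
          # warning about that is expected here
          fit <- suppressWarnings(
            randomForest::randomForest(dtr[-1], dtr$y, ntree = 300))
          unname(stats::predict(fit, dte))
        }),
        svm_rbf = {
          fit <- e1071::svm(y ~ ., data = dtr, kernel = "radial")
          unname(stats::predict(fit, dte))
        })
    }
  }
  out <- do.call(rbind, lapply(regressors, function(m) {
    r <- stats::cor(preds[, m], ages)
    data.frame(regressor = m, r = r, r_squared = r^2,
               mae = mean(abs(preds[, m] - ages)))
  }))
  attr(out, "predictions") <- preds
  out
}
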