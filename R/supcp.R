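# Supervised canonical polyadic (SupCP) factorization.
#
# Generative model for participant i with vectorized tensor slice x_i (D = prod
# of non-participant mode dimensions):
#
#   x_i = W u_i + e_i,     u_i = B' y_i + f_i,
#   f_i ~ N(0, Sigma_f) (diagonal),  e_i ~ N(0, sigma2 I_D),
#
# where W (D x R) is the column-wise Khatri-Rao product of the per-mode
# loading matrices V_k (d_k x R, unit-norm columns) and y_i is the row of the
# supervision matrix (class indicator + covariates). Marginally over u_i,
#
#   x_i ~ N(W B' y_i,  W Sigma_f W' + sigma2 I),
#
# which is the likelihood used for probabilistic classification. Fitting is
# by expectation-conditional-maximization: the E-step gives the conditional
# mean/covariance of u_i; each M-step block (each V_k, then B, Sigma_f,
# sigma2) has a closed form. The observed-data log-likelihood is evaluated
# with the Woodbury identity and must be non-decreasing across iterations.

# column-wise Khatri-Rao: out[, r] = kron(A[, r], B[, r])
khatri_rao_cols <- function(A, B) {
  out <- matrix(0, nrow(A) * nrow(B), ncol(A))
  for (r in seq_len(ncol(A))) out[, r] <- kronecker(A[, r], B[, r])
  out
}

# W from the loading list (first mode varying fastest in vec())
build_w <- function(V_list) {
  Reduce(function(acc, Vk) khatri_rao_cols(Vk, acc), V_list[-1], V_list[[1]])
}

# observed-data log-likelihood via Woodbury (shared across i)
supcp_loglik <- function(X, Y, W, B, sigf, s2) {
  n <- nrow(X)
  D <- ncol(X)
  G <- crossprod(W)
  A <- diag(1 / sigf, length(sigf)) + G / s2
  R_mat <- X - tcrossprod(Y %*% B, W)
  P <- R_mat %*% W
  qf <- rowSums(R_mat^2) / s2 -
    colSums(t(P) * solve(A, t(P))) / s2^2
  logdet <- D * log(s2) + as.numeric(determinant(A)$modulus) + sum(log(sigf))
  -0.5 * (n * D * log(2 * pi) + n * logdet + sum(qf))
}

# greedy factor matching by absolute cosine similarity (permutation + sign)
#' Congruence between two factor matrices
#'
#' Greedily matches columns of `A` to columns of `B` by largest absolute
#' cosine similarity (resolving the permutation and sign indeterminacy of CP
#' factors) and returns the matched similarities.
#'
#' @param A,B Matrices with the same number of rows.
#' @return Numeric vector of matched absolute congruence coefficients (one
#'   per column of `A`), plus attribute `perm` giving the matched column of
#'   `B` for each column of `A`.
#' @export
factor_congruence <- function(A, B) {
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  C <- abs(crossprod(An, Bn))
  perm <- integer(ncol(A))
  cong <- numeric(ncol(A))
  work <- C
  for (step in seq_len(min(ncol(A), ncol(B)))) {
    best <- which(work == max(work), arr.ind = TRUE)[1, ]
    perm[best[1]] <- best[2]
    cong[best[1]] <- C[best[1], best[2]]
    work[best[1], ] <- -Inf
    work[, best[2]] <- -Inf
  }
  structure(cong, perm = perm)
}

as_participant_matrix <- function(X) {
  if (inherits(X, "feature_tensor")) {
    arr <- X$array
    list(mat = matrix(arr, nrow = dim(arr)[1]), dims = dim(arr)[-1],
         axes = X$axes)
  } else if (is.array(X) && length(dim(X)) >= 2) {
    arr <- as.array(X)
    list(mat = matrix(arr, nrow = dim(arr)[1]), dims = dim(arr)[-1],
         axes = NULL)
  } else {
    stop("fit_supcp: X must be a feature_tensor or an array with ",
         "participants on the first mode")
  }
}

#' Fit the supervised CP factorization by EM
#'
#' Maximum-likelihood fit of the SupCP model (see the package vignette): a
#' rank-`R` CP structure whose participant scores are regressed on the
#' supervision matrix `Y`, with diagonal residual score covariance and
#' isotropic entrywise noise. Initialization draws random orthonormal-ish
#' loadings from the given seed; every M-step block is closed-form, so the
#' observed-data log-likelihood ascends monotonically.
#'
#' @param X A `feature_tensor` or numeric array, participants first.
#' @param Y Supervision matrix (participants x q); an intercept column is
#'   prepended unless `add_intercept = FALSE`.
#' @param R Rank (number of latent factors), default 30.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations.
#' @param seed Integer seed for the random components of initialization.
#' @param add_intercept Prepend an intercept column to `Y` (default TRUE).
#' @param init `"hosvd"` (default): start each loading matrix from the top
#'   singular vectors of the corresponding mode unfolding, padded with seeded
#'   random orthonormal columns when the rank exceeds the mode dimension;
#'   `"random"`: seeded random orthonormal loadings.
#' @return Object of class `supcp_model`: `factor_matrices` (one unit-norm
#'   loading matrix per non-participant mode), `coeff_matrix` (q x R),
#'   `score_var` (diagonal of Sigma_f), `noise_var`, `scores` (conditional
#'   means of U), `loglik_trace`, `rank`, `dims`, `converged`.
#' @export
fit_supcp <- function(X, Y, R = 30, tol = 1e-6, max_iter = 500, seed = 1,
                      add_intercept = TRUE, init = c("hosvd", "random")) {
  init <- match.arg(init)
  xp <- as_participant_matrix(X)
  Xm <- xp$mat
  dims <- xp$dims
  n <- nrow(Xm)
  D <- ncol(Xm)
  if (anyNA(Xm)) stop("fit_supcp: tensor contains NA; complete cases only")
  Y <- as.matrix(Y)
  if (nrow(Y) != n) {
    stop("fit_supcp: Y has ", nrow(Y), " rows but the tensor has ", n,
         " participants")
  }
  if (add_intercept) {
    Y <- cbind(`(intercept)` = 1, Y)
  }
  q <- ncol(Y)
  if (R < 1 || R > D) {
    stop("fit_supcp: rank ", R, " infeasible for ", D,
         " entries per participant")
  }
  K <- length(dims)

  # initialization: per-mode spectral (HOSVD) loadings, seeded random
  # orthonormal-ish columns where the mode is too small or on request
  arr_init <- array(Xm, c(n, dims))
  V <- with_seed(seed, lapply(seq_len(K), function(k) {
    d <- dims[k]
    rand_cols <- function(m) {
      M <- matrix(stats::rnorm(d * m), d, m)
      if (d >= m) qr.Q(qr(M)) else sweep(M, 2, sqrt(colSums(M^2)), "/")
    }
    if (init == "random") return(rand_cols(R))
    perm <- c(k + 1, 1, setdiff(seq_len(K), k) + 1)
    Xk <- matrix(aperm(arr_init, perm), nrow = d)
    sv <- svd(Xk, nu = min(d, R), nv = 0)
    Vk <- sv$u
    if (ncol(Vk) < R) Vk <- cbind(Vk, rand_cols(R - ncol(Vk)))
    Vk
  }))
  B <- matrix(0, q, R)
  sigf <- rep(1, R)
  s2 <- stats::var(as.numeric(Xm))
  if (!is.finite(s2) || s2 <= 0) s2 <- 1

  ssX <- sum(Xm^2)
  YtY <- crossprod(Y)
  arr_full <- array(Xm, c(n, dims))
  trace <- numeric(0)
  converged <- FALSE
  # noise floor scaled to the data: below this the model is effectively
  # noiseless and the likelihood surface is flat (and numerically fragile)
  s2_floor <- 1e-8 * max(s2, 1e-12)
  s2_floored <- FALSE

  for (it in seq_len(max_iter)) {
    W <- build_w(V)
    ll <- supcp_loglik(Xm, Y, W, B, sigf, s2)
    if (!is.finite(ll)) {
      stop("fit_supcp: non-finite log-likelihood at iteration ", it)
    }
    trace <- c(trace, ll)
    if (s2_floored) {
      converged <- TRUE
      break
    }
    if (it > 1) {
      rel <- (ll - trace[it - 1]) / (abs(trace[it - 1]) + 1e-12)
      if (abs(rel) < tol) {
        converged <- TRUE
        break
      }
    }

    # E-step
    G <- crossprod(W)
    A <- diag(1 / sigf, R) + G / s2
    Sigma_u <- solve(A)
    Sigma_u <- (Sigma_u + t(Sigma_u)) / 2
    Mu_prior <- Y %*% B
    M <- (Xm %*% W / s2 + sweep(Mu_prior, 2, sigf, "/")) %*% Sigma_u
    S_uu <- n * Sigma_u + crossprod(M)   # sum_i E[u_i u_i']

    # M-step: loadings, mode by mode
    for (k in seq_len(K)) {
      # matricize with mode k first, then participants, then other modes
      perm <- c(k + 1, 1, setdiff(seq_len(K), k) + 1)
      Xk <- matrix(aperm(arr_full, perm), nrow = dims[k])
      Z <- M
      for (j in setdiff(seq_len(K), k)) Z <- khatri_rao_cols(V[[j]], Z)
      had <- S_uu
      for (j in setdiff(seq_len(K), k)) had <- had * crossprod(V[[j]])
      V[[k]] <- t(solve(had, t(Xk %*% Z)))
    }

    # M-step: regression coefficients, score variances, noise variance
    B <- solve(YtY, crossprod(Y, M))
    Resid <- M - Y %*% B
    sigf <- pmax(diag(Sigma_u) + colSums(Resid^2) / n, 1e-10)
    W <- build_w(V)
    G <- crossprod(W)
    s2_new <- (ssX - 2 * sum((Xm %*% W) * M) + sum(G * S_uu)) / (n * D)
    if (s2_new < s2_floor) {
      s2 <- s2_floor
      s2_floored <- TRUE
    } else {
      s2 <- s2_new
    }

    # renormalize loading columns; absorb scale into B, Sigma_f (invariant)
    for (k in seq_len(K)) {
      nrm <- sqrt(colSums(V[[k]]^2))
      nrm[nrm < 1e-300] <- 1
      V[[k]] <- sweep(V[[k]], 2, nrm, "/")
      B <- sweep(B, 2, nrm, "*")
      sigf <- sigf * nrm^2
    }
  }

  W <- build_w(V)
  # final conditional scores under the converged parameters
  G <- crossprod(W)
  A <- diag(1 / sigf, R) + G / s2
  Sigma_u <- solve(A)
  M <- (Xm %*% W / s2 + sweep(Y %*% B, 2, sigf, "/")) %*% Sigma_u

  axis_names <- if (!is.null(xp$axes)) names(xp$axes)[-1] else
    paste0("mode", seq_len(K))
  names(V) <- axis_names
  for (k in seq_len(K)) {
    if (!is.null(xp$axes)) rownames(V[[k]]) <- xp$axes[[k + 1]]
  }
  structure(list(rank = R, factor_matrices = V, coeff_matrix = B,
                 score_var = sigf, noise_var = s2, scores = M,
                 loglik_trace = trace, dims = dims, q = q,
                 y_colnames = colnames(Y), add_intercept = add_intercept,
                 converged = converged, seed = seed),
            class = "supcp_model")
}

#' @export
print.supcp_model <- function(x, ...) {
  cat(sprintf(paste0("supcp_model: rank %d, modes %s, %d participants, ",
                     "loglik %.2f (%d iterations%s)\n"),
              x$rank, paste(x$dims, collapse = " x "), nrow(x$scores),
              tail(x$loglik_trace, 1), length(x$loglik_trace),
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Marginal log-likelihood of one participant slice
#'
#' Log density of a single participant's tensor slice under the fitted
#' model's Gaussian marginal (latent scores integrated out): a multivariate
#' normal with mean `W B' y` and covariance `W Sigma_f W' + sigma2 I`,
#' evaluated via the Woodbury identity. This is the quantity exponentiated
#' into the class likelihood during probabilistic classification.
#'
#' @param model A `supcp_model`.
#' @param x_i Numeric slice with the model's non-participant dimensions (any
#'   shape with the right number of entries).
#' @param y_i Supervision row (length q, without the intercept if the model
#'   added one).
#' @return Log-likelihood (scalar).
#' @export
marginal_log_likelihood <- function(model, x_i, y_i) {
  stopifnot(inherits(model, "supcp_model"))
  x <- as.numeric(x_i)
  D <- prod(model$dims)
  if (length(x) != D) {
    stop("marginal_log_likelihood: slice has ", length(x),
         " entries, model expects ", D)
  }
  y <- as.numeric(y_i)
  if (model$add_intercept) y <- c(1, y)
  if (length(y) != model$q) {
    stop("marginal_log_likelihood: supervision row has wrong length")
  }
  W <- build_w(model$factor_matrices)
  supcp_loglik(matrix(x, 1), matrix(y, 1), W, model$coeff_matrix,
               model$score_var, model$noise_var)
}

#' Rank latent factors by association with an outcome
#'
#' Computes, for every latent factor, the correlation between the
#' participant score column and the outcome (Pearson r; for a binary
#' outcome this is the point-biserial correlation) together with its p-value,
#' ranks factors by `|r|`, and marks the retained set `|r| > threshold`
#' (default 0.2).
#'
#' @param model A `supcp_model`.
#' @param outcome Numeric vector (e.g. age) or two-level vector (group).
#' @param threshold Retention threshold on `|r|`.
#' @return Data frame of class `latent_factor_report`: `factor`, `r`, `p`,
#'   `rank`, `retained`, `flag`, ordered by decreasing `|r|`, with the
#'   per-mode weight vectors in attribute `weights` and participant scores
#'   in attribute `scores`.
#' @export
extract_factor_report <- function(model, outcome, threshold = 0.2) {
  stopifnot(inherits(model, "supcp_model"))
  U <- model$scores
  if (is.factor(outcome) || is.character(outcome) || is.logical(outcome)) {
    outcome <- as.numeric(factor(outcome)) - 1
  }
  outcome <- as.numeric(outcome)
  if (length(outcome) != nrow(U)) {
    stop("extract_factor_report: outcome length must match participants")
  }
  res <- lapply(seq_len(model$rank), function(r) {
    u <- U[, r]
    if (stats::sd(u) < 1e-12 || stats::sd(outcome) < 1e-12) {
      data.frame(factor = r, r = 0, p = 1, flag = "constant weights")
    } else {
      ct <- suppressWarnings(stats::cor.test(u, outcome))
      data.frame(factor = r, r = unname(ct$estimate), p = ct$p.value,
                 flag = "")
    }
  })
  rep_df <- do.call(rbind, res)
  ord <- order(-abs(rep_df$r))
  rep_df <- rep_df[ord, ]
  rep_df$rank <- seq_len(nrow(rep_df))
  rep_df$retained <- abs(rep_df$r) > threshold
  rownames(rep_df) <- NULL
  attr(rep_df, "weights") <- lapply(model$factor_matrices, function(V) {
    V[, rep_df$factor, drop = FALSE]
  })
  attr(rep_df, "scores") <- model$scores[, rep_df$factor, drop = FALSE]
  class(rep_df) <- c("latent_factor_report", "data.frame")
  rep_df
}

#' Serialize a fitted SupCP model (JSON metadata + binary arrays)
#'
#' @param model A `supcp_model`.
#' @param path Path prefix; writes `<path>.json` and `<path>.bin`.
#' @export
write_supcp_model <- function(model, path) {
  stopifnot(inherits(model, "supcp_model"))
  arrays <- c(lapply(model$factor_matrices, as.numeric),
              list(coeff = as.numeric(model$coeff_matrix),
                   score_var = model$score_var,
                   scores = as.numeric(model$scores),
                   loglik_trace = model$loglik_trace))
  lens <- vapply(arrays, length, integer(1))
  con <- file(paste0(path, ".bin"), "wb")
  for (a in arrays) writeBin(as.numeric(a), con, size = 8, endian = "little")
  close(con)
  meta <- list(rank = model$rank, dims = model$dims, q = model$q,
               noise_var = model$noise_var, seed = model$seed,
               add_intercept = model$add_intercept,
               y_colnames = model$y_colnames,
               n_participants = nrow(model$scores),
               mode_names = names(model$factor_matrices),
               array_lengths = as.list(lens))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a serialized SupCP model
#'
#' @param path Path prefix used in [write_supcp_model()].
#' @return A `supcp_model`.
#' @export
read_supcp_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  lens <- unlist(meta$array_lengths)
  vals <- lapply(lens, function(L) {
    readBin(con, "numeric", n = L, size = 8, endian = "little")
  })
  K <- length(meta$dims)
  V <- lapply(seq_len(K), function(k) {
    matrix(vals[[k]], meta$dims[k], meta$rank)
  })
  names(V) <- meta$mode_names
  structure(list(rank = meta$rank, factor_matrices = V,
                 coeff_matrix = matrix(vals[[K + 1]], meta$q, meta$rank),
                 score_var = vals[[K + 2]], noise_var = meta$noise_var,
                 scores = matrix(vals[[K + 3]], meta$n_participants,
                                 meta$rank),
                 loglik_trace = vals[[K + 4]], dims = meta$dims, q = meta$q,
                 y_colnames = meta$y_colnames,
                 add_intercept = meta$add_intercept, converged = NA,
                 seed = meta$seed),
            class = "supcp_model")
}
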