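# Independent oracles used across the suite: brute-force implementations kept
# deliberately separate from the package's computational paths.

# O(N^2) template-counting sample entropy (Richman-Moorman convention)
oracle_sampen <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  N <- length(x)
  nt <- N - m
  A <- 0
  B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dB <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dB <= r) {
        B <- B + 1
        if (max(dB, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (B == 0) return(NA_real_)
  -log(A / B)
}

# exhaustive run-length enumeration of a binary recurrence plot
oracle_rqa <- function(mat, theiler = 1, lmin = 2, vmin = 2) {
  mat <- mat != 0
  n <- nrow(mat)
  runs_of <- function(v) {
    r <- rle(v)
    r$lengths[r$values]
  }
  white_runs_of <- function(v) {
    r <- rle(v)
    r$lengths[!r$values]
  }
  dl <- integer(0)
  for (off in setdiff(-(n - 1):(n - 1), (-(theiler - 1)):(theiler - 1))) {
    idx <- if (off >= 0) cbind(1:(n - off), (1 + off):n) else
      cbind((1 - off):n, 1:(n + off))
    dl <- c(dl, runs_of(mat[idx]))
  }
  vl <- integer(0)
  wl <- integer(0)
  for (j in 1:n) {
    vl <- c(vl, runs_of(mat[, j]))
    wl <- c(wl, white_runs_of(mat[, j]))
  }
  dlk <- dl[dl >= lmin]
  vlk <- vl[vl >= vmin]
  ent <- function(lens) {
    if (!length(lens)) return(0)
    p <- table(lens) / length(lens)
    -sum(p * log(p))
  }
  c(RR = (sum(mat) - sum(diag(mat))) / (n * (n - 1)),
    DET = if (sum(dl) > 0) sum(dlk) / sum(dl) else 0,
    LAM = if (sum(vl) > 0) sum(vlk) / sum(vl) else 0,
    TT = if (length(vlk)) mean(vlk) else 0,
    Lentr = ent(dlk),
    Lmax = if (length(dlk)) max(dlk) else 0,
    Lmean = if (length(dlk)) mean(dlk) else 0,
    VertEnt = ent(vlk),
    AvgVertWhiteLen = if (length(wl)) mean(wl) else 0)
}

# Mann-Whitney pair counting AUROC (ties counted half)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# dense multivariate-normal marginal log-likelihood for a SupCP model
oracle_marginal_ll <- function(model, x, y) {
  V <- model$factor_matrices
  W <- Reduce(function(acc, Vk) {
    out <- matrix(0, nrow(Vk) * nrow(acc), ncol(acc))
    for (r in seq_len(ncol(acc))) out[, r] <- kronecker(Vk[, r], acc[, r])
    out
  }, V[-1], V[[1]])
  yfull <- if (model$add_intercept) c(1, y) else y
  mu <- as.numeric(W %*% crossprod(model$coeff_matrix, yfull))
  D <- length(mu)
  S <- W %*% (model$score_var * t(W)) + model$noise_var * diag(D)
  dev <- as.numeric(x) - mu
  -0.5 * (D * log(2 * pi) + as.numeric(determinant(S)$modulus) +
            as.numeric(t(dev) %*% solve(S, dev)))
}

# FFT band energy fraction of a real signal
oracle_band_energy <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- abs(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  sum(sp[freqs >= lo & freqs <= hi]) / sum(sp)
}

# random symmetric binary recurrence plot with recurrent diagonal
random_rp_matrix <- function(n, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rbinom(n * n, 1, p), n, n)
    m <- (m + t(m)) > 0
    diag(m) <- TRUE
    m
  })
}

# small complete long-format feature table for tensor tests
synthetic_feature_table <- function(n_participants = 6, ages = 1L,
                                    channels = eegdyn_1020_labels(),
                                    bands = eegdyn_bands(), seed = 1) {
  grid <- expand.grid(participant = sprintf("P%02d", seq_len(n_participants)),
                      age_code = ages, channel = channels, band = bands,
                      measure = eegdyn_measures(),
                      stringsAsFactors = FALSE)
  grid$value <- withr::with_seed(seed, stats::rnorm(nrow(grid)))
  grid
}

# roster consistent with the published cohort counts: 111 healthy controls;
# 29 anxiety (25 single, 4 double; SP 19, SAD 10, GAD 4); 10 externalizing
# (7 single, 3 double; ADHD 8, ODD 4, CD 1; one comorbid MDD); 2 comorbid
# anxiety+externalizing and 1 PTSD-only, both excluded
reference_roster <- function() {
  dx <- c(rep(list(character(0)), 111),
          rep(list("SP"), 15), rep(list("SAD"), 7), rep(list("GAD"), 3),
          rep(list(c("SP", "SAD")), 3), list(c("SP", "GAD")),
          rep(list("ADHD"), 4), list(c("ADHD", "MDD")),
          rep(list("ODD"), 2),
          rep(list(c("ADHD", "ODD")), 2), list(c("ADHD", "CD")),
          list(c("GAD", "ADHD")), list(c("SAD", "ODD")),
          list("PTSD"))
  names(dx) <- sprintf("C%03d", seq_along(dx))
  dx
}
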