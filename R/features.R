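# Nonlinear dynamical measures computed per (channel, band) sub-signal:
# sample entropy, correlation dimension, DFA, and nine recurrence-plot
# measures under a fixed-recurrence-rate thresholding convention.

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B), where B counts pairs of length-`m` templates and A
#' pairs of length-`m+1` templates within Chebyshev distance `r` of each other,
#' self-matches excluded. Both counts run over the first `N - m` template start
#' positions (the Richman-Moorman convention). Lower values indicate a more
#' regular, self-similar signal.
#'
#' @param x Numeric series.
#' @param m Template length (default 2).
#' @param r_frac Tolerance as a fraction of `sd(x)` (default 0.2); ignored if
#'   `r` is given.
#' @param r Absolute tolerance; overrides `r_frac`.
#' @return A single number; `NA` (with attribute `reason`) when no length-`m`
#'   template pair matches so the statistic is undefined; `Inf` when template
#'   matches never extend to length `m + 1`.
#' @export
sample_entropy <- function(x, m = 2, r_frac = 0.2, r = NULL) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("sample_entropy: input contains NA")
  if (length(x) < m + 2) {
    stop("sample_entropy: need at least m + 2 = ", m + 2, " samples, got ",
         length(x))
  }
  if (is.null(r)) r <- r_frac * stats::sd(x)
  cnt <- cpp_sampen_counts(x, as.integer(m), as.numeric(r))
  if (cnt$B == 0) {
    return(structure(NA_real_, reason = "no m-length template matches (B = 0)"))
  }
  -log(cnt$A / cnt$B)
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Estimates attractor dimensionality as the slope of the log correlation sum
#' versus log radius. The series is delay-embedded (`emb_dim`, `delay`), the
#' correlation sum C(r) is the fraction of embedded pairs (separated in time by
#' at least `theiler` samples) within Euclidean distance r, and the slope is
#' fit by least squares over an automatically selected scaling region
#' (radii where C(r) is small but supported by enough pairs).
#'
#' @param x Numeric series.
#' @param emb_dim Embedding dimension (default 10, matching the recurrence
#'   analysis).
#' @param delay Embedding delay in samples.
#' @param theiler Temporal exclusion window for pairs (default
#'   `emb_dim * delay`, suppressing trivially close successive states).
#' @param n_radii Number of log-spaced radii probed.
#' @return Estimated dimension (positive real).
#' @export
correlation_dimension <- function(x, emb_dim = 10, delay = 1,
                                  theiler = emb_dim * delay, n_radii = 24) {
  x <- as.numeric(x)
  N <- length(x)
  if (stats::sd(x) == 0) {
    stop("correlation_dimension: constant series has zero spread")
  }
  if (N <= (emb_dim - 1) * delay + 10) {
    stop("correlation_dimension: series too short for embedding dimension ",
         emb_dim)
  }
  ne <- N - (emb_dim - 1) * delay
  # deterministic subsample of embedded states to set the radius grid
  idx <- unique(round(seq(1, ne, length.out = min(ne, 400))))
  emb <- sapply(seq_len(emb_dim), function(k) x[idx + (k - 1) * delay])
  dsub <- as.numeric(stats::dist(emb))
  qs <- stats::quantile(dsub[dsub > 0], c(0.003, 0.5), names = FALSE)
  radii <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_radii))
  cc <- cpp_corr_counts(x, as.integer(emb_dim), as.integer(delay), radii,
                        as.integer(theiler))
  C <- cc$counts / cc$n_pairs
  keep <- C >= max(10 / cc$n_pairs, 1e-5) & C <= 0.2
  if (sum(keep) < 4) keep <- C > 0 & C <= 0.5
  if (sum(keep) < 2) stop("correlation_dimension: no usable scaling region")
  fit <- stats::lm(log(C[keep]) ~ log(radii[keep]))
  unname(coef(fit)[2])
}

#' Detrended fluctuation analysis exponent
#'
#' Integrates the mean-removed series into a profile, splits the profile into
#' non-overlapping boxes of log-spaced sizes, removes a polynomial trend of
#' order `order` per box, and returns the slope alpha of log RMS fluctuation
#' versus log box size. alpha = 0.5 for white noise, 1.5 for its cumulative
#' sum (Brownian motion); intermediate values indicate long-range correlation.
#'
#' @param x Numeric series.
#' @param min_box,max_box Smallest / largest box size in samples.
#' @param order Detrending polynomial order (default 1, linear).
#' @param n_boxes Number of log-spaced box sizes.
#' @return Scaling exponent alpha.
#' @export
dfa <- function(x, min_box = 4, max_box = floor(length(x) / 4), order = 1,
                n_boxes = 20) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 16 * min_box) {
    stop("dfa: need at least 16 * min_box = ", 16 * min_box,
         " samples, got ", N)
  }
  prof <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(min_box), log(max_box),
                                length.out = n_boxes))))
  sizes <- sizes[sizes >= order + 2 & sizes <= N]
  flucts <- vapply(sizes, function(n) {
    nwin <- N %/% n
    segs <- matrix(prof[seq_len(nwin * n)], nrow = n)  # one window per column
    X <- outer(seq_len(n), 0:order, `^`)
    res <- stats::lm.fit(X, segs)$residuals
    sqrt(sum(res^2) / (nwin * n))
  }, numeric(1))
  ok <- flucts > 0
  fit <- stats::lm(log(flucts[ok]) ~ log(sizes[ok]))
  unname(coef(fit)[2])
}

#' Embedding and recurrence configuration
#'
#' Parameters for time-delay embedding and fixed-recurrence-rate recurrence
#' plots: embedding dimension `emb_dim` (default 10), `delay` in samples,
#' target recurrence rate (default 0.05), Euclidean distance norm, Theiler
#' exclusion half-width (default 1: exclude the line of identity only) and
#' minimum diagonal/vertical line lengths `lmin`/`vmin` (default 2).
#'
#' @param emb_dim,delay Embedding dimension and delay.
#' @param recurrence_rate Target fraction of recurrent off-diagonal pairs.
#' @param norm Distance metric; only `"euclidean"` is implemented.
#' @param theiler Exclude diagonals with offset `|i - j| < theiler` from
#'   diagonal-line measures.
#' @param lmin,vmin Minimum diagonal / vertical line lengths.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(emb_dim = 10, delay = 1, recurrence_rate = 0.05,
                             norm = "euclidean", theiler = 1, lmin = 2,
                             vmin = 2) {
  stopifnot(emb_dim >= 1, delay >= 1, recurrence_rate > 0,
            recurrence_rate < 1, lmin >= 2, vmin >= 2, theiler >= 1)
  norm <- match.arg(norm, "euclidean")
  structure(list(emb_dim = as.integer(emb_dim), delay = as.integer(delay),
                 recurrence_rate = recurrence_rate, norm = norm,
                 theiler = as.integer(theiler), lmin = as.integer(lmin),
                 vmin = as.integer(vmin)),
            class = "embedding_config")
}

#' Recurrence plot with fixed recurrence rate
#'
#' Delay-embeds the series, computes all pairwise Euclidean distances between
#' embedded states, and thresholds at the distance quantile that attains the
#' target recurrence rate over off-diagonal pairs. The main diagonal (line of
#' identity) is recurrent by construction and excluded from the attained-rate
#' bookkeeping.
#'
#' @param x Numeric series.
#' @param config An [embedding_config()].
#' @return Object of class `recurrence_plot`: fields `matrix` (N x N logical,
#'   symmetric), `epsilon` (attained distance threshold), `attained_rr`, and
#'   `config`.
#' @export
recurrence_matrix <- function(x, config = embedding_config()) {
  x <- as.numeric(x)
  m <- config$emb_dim
  tau <- config$delay
  N <- length(x)
  if (N <= (m - 1) * tau + 2) {
    stop("recurrence_matrix: series too short for embedding (need > ",
         (m - 1) * tau + 2, " samples)")
  }
  if (stats::sd(x) == 0) {
    stop("recurrence_matrix: constant series; fixed-RR threshold is undefined",
         " (all embedded distances are zero)")
  }
  ne <- N - (m - 1) * tau
  if (ne > 6000) {
    stop("recurrence_matrix: ", ne, " embedded states would need a ",
         "prohibitively large plot; analyse a shorter segment")
  }
  d <- cpp_embed_dists(x, m, tau)
  k <- max(1L, round(config$recurrence_rate * length(d)))
  eps <- sort(d, partial = k)[k]
  rp <- cpp_recurrence_from_dists(d, ne, eps)
  new_recurrence_plot(rp, epsilon = eps, config = config,
                      attained_rr = mean(d <= eps))
}

#' Construct a recurrence-plot object from an explicit binary matrix
#'
#' Wraps a precomputed symmetric binary matrix (e.g. a hand-built test case)
#' in the same container returned by [recurrence_matrix()].
#'
#' @param matrix Square logical/0-1 matrix.
#' @param epsilon Distance threshold, if known.
#' @param config An [embedding_config()].
#' @param attained_rr Off-diagonal recurrence fraction; computed from the
#'   matrix when missing.
#' @return Object of class `recurrence_plot`.
#' @export
new_recurrence_plot <- function(matrix, epsilon = NA_real_,
                                config = embedding_config(),
                                attained_rr = NULL) {
  matrix <- matrix != 0
  stopifnot(nrow(matrix) == ncol(matrix))
  if (!isTRUE(all(matrix == t(matrix)))) {
    stop("recurrence plot matrix must be symmetric")
  }
  if (is.null(attained_rr)) {
    n <- nrow(matrix)
    attained_rr <- (sum(matrix) - sum(diag(matrix))) / (n * (n - 1))
  }
  structure(list(matrix = matrix, epsilon = epsilon,
                 attained_rr = attained_rr, config = config),
            class = "recurrence_plot")
}

#' @export
print.recurrence_plot <- function(x, ...) {
  cat(sprintf("recurrence plot: %d x %d, attained RR %.4f, epsilon %.4g\n",
              nrow(x$matrix), ncol(x$matrix), x$attained_rr, x$epsilon))
  invisible(x)
}

line_entropy <- function(lengths) {
  if (length(lengths) == 0) return(0)
  p <- tabulate(lengths)
  p <- p[p > 0] / length(lengths)
  -sum(p * log(p))
}

#' Recurrence quantification measures
#'
#' Computes the seven recurrence-quantification values from a recurrence plot:
#' recurrence rate (`RR`), determinism (`DET`, fraction of recurrence points
#' on diagonal lines of length >= `lmin`), laminarity (`LAM`, vertical
#' analogue with `vmin`), trapping time (`TT`, mean vertical line length >=
#' `vmin`), diagonal line length entropy (`Lentr`, Shannon entropy in nats of
#' the distribution of diagonal lengths >= `lmin`), and the maximum and mean
#' diagonal line lengths (`Lmax`, `Lmean`). Diagonal-line measures exclude
#' diagonals with offset `< theiler` (so the line of identity never counts);
#' vertical-line measures scan full columns. Empty line distributions yield 0.
#'
#' @param rp A `recurrence_plot`.
#' @return Named numeric vector `RR, DET, LAM, TT, Lentr, Lmax, Lmean`.
#' @export
rqa_measures <- function(rp) {
  stopifnot(inherits(rp, "recurrence_plot"))
  cfg <- rp$config
  runs <- cpp_line_runs(rp$matrix, cfg$theiler)
  dl <- runs$diagonal
  vl <- runs$vertical
  dl_keep <- dl[dl >= cfg$lmin]
  vl_keep <- vl[vl >= cfg$vmin]
  det <- if (sum(dl) > 0) sum(dl_keep) / sum(dl) else 0
  lam <- if (sum(vl) > 0) sum(vl_keep) / sum(vl) else 0
  c(RR = rp$attained_rr,
    DET = det,
    LAM = lam,
    TT = if (length(vl_keep)) mean(vl_keep) else 0,
    Lentr = line_entropy(dl_keep),
    Lmax = if (length(dl_keep)) max(dl_keep) else 0,
    Lmean = if (length(dl_keep)) mean(dl_keep) else 0)
}

#' Vertical-line recurrence measures
#'
#' `VertEnt` is the Shannon entropy (nats) of the distribution of recurrent
#' vertical line lengths >= `vmin`; `AvgVertWhiteLen` is the mean length of
#' vertical runs of non-recurrent ("white") points, scanned over full columns
#' (the always-recurrent line of identity bounds white runs naturally). Empty
#' distributions yield 0.
#'
#' @param rp A `recurrence_plot`.
#' @return Named numeric vector `VertEnt, AvgVertWhiteLen`.
#' @export
vertical_line_measures <- function(rp) {
  stopifnot(inherits(rp, "recurrence_plot"))
  cfg <- rp$config
  runs <- cpp_line_runs(rp$matrix, cfg$theiler)
  vl_keep <- runs$vertical[runs$vertical >= cfg$vmin]
  wl <- runs$white_vertical
  c(VertEnt = line_entropy(vl_keep),
    AvgVertWhiteLen = if (length(wl)) mean(wl) else 0)
}

#' Feature-extraction configuration
#'
#' Bundles the constants of the twelve-measure computation: sample-entropy
#' template length and tolerance fraction, correlation-dimension embedding,
#' DFA box limits, and the recurrence [embedding_config()].
#'
#' @param sampen_m,sampen_r_frac Sample entropy template length and tolerance
#'   fraction of the sub-signal SD.
#' @param cd_emb_dim,cd_delay Correlation-dimension embedding.
#' @param dfa_min_box,dfa_order DFA smallest box and detrending order.
#' @param rqa An [embedding_config()] for the recurrence measures.
#' @return List of class `feature_config`.
#' @export
feature_config <- function(sampen_m = 2, sampen_r_frac = 0.2,
                           cd_emb_dim = 10, cd_delay = 1,
                           dfa_min_box = 4, dfa_order = 1,
                           rqa = embedding_config()) {
  structure(list(sampen_m = sampen_m, sampen_r_frac = sampen_r_frac,
                 cd_emb_dim = cd_emb_dim, cd_delay = cd_delay,
                 dfa_min_box = dfa_min_box, dfa_order = dfa_order,
                 rqa = rqa),
            class = "feature_config")
}

# measures from run-length histograms (hist[l] = number of runs of length l)
hist_entropy <- function(h) {
  tot <- sum(h)
  if (tot == 0) return(0)
  p <- h[h > 0] / tot
  -sum(p * log(p))
}

rqa_from_hists <- function(diag_hist, vert_hist, white_hist, attained_rr,
                           lmin, vmin) {
  L <- seq_along(diag_hist)
  dl_pts <- sum(L * diag_hist)
  dl_keep <- diag_hist
  dl_keep[L < lmin] <- 0
  vl_pts <- sum(L * vert_hist)
  vl_keep <- vert_hist
  vl_keep[L < vmin] <- 0
  c(RR = attained_rr,
    DET = if (dl_pts > 0) sum(L * dl_keep) / dl_pts else 0,
    LAM = if (vl_pts > 0) sum(L * vl_keep) / vl_pts else 0,
    TT = if (sum(vl_keep) > 0) sum(L * vl_keep) / sum(vl_keep) else 0,
    Lentr = hist_entropy(dl_keep),
    Lmax = if (sum(dl_keep) > 0) max(L[dl_keep > 0]) else 0,
    Lmean = if (sum(dl_keep) > 0) sum(L * dl_keep) / sum(dl_keep) else 0,
    VertEnt = hist_entropy(vl_keep),
    AvgVertWhiteLen = if (sum(white_hist) > 0) {
      sum(L * white_hist) / sum(white_hist)
    } else {
      0
    })
}

# fast recurrence measures straight from the series (no N x N matrix)
rqa_measures_fast <- function(x, config = embedding_config()) {
  if (stats::sd(x) == 0) {
    stop("recurrence analysis: constant series; fixed-RR threshold is ",
         "undefined (all embedded distances are zero)")
  }
  res <- cpp_rqa_from_series(x, config$emb_dim, config$delay,
                             config$recurrence_rate, config$theiler)
  # C++ histograms are indexed from length 0; drop the empty zero bin
  out <- rqa_from_hists(res$diag_hist[-1], res$vert_hist[-1],
                        res$white_hist[-1], res$attained_rr, config$lmin,
                        config$vmin)
  attr(out, "epsilon") <- res$epsilon
  out
}

# all 12 measures for one sub-signal; returns list(values, reason)
nonlinear_feature_vector <- function(x, config = feature_config()) {
  values <- stats::setNames(rep(NA_real_, 12), eegdyn_measures())
  reasons <- character(0)
  if (anyNA(x)) {
    return(list(values = values, reasons = "sub-signal contains NA"))
  }
  if (stats::sd(x) == 0) {
    return(list(values = values,
                reasons = "degenerate (constant) sub-signal"))
  }
  grab <- function(name, expr) {
    v <- tryCatch(expr, error = function(e) {
      reasons <<- c(reasons, paste0(name, ": ", conditionMessage(e)))
      NA_real_
    })
    if (length(v) == 1 && is.finite(v)) {
      values[name] <<- v
    } else if (!is.na(v)) {
      reasons <<- c(reasons, paste0(name, ": non-finite value"))
    }
    invisible(NULL)
  }
  grab("SampE", sample_entropy(x, m = config$sampen_m,
                               r_frac = config$sampen_r_frac))
  grab("CD", correlation_dimension(x, emb_dim = config$cd_emb_dim,
                                   delay = config$cd_delay))
  grab("DFA", dfa(x, min_box = config$dfa_min_box, order = config$dfa_order))
  rv <- tryCatch(rqa_measures_fast(x, config$rqa), error = function(e) {
    reasons <<- c(reasons, paste0("recurrence: ", conditionMessage(e)))
    NULL
  })
  if (!is.null(rv)) {
    for (nm in names(rv)) values[nm] <- rv[[nm]]
  }
  list(values = values, reasons = reasons)
}

#' Extract the twelve nonlinear measures per channel and band
#'
#' Decomposes each channel of a recording into the six frequency bands (or
#' takes an existing per-channel list of [decompose_bands()] results) and
#' computes the twelve nonlinear measures on every band sub-signal. Failures
#' on degenerate sub-signals are recorded as missing values with a reason,
#' never silently zeroed.
#'
#' @param x An `eeg_recording`, or a named list (one entry per channel) of
#'   `band_signals` objects.
#' @param config A [feature_config()].
#' @return Long-format data frame with columns `channel`, `band`, `measure`,
#'   `value` (exactly 12 rows per channel x band; `NA` where a measure failed)
#'   and an attribute `missing_log`, a data frame of `channel`, `band`,
#'   `reason` rows for every failure.
#' @export
extract_features <- function(x, config = feature_config()) {
  if (inherits(x, "eeg_recording")) {
    chans <- lapply(seq_len(nrow(x$data)), function(i) {
      decompose_bands(x$data[i, ], fs = x$fs)
    })
    names(chans) <- x$channel_labels
  } else if (is.list(x) && all(vapply(x, inherits, logical(1),
                                      "band_signals"))) {
    chans <- x
    if (is.null(names(chans))) {
      names(chans) <- paste0("ch", seq_along(chans))
    }
  } else {
    stop("extract_features: expected an eeg_recording or a list of ",
         "band_signals objects")
  }
  rows <- list()
  log_rows <- list()
  for (ch in names(chans)) {
    bs <- chans[[ch]]
    for (band in bs$band_names) {
      fv <- nonlinear_feature_vector(bs$bands[[band]], config)
      rows[[length(rows) + 1]] <- data.frame(
        channel = ch, band = band, measure = names(fv$values),
        value = unname(fv$values), stringsAsFactors = FALSE)
      if (length(fv$reasons)) {
        log_rows[[length(log_rows) + 1]] <- data.frame(
          channel = ch, band = band, reason = fv$reasons,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "missing_log") <- if (length(log_rows)) {
    do.call(rbind, log_rows)
  } else {
    data.frame(channel = character(0), band = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  out
}
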