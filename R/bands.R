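# Dyadic sub-band decomposition of EEG channels with an orthogonal
# Daubechies-4 (8-tap) discrete wavelet transform. Each named band is the
# time-domain reconstruction of one detail level; the transform is periodized
# (circular), which keeps it exactly orthogonal so that perfect-reconstruction
# and energy-additivity identities hold to machine precision.

# canonical db4 scaling (low-pass reconstruction) filter, 8 taps
DB4_LO <- c(0.2303778133088552, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.1870348117188811, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728)

db4_filters <- function() {
  g <- DB4_LO
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)  # quadrature mirror high-pass
  list(g = g, h = h)
}

# one periodized analysis step: x (even length) -> list(approx, detail)
dwt_step <- function(x, g, h) {
  n <- length(x)
  n2 <- n %/% 2L
  a <- numeric(n2)
  d <- numeric(n2)
  base <- 2L * (seq_len(n2) - 1L)
  for (j in seq_along(g)) {
    idx <- ((base + j - 1L) %% n) + 1L
    a <- a + g[j] * x[idx]
    d <- d + h[j] * x[idx]
  }
  list(a = a, d = d)
}

# one periodized synthesis step (transpose of dwt_step)
idwt_step <- function(a, d, g, h) {
  n2 <- length(a)
  n <- 2L * n2
  x <- numeric(n)
  base <- 2L * (seq_len(n2) - 1L)
  for (j in seq_along(g)) {
    idx <- ((base + j - 1L) %% n) + 1L
    x[idx] <- x[idx] + g[j] * a + h[j] * d
  }
  x
}

wavedec_per <- function(x, n_levels) {
  f <- db4_filters()
  details <- vector("list", n_levels)
  a <- x
  for (lev in seq_len(n_levels)) {
    s <- dwt_step(a, f$g, f$h)
    details[[lev]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

waverec_per <- function(coeffs, n_levels) {
  f <- db4_filters()
  a <- coeffs$approx
  for (lev in rev(seq_len(n_levels))) {
    a <- idwt_step(a, coeffs$details[[lev]], f$g, f$h)
  }
  a
}

# canonical band frequency ranges (Hz) used to assign detail levels
canonical_band_ranges <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30),
       gamma = c(30, 60), gamma_plus = c(60, 120))
}

# best detail level per band: maximise Jaccard overlap between the level's
# dyadic interval [fs/2^(j+1), fs/2^j] and the band's canonical range
assign_band_levels <- function(fs, max_level) {
  ranges <- canonical_band_ranges()
  vapply(ranges, function(rg) {
    scores <- vapply(seq_len(max_level), function(j) {
      lo <- fs / 2^(j + 1)
      hi <- fs / 2^j
      inter <- max(0, min(hi, rg[2]) - max(lo, rg[1]))
      inter / (max(hi, rg[2]) - min(lo, rg[1]))
    }, numeric(1))
    which.max(scores)
  }, integer(1))
}

#' Decompose a signal into six frequency bands by DB4 wavelet details
#'
#' Runs a periodized orthogonal Daubechies-4 discrete wavelet transform and
#' reconstructs one time-domain sub-signal per named band (delta, theta,
#' alpha, beta, gamma, gamma_plus) from the corresponding detail level. At
#' fs = 500 Hz the assignment is D7 -> delta (about 2-3.9 Hz), D6 -> theta
#' (3.9-7.8), D5 -> alpha (7.8-15.6), D4 -> beta (15.6-31.25), D3 -> gamma
#' (31.25-62.5) and D2 -> gamma_plus (62.5-125); at other sampling rates each
#' band gets the detail level whose dyadic interval best overlaps its
#' canonical range. The level-`n_levels` approximation and any unassigned
#' details form the residual, so bands + residual reconstruct the input
#' exactly. Signals whose length is not a multiple of `2^n_levels` are padded
#' cyclically before the transform and trimmed afterwards; reconstruction
#' stays exact, while band energies add to the signal energy exactly only for
#' multiple-of-`2^n_levels` lengths.
#'
#' @param signal Numeric series (one channel).
#' @param fs Sampling rate in Hz.
#' @param wavelet Only `"db4"` is implemented.
#' @param n_levels Decomposition depth; defaults to the deepest level any
#'   band needs at this sampling rate.
#' @return Object of class `band_signals`: `bands` (named list of series, one
#'   per band, each of the input length), `band_names`, `residual`,
#'   `level_map` (band -> detail level), `band_edges` (Hz), `fs`.
#' @export
decompose_bands <- function(signal, fs, wavelet = "db4", n_levels = NULL) {
  signal <- as.numeric(signal)
  if (fs <= 0) stop("decompose_bands: fs must be positive")
  if (!identical(wavelet, "db4")) {
    stop("decompose_bands: only the db4 wavelet is implemented")
  }
  N <- length(signal)
  max_feasible <- floor(log2(max(N, 1)))
  if (is.null(n_levels)) {
    lv <- assign_band_levels(fs, max_level = min(12L, max_feasible))
    n_levels <- max(lv)
  }
  if (N < 2^n_levels) {
    stop("decompose_bands: signal of length ", N, " too short for ",
         n_levels, " decomposition levels (need >= ", 2^n_levels, ")")
  }
  level_map <- assign_band_levels(fs, max_level = n_levels)
  # cyclic padding to a multiple of 2^n_levels
  block <- 2^n_levels
  M <- ceiling(N / block) * block
  xpad <- if (M > N) c(signal, signal[seq_len(M - N)]) else signal
  dec <- wavedec_per(xpad, n_levels)
  recon_level <- function(lev) {
    z <- list(approx = numeric(length(dec$approx)),
              details = lapply(dec$details, function(d) numeric(length(d))))
    z$details[[lev]] <- dec$details[[lev]]
    waverec_per(z, n_levels)[seq_len(N)]
  }
  band_names <- eegdyn_bands()
  bands <- lapply(band_names, function(b) recon_level(level_map[[b]]))
  names(bands) <- band_names
  residual <- signal - Reduce(`+`, bands)
  edges <- lapply(level_map, function(j) c(fs / 2^(j + 1), fs / 2^j))
  structure(list(bands = bands, band_names = band_names, residual = residual,
                 level_map = level_map, band_edges = edges, fs = fs,
                 wavelet = wavelet, n_levels = n_levels, input_length = N,
                 padded_length = M),
            class = "band_signals")
}

#' @export
print.band_signals <- function(x, ...) {
  cat(sprintf("band_signals: %d samples at %g Hz, %d levels (db4)\n",
              x$input_length, x$fs, x$n_levels))
  for (b in x$band_names) {
    cat(sprintf("  %-10s D%d  %.2f-%.2f Hz\n", b, x$level_map[[b]],
                x$band_edges[[b]][1], x$band_edges[[b]][2]))
  }
  invisible(x)
}

#' Write band sub-signals as delimited text
#'
#' One column per band plus the residual; samples as rows.
#'
#' @param bs A `band_signals` object.
#' @param path Output file.
#' @export
write_band_signals <- function(bs, path) {
  stopifnot(inherits(bs, "band_signals"))
  df <- as.data.frame(bs$bands)
  df$residual <- bs$residual
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
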