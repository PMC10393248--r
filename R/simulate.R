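# Synthetic data with known ground truth: (a) supervised low-rank tensors for
# factorization-recovery tests, (b) EEG-like multichannel cohorts whose
# dynamical regularity varies with a synthetic age gradient and with group
# membership, standing in for restricted cohort recordings.

#' Specification for a supervised low-rank tensor simulation
#'
#' @param n_participants Number of participants (rows of the first mode).
#' @param mode_dims Integer vector of non-participant mode dimensions.
#' @param rank Number of rank-1 components R.
#' @param coeff_matrix Supervision-effect matrix B (q x R) mapping the
#'   supervision columns to latent scores; default: class effect `2` on every
#'   factor and one standard-normal covariate with effect `1`.
#' @param score_sd Residual score spread sigma_f (>= 0).
#' @param noise_sd Entrywise noise spread sigma_e (>= 0).
#' @param seed Integer seed.
#' @return List of class `tensor_sim_spec`.
#' @export
tensor_sim_spec <- function(n_participants, mode_dims, rank,
                            coeff_matrix = NULL, score_sd = 1,
                            noise_sd = 0.1, seed = 1) {
  stopifnot(n_participants >= 2, rank >= 1, all(mode_dims >= 1),
            score_sd >= 0, noise_sd >= 0)
  if (is.null(coeff_matrix)) {
    coeff_matrix <- rbind(class = rep(2, rank), cov1 = rep(1, rank))
  }
  structure(list(n_participants = as.integer(n_participants),
                 mode_dims = as.integer(mode_dims), rank = as.integer(rank),
                 coeff_matrix = as.matrix(coeff_matrix),
                 score_sd = score_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "tensor_sim_spec")
}

#' Simulate a supervised low-rank tensor with known ground truth
#'
#' Draws supervision `Y` (a balanced 0/1 class column plus standard-normal
#' covariates, matching the encoding of [encode_covariates()]), scores
#' `U = Y B + F` with `F ~ N(0, score_sd^2)`, orthonormal per-mode loadings,
#' and the tensor as the sum of R rank-1 terms plus entrywise Gaussian noise
#' with spread `noise_sd`. All generating factors are returned so recovery
#' can be scored.
#'
#' @param spec A [tensor_sim_spec()].
#' @return List: `tensor` (raw `feature_tensor`), `supervision` (Y matrix,
#'   class + covariates, no intercept), `truth` (list with `factor_matrices`,
#'   `coeff_matrix`, `scores`, `score_var`, `noise_var`, and the noiseless
#'   participant-by-entries matrix `signal`).
#' @export
simulate_supcp_tensor <- function(spec) {
  stopifnot(inherits(spec, "tensor_sim_spec"))
  dims <- spec$mode_dims
  R <- spec$rank
  if (any(R > dims)) {
    stop("simulate_supcp_tensor: rank ", R, " exceeds a mode dimension (",
         paste(dims, collapse = " x "), "); orthonormal loadings need ",
         "rank <= every mode dimension")
  }
  n <- spec$n_participants
  q <- nrow(spec$coeff_matrix)
  out <- with_seed(spec$seed, {
    cls <- rep(c(0, 1), length.out = n)
    Y <- cbind(class = cls)
    if (q > 1) {
      Y <- cbind(Y, matrix(stats::rnorm(n * (q - 1)), n, q - 1,
                           dimnames = list(NULL, rownames(
                             spec$coeff_matrix)[-1])))
    }
    U <- Y %*% spec$coeff_matrix +
      matrix(stats::rnorm(n * R, sd = spec$score_sd), n, R)
    V <- lapply(dims, function(d) qr.Q(qr(matrix(stats::rnorm(d * R), d, R))))
    W <- build_w(V)
    signal <- tcrossprod(U, W)
    noise <- matrix(stats::rnorm(n * prod(dims), sd = spec$noise_sd),
                    n, prod(dims))
    list(Y = Y, U = U, V = V, signal = signal, X = signal + noise)
  })
  axes <- c(list(participant = paste0("p", seq_len(n))),
            stats::setNames(lapply(seq_along(dims), function(k) {
              paste0("m", k, "_", seq_len(dims[k]))
            }), paste0("mode", seq_along(dims))))
  tens <- feature_tensor(array(out$X, c(n, dims)), axes)
  rownames(out$Y) <- axes$participant
  truth <- list(rank = R, factor_matrices = out$V,
                coeff_matrix = spec$coeff_matrix,
                scores = out$U, score_var = rep(spec$score_sd^2, R),
                noise_var = spec$noise_sd^2, signal = out$signal)
  list(tensor = tens, supervision = out$Y, truth = truth)
}

#' Specification for a synthetic EEG cohort
#'
#' Defines a cohort whose per-channel signals mix, within each canonical
#' frequency band, band-limited Gaussian noise with a deterministic tone
#' shared across channels (plus a small chaotic logistic-map component). The
#' deterministic weight falls with the synthetic age code (signals become
#' more complex/noise-dominated as children grow, raising sample entropy) and
#' shifts with diagnostic group: the anxiety group is more regular (higher
#' deterministic weight, higher recurrence determinism), the externalizing
#' group less regular than healthy controls.
#'
#' @param group_sizes Named integer vector of participants per group; names
#'   from `healthy_control`, `anxiety`, `externalizing`.
#' @param ages Integer age codes (1, 3, 5, 7) per participant; default cycles
#'   through all four within each group.
#' @param age_effect Strength of the age -> complexity gradient (0 = none;
#'   1 sweeps the deterministic weight from 0.85 in infancy down to 0.15 at
#'   7 years).
#' @param group_effect Strength of the group shift (0 = none; 1 shifts the
#'   anxiety weight up by 0.25 and the externalizing weight down by 0.15).
#' @param n_channels Number of channels (19 = the 10-20 montage labels).
#' @param fs Sampling rate in Hz (default 500).
#' @param duration Recording length in seconds (default 30).
#' @param seed Integer seed.
#' @return List of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(group_sizes = c(healthy_control = 20,
                                            anxiety = 20),
                            ages = NULL, age_effect = 0.5, group_effect = 0.5,
                            n_channels = 19, fs = 500, duration = 30,
                            seed = 1) {
  stopifnot(all(group_sizes >= 0), fs > 0)
  if (duration <= 0) stop("cohort_sim_spec: duration must be positive")
  if (n_channels < 1) stop("cohort_sim_spec: need at least one channel")
  if (is.null(names(group_sizes))) {
    stop("cohort_sim_spec: group_sizes must be named")
  }
  bad <- setdiff(names(group_sizes),
                 c("healthy_control", "anxiety", "externalizing"))
  if (length(bad)) stop("cohort_sim_spec: unknown group(s): ",
                        paste(bad, collapse = ", "))
  n <- sum(group_sizes)
  if (is.null(ages)) {
    ages <- unlist(lapply(group_sizes, function(g) {
      rep(c(1L, 3L, 5L, 7L), length.out = g)
    }), use.names = FALSE)
  }
  if (length(ages) != n) {
    stop("cohort_sim_spec: ages must have one entry per participant")
  }
  structure(list(group_sizes = group_sizes, ages = as.integer(ages),
                 age_effect = age_effect, group_effect = group_effect,
                 n_channels = as.integer(n_channels), fs = fs,
                 duration = duration, seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

# band-limited Gaussian noise via FFT masking, unit variance
fft_band_noise <- function(n, fs, lo, hi) {
  z <- stats::rnorm(n)
  f <- stats::fft(z)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # two-sided
  mask <- freqs >= lo & freqs <= hi
  f[!mask] <- 0
  x <- Re(stats::fft(f, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s < 1e-12) stats::rnorm(n) * 0 else x / s
}

logistic_map_series <- function(n, x0, r = 3.99, burn = 100) {
  x <- x0
  for (i in seq_len(burn)) x <- r * x * (1 - x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- r * x * (1 - x)
    out[i] <- x
  }
  (out - mean(out)) / stats::sd(out)
}

# deterministic-component weight for one participant; infancy sits near the
# tone-dominated end (0.85) where every band's entropy responds, and a full
# age effect sweeps down to 0.15 (noise-dominated) by 7 years
det_weight <- function(group, age_code, age_effect, group_effect) {
  w <- 0.85 - age_effect * 0.70 * (age_code - 1) / 6
  w <- w + switch(group,
                  anxiety = 0.25 * group_effect,
                  externalizing = -0.15 * group_effect,
                  healthy_control = 0)
  min(max(w, 0.05), 0.95)
}

#' Simulate a synthetic EEG cohort
#'
#' Generates one recording per participant. Within each of the six canonical
#' frequency bands, every channel mixes independent band-limited Gaussian
#' noise with a participant-level sinusoidal tone (frequencies jittered per
#' participant, phases shared across channels) at deterministic weight `w`
#' from [cohort_sim_spec()]'s age and group effects; a small chaotic
#' logistic-map component rides on the deterministic part. Noise-dominated
#' signals (young/externalizing) have high band sample entropy and lower
#' recurrence determinism; tone-dominated signals (anxiety group) the
#' reverse, so sample entropy rises with age and determinism separates
#' groups. Covariates (sex, birthweight in grams, exact initial-recording
#' age in months) are drawn to match the published cohort summary
#' statistics.
#'
#' @param spec A [cohort_sim_spec()].
#' @return List: `recordings` (list of `eeg_recording`) and `participants`
#'   (data frame `id`, `group`, `age_code`, `sex`, `birthweight`,
#'   `age_initial`, `det_weight`).
#' @export
simulate_eeg_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  n <- sum(spec$group_sizes)
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  nsamp <- round(spec$duration * spec$fs)
  # band edges matched to the dyadic analysis bands at 500 Hz (capped at
  # the actual Nyquist) so every analysis band sees its own tone/noise mix
  nyq <- spec$fs / 2
  band_defs <- lapply(list(c(1, 3.9), c(3.9, 7.8), c(7.8, 15.6),
                           c(15.6, 31.2), c(31.2, 62.5), c(62.5, 125)),
                      function(b) pmin(b, nyq * 0.99))
  band_amp <- c(1, 0.8, 0.6, 0.5, 0.45, 0.4)
  tone_freq <- c(3, 6, 11, 22, 45, 90)
  labels <- if (spec$n_channels == 19) {
    eegdyn_1020_labels()
  } else {
    paste0("ch", seq_len(spec$n_channels))
  }
  tvec <- (seq_len(nsamp) - 1) / spec$fs

  with_seed(spec$seed, {
    participants <- data.frame(
      id = sprintf("S%03d", seq_len(n)),
      group = groups,
      age_code = spec$ages,
      sex = stats::rbinom(n, 1, 0.5),
      birthweight = round(stats::rnorm(n, 3541, 701)),
      age_initial = round(stats::rnorm(n, 7.92, 2.75), 1),
      stringsAsFactors = FALSE)
    recordings <- vector("list", n)
    wts <- numeric(n)
    for (i in seq_len(n)) {
      w <- det_weight(groups[i], spec$ages[i], spec$age_effect,
                      spec$group_effect)
      wts[i] <- w
      jit <- stats::runif(1, 0.95, 1.05)
      phases <- stats::runif(length(tone_freq), 0, 2 * pi)
      tones <- lapply(seq_along(tone_freq), function(b) {
        tn <- sin(2 * pi * min(tone_freq[b] * jit, nyq * 0.9) * tvec +
                    phases[b])
        tn / stats::sd(tn)
      })
      chaos <- logistic_map_series(nsamp, stats::runif(1, 0.2, 0.8))
      data <- matrix(0, spec$n_channels, nsamp)
      for (ch in seq_len(spec$n_channels)) {
        x <- numeric(nsamp)
        for (b in seq_along(band_defs)) {
          nz <- fft_band_noise(nsamp, spec$fs, band_defs[[b]][1],
                               band_defs[[b]][2])
          x <- x + band_amp[b] * ((1 - w) * nz + w * tones[[b]])
        }
        x <- x + 0.08 * w * chaos
        data[ch, ] <- 40 * x / stats::sd(x)
      }
      recordings[[i]] <- eeg_recording(data, fs = spec$fs,
                                       channel_labels = labels,
                                       participant_id = participants$id[i],
                                       age_code = spec$ages[i])
    }
    participants$det_weight <- wts
    list(recordings = recordings, participants = participants)
  })
}

#' Write a cohort participant table as delimited text
#'
#' @param participants Data frame from [simulate_eeg_cohort()].
#' @param path Output file (tab-separated, header row).
#' @export
write_participant_table <- function(participants, path) {
  utils::write.table(participants, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a participant table written by [write_participant_table()]
#'
#' @param path Input file.
#' @return Data frame.
#' @export
read_participant_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
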