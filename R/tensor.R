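# Assembly of long-format feature tables into axis-labelled multiway tensors
# (participant x measure x channel x band, with an optional recording-age
# mode) and of the supervision matrix of class labels and covariates.

#' Construct a feature tensor
#'
#' @param array Numeric multiway array, participants on the first mode.
#' @param axes Named list of axis labels, one character vector per mode, in
#'   array order (first entry = participant ids).
#' @param normalization Optional list with `center` and `scale` arrays (the
#'   per-cell standardization constants) or `NULL` for raw values.
#' @return Object of class `feature_tensor`.
#' @export
feature_tensor <- function(array, axes, normalization = NULL) {
  array <- as.array(array)
  if (length(dim(array)) != length(axes)) {
    stop("feature_tensor: ", length(axes), " axis label sets for a ",
         length(dim(array)), "-mode array")
  }
  for (k in seq_along(axes)) {
    if (dim(array)[k] != length(axes[[k]])) {
      stop("feature_tensor: axis ", k, " has ", length(axes[[k]]),
           " labels but dimension ", dim(array)[k])
    }
  }
  dimnames(array) <- lapply(axes, as.character)
  structure(list(array = array, axes = axes, normalization = normalization),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat("feature_tensor:", paste(dim(x$array), collapse = " x "),
      paste0("(", paste(names(x$axes), collapse = ", "), ")"),
      if (!is.null(x$normalization)) "[standardized]" else "[raw]", "\n")
  invisible(x)
}

#' Covariate and contrast configuration for supervision
#'
#' Defines how the supervision matrix is built: which two diagnostic groups
#' form the classification contrast (case coded 1, control 0) and which
#' covariate columns accompany the class indicator. `covariates =
#' character(0)` is the "EEG only" configuration.
#'
#' @param contrast Character vector `c(case, control)`, or `NULL` for
#'   unsupervised-by-class designs (e.g. age regression).
#' @param covariates Subset of `c("age_initial", "sex", "birthweight",
#'   "age_code")`.
#' @return List of class `covariate_config`.
#' @export
covariate_config <- function(contrast = NULL,
                             covariates = character(0)) {
  known <- c("age_initial", "sex", "birthweight", "age_code")
  bad <- setdiff(covariates, known)
  if (length(bad)) {
    stop("covariate_config: unknown covariate name(s): ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(contrast) && length(contrast) != 2) {
    stop("covariate_config: contrast must name exactly two groups")
  }
  structure(list(contrast = contrast, covariates = covariates),
            class = "covariate_config")
}

#' Encode class labels and covariates into a supervision matrix
#'
#' Builds the participant x q matrix that supervises the factorization. The
#' class column is a 0/1 indicator of the contrast's case group; age at
#' recording is the integer code (1 = infancy, then 3, 5, 7 years); sex is
#' 0/1; birthweight is in grams; `age_initial` is the exact age in months at
#' the first recording.
#'
#' @param participant_table Data frame with column `id` plus whichever of
#'   `group`, `age_code`, `sex`, `birthweight`, `age_initial` the
#'   configuration requires.
#' @param config A [covariate_config()].
#' @return Numeric matrix with row names = participant ids and one column per
#'   supervision variable (class first when a contrast is set).
#' @export
encode_covariates <- function(participant_table, config) {
  stopifnot(is.data.frame(participant_table), "id" %in%
              names(participant_table), inherits(config, "covariate_config"))
  tab <- participant_table
  cols <- list()
  if (!is.null(config$contrast)) {
    if (!"group" %in% names(tab)) {
      stop("encode_covariates: participant table lacks a 'group' column")
    }
    keep <- tab$group %in% config$contrast
    tab <- tab[keep, , drop = FALSE]
    cols$class <- as.numeric(tab$group == config$contrast[1])
  }
  for (cv in config$covariates) {
    if (!cv %in% names(tab)) {
      stop("encode_covariates: covariate '", cv, "' not in participant table")
    }
    v <- tab[[cv]]
    if (cv == "sex" && !is.numeric(v)) {
      v <- as.numeric(factor(v, levels = sort(unique(v)))) - 1
    }
    v <- as.numeric(v)
    if (anyNA(v)) {
      stop("encode_covariates: missing '", cv, "' for participant(s) ",
           paste(tab$id[is.na(v)], collapse = ", "))
    }
    cols[[cv]] <- v
  }
  if (!length(cols)) {
    stop("encode_covariates: configuration selects no supervision columns")
  }
  Y <- do.call(cbind, cols)
  rownames(Y) <- tab$id
  Y
}

# order labels canonically where a registry exists, first-appearance otherwise
order_axis_labels <- function(values, registry) {
  u <- unique(values)
  known <- registry[registry %in% u]
  c(known, setdiff(u, registry))
}

#' Build a feature tensor and supervision matrix from a long feature table
#'
#' Pivots a long-format table (columns `participant`, `age_code`, `channel`,
#' `band`, `measure`, `value`) into a participant x measure x channel x band
#' array, with recording age as an additional fifth mode when more than one
#' required age is present. Participants lacking any required age or any
#' feature cell are dropped (complete-case); surviving cells are z-scored
#' across participants. When a participant table and configuration are given,
#' the matching supervision matrix is returned as well.
#'
#' @param feature_table Long-format data frame as above (`age_code` may be
#'   omitted for single-age data).
#' @param ages_required Integer vector of age codes every retained
#'   participant must have; these become the levels of the fifth (age) mode
#'   when more than one is requested. `NULL` (default) builds a
#'   cross-sectional 4-way tensor ignoring `age_code` (each participant one
#'   recording).
#' @param participant_table Optional data frame for [encode_covariates()].
#' @param config A [covariate_config()]; required with `participant_table`.
#' @param standardize Z-score each cell across participants (default TRUE).
#' @return List with elements `tensor` (a `feature_tensor`) and `supervision`
#'   (matrix or `NULL`), rows aligned.
#' @export
build_tensor <- function(feature_table, ages_required = NULL,
                         participant_table = NULL, config = NULL,
                         standardize = TRUE) {
  ft <- as.data.frame(feature_table)
  need <- c("participant", "channel", "band", "measure", "value")
  if (!all(need %in% names(ft))) {
    stop("build_tensor: feature table must have columns ",
         paste(need, collapse = ", "))
  }
  if (!"age_code" %in% names(ft)) ft$age_code <- 1L
  if (is.null(ages_required)) {
    # cross-sectional: one recording per participant, no age mode
    if (anyDuplicated(unique(ft[c("participant", "age_code")])$participant)) {
      stop("build_tensor: multiple ages per participant; pass ages_required",
           " to build a longitudinal (5-way) tensor")
    }
    ft$age_code <- 1L
    ages_required <- 1L
  } else {
    ages_required <- sort(as.integer(ages_required))
    ft <- ft[ft$age_code %in% ages_required, , drop = FALSE]
  }
  if (!is.null(participant_table) && !is.null(config) &&
      !is.null(config$contrast)) {
    ids_in_contrast <- participant_table$id[
      participant_table$group %in% config$contrast]
    ft <- ft[ft$participant %in% ids_in_contrast, , drop = FALSE]
  }

  measures <- order_axis_labels(ft$measure, eegdyn_measures())
  channels <- order_axis_labels(ft$channel, eegdyn_1020_labels())
  bands <- order_axis_labels(ft$band, eegdyn_bands())
  participants <- unique(ft$participant)
  n_age <- length(ages_required)

  dims <- c(length(participants), length(measures), length(channels),
            length(bands), if (n_age > 1) n_age)
  arr <- array(NA_real_, dims)
  pi_ <- match(ft$participant, participants)
  mi <- match(ft$measure, measures)
  ci <- match(ft$channel, channels)
  bi <- match(ft$band, bands)
  if (n_age > 1) {
    ai <- match(ft$age_code, ages_required)
    arr[cbind(pi_, mi, ci, bi, ai)] <- ft$value
  } else {
    arr[cbind(pi_, mi, ci, bi)] <- ft$value
  }

  # complete-case across all non-participant cells
  flat <- matrix(arr, nrow = dims[1])
  complete <- !apply(flat, 1, anyNA)
  if (!any(complete)) {
    stop("build_tensor: no participant has complete features for ages ",
         paste(ages_required, collapse = ", "))
  }
  participants <- participants[complete]
  arr <- if (n_age > 1) {
    arr[complete, , , , , drop = FALSE]
  } else {
    arr[complete, , , , drop = FALSE]
  }

  normalization <- NULL
  if (standardize) {
    st <- tensor_cell_stats(arr)
    arr <- apply_standardization(arr, st)
    normalization <- st
  }

  axes <- c(list(participant = participants,
                 measure = measures, channel = channels, band = bands),
            if (n_age > 1) list(age = as.character(ages_required)))
  tens <- feature_tensor(arr, axes, normalization)

  supervision <- NULL
  if (!is.null(participant_table) && !is.null(config)) {
    pt <- participant_table[match(participants, participant_table$id), ,
                            drop = FALSE]
    if (anyNA(pt$id)) {
      stop("build_tensor: participant table lacks rows for: ",
           paste(setdiff(participants, participant_table$id),
                 collapse = ", "))
    }
    supervision <- encode_covariates(pt, config)
    supervision <- supervision[match(participants, rownames(supervision)), ,
                               drop = FALSE]
  }
  list(tensor = tens, supervision = supervision)
}

# per-cell mean/sd across participants (mode 1)
tensor_cell_stats <- function(arr, rows = seq_len(dim(arr)[1])) {
  flat <- matrix(arr, nrow = dim(arr)[1])[rows, , drop = FALSE]
  center <- colMeans(flat)
  scale <- apply(flat, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale, cell_dims = dim(arr)[-1])
}

apply_standardization <- function(arr, stats) {
  flat <- matrix(arr, nrow = dim(arr)[1])
  flat <- sweep(sweep(flat, 2, stats$center), 2, stats$scale, "/")
  array(flat, dim(arr))
}

#' Standardize a feature tensor with given (e.g. training-fold) statistics
#'
#' @param ft A raw `feature_tensor`.
#' @param stats Result of standardizing statistics computed on a participant
#'   subset (internal structure with `center` and `scale`); when `NULL`,
#'   statistics are computed from `rows`.
#' @param rows Participant indices used to compute statistics when `stats`
#'   is `NULL`.
#' @return A standardized `feature_tensor` carrying the constants used.
#' @export
standardize_tensor <- function(ft, stats = NULL,
                               rows = seq_len(dim(ft$array)[1])) {
  stopifnot(inherits(ft, "feature_tensor"))
  if (is.null(stats)) stats <- tensor_cell_stats(ft$array, rows)
  feature_tensor(apply_standardization(ft$array, stats), ft$axes, stats)
}

#' Serialize a feature tensor (flat binary + JSON sidecar)
#'
#' Writes `<path>.bin` (doubles, little-endian, column-major) and
#' `<path>.json` (shape, axis names and labels, normalization constants).
#'
#' @param ft A `feature_tensor`.
#' @param path Path prefix (no extension).
#' @export
write_feature_tensor <- function(ft, path) {
  stopifnot(inherits(ft, "feature_tensor"))
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.numeric(ft$array), con, size = 8, endian = "little")
  close(con)
  meta <- list(dim = dim(ft$array), axis_names = names(ft$axes),
               axis_labels = ft$axes,
               normalization = if (!is.null(ft$normalization)) {
                 list(center = ft$normalization$center,
                      scale = ft$normalization$scale,
                      cell_dims = ft$normalization$cell_dims)
               })
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a serialized feature tensor
#'
#' @param path Path prefix used in [write_feature_tensor()].
#' @return A `feature_tensor`.
#' @export
read_feature_tensor <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(paste0(path, ".bin"), "rb")
  vals <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  close(con)
  axes <- meta$axis_labels
  names(axes) <- meta$axis_names
  norm <- NULL
  if (!is.null(meta$normalization)) {
    norm <- list(center = meta$normalization$center,
                 scale = meta$normalization$scale,
                 cell_dims = meta$normalization$cell_dims)
  }
  feature_tensor(array(vals, meta$dim), axes, norm)
}
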