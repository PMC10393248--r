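# Diagnostic grouping of participants from lifetime diagnosis records, and
# group summary tables with the rounding conventions of clinical cohort
# reports.

ANXIETY_DX <- c("GAD", "SAD", "SP")
EXTERNALIZING_DX <- c("ADHD", "ODD", "CD")
OTHER_DX <- c("MDD", "DMDD", "OCD", "PTSD")

#' Registry of recognised lifetime diagnosis codes
#'
#' @return Character vector: the three anxiety disorders (GAD, SAD, SP), the
#'   three externalizing disorders (ADHD, ODD, CD) and the other assessed
#'   disorders (MDD, DMDD, OCD, PTSD).
#' @export
diagnosis_registry <- function() c(ANXIETY_DX, EXTERNALIZING_DX, OTHER_DX)

#' Assign a diagnostic group from a lifetime diagnosis set
#'
#' Deterministic grouping rules: (1) anxiety = at least one anxiety disorder
#' (GAD, SAD and/or SP) and no externalizing disorder; (2) externalizing =
#' at least one of ADHD, ODD, CD and no anxiety disorder (comorbid MDD or
#' other internalizing diagnoses do not change this); (3) healthy control =
#' no diagnosis at all. Children comorbid for both an anxiety and an
#' externalizing disorder are excluded, as are children whose only
#' diagnoses fall outside the two a-priori families (e.g. PTSD alone).
#'
#' @param diagnoses Character vector of diagnosis codes for one participant
#'   (may be empty).
#' @return List with `group` (one of `healthy_control`, `anxiety`,
#'   `externalizing`, `excluded`) and `exclusion_reason` (`NA` unless
#'   excluded).
#' @export
assign_group <- function(diagnoses) {
  diagnoses <- unique(as.character(diagnoses))
  diagnoses <- diagnoses[diagnoses != ""]
  unknown <- setdiff(diagnoses, diagnosis_registry())
  if (length(unknown)) {
    stop("assign_group: unknown diagnosis code(s): ",
         paste(unknown, collapse = ", "))
  }
  has_anx <- any(diagnoses %in% ANXIETY_DX)
  has_ext <- any(diagnoses %in% EXTERNALIZING_DX)
  has_other <- any(diagnoses %in% OTHER_DX)
  if (has_anx && has_ext) {
    list(group = "excluded",
         exclusion_reason = "comorbid anxiety and externalizing disorders")
  } else if (has_anx) {
    list(group = "anxiety", exclusion_reason = NA_character_)
  } else if (has_ext) {
    list(group = "externalizing", exclusion_reason = NA_character_)
  } else if (has_other) {
    list(group = "excluded",
         exclusion_reason = "diagnosis outside the a priori groups")
  } else {
    list(group = "healthy_control", exclusion_reason = NA_character_)
  }
}

#' Assign diagnostic groups for a roster of participants
#'
#' @param records Data frame with `participant_id` and `diagnoses`
#'   (semicolon-separated codes, empty string = none), or a named list of
#'   character vectors.
#' @return Data frame: `participant_id`, `group`, `exclusion_reason`.
#' @export
assign_groups <- function(records) {
  if (is.data.frame(records)) {
    ids <- records$participant_id
    dx <- strsplit(ifelse(is.na(records$diagnoses), "", records$diagnoses),
                   ";")
  } else {
    ids <- names(records)
    dx <- records
  }
  res <- lapply(dx, function(d) assign_group(trimws(d)))
  data.frame(participant_id = ids,
             group = vapply(res, `[[`, character(1), "group"),
             exclusion_reason = vapply(res, `[[`, character(1),
                                       "exclusion_reason"),
             stringsAsFactors = FALSE)
}

#' Summarize diagnostic groups and per-diagnosis frequencies
#'
#' Produces the cohort summary: per group, the count and percentage of the
#' included sample (excluded children are dropped from the denominator) and
#' the number and percentage of members with exactly one versus two or more
#' diagnoses of that group's family; per diagnosis, the count, percentage of
#' the included sample, and percentage within its group. Percentages are
#' rounded to the nearest integer.
#'
#' @param records As in [assign_groups()].
#' @return List of class `group_summary`: `groups` and `diagnoses` data
#'   frames, `n_included`, `n_excluded`.
#' @export
summarize_groups <- function(records) {
  assignments <- assign_groups(records)
  if (nrow(assignments) == 0) stop("summarize_groups: empty roster")
  if (is.data.frame(records)) {
    dx <- strsplit(ifelse(is.na(records$diagnoses), "", records$diagnoses),
                   ";")
  } else {
    dx <- records
  }
  dx <- lapply(dx, function(d) {
    d <- trimws(d)
    unique(d[d != ""])
  })
  included <- assignments$group != "excluded"
  n_inc <- sum(included)
  if (n_inc == 0) stop("summarize_groups: no participants survive exclusion")
  pct <- function(num, den) round(100 * num / den)

  fam <- list(healthy_control = character(0), anxiety = ANXIETY_DX,
              externalizing = EXTERNALIZING_DX)
  groups <- do.call(rbind, lapply(names(fam), function(g) {
    sel <- included & assignments$group == g
    ndx <- vapply(dx[sel], function(d) sum(d %in% fam[[g]]), integer(1))
    data.frame(group = g, n = sum(sel), pct_of_sample = pct(sum(sel), n_inc),
               n_single = sum(ndx == 1), pct_single = if (sum(sel)) {
                 pct(sum(ndx == 1), sum(sel))
               } else {
                 NA_real_
               },
               n_multiple = sum(ndx >= 2), pct_multiple = if (sum(sel)) {
                 pct(sum(ndx >= 2), sum(sel))
               } else {
                 NA_real_
               },
               stringsAsFactors = FALSE)
  }))

  diag_rows <- list()
  for (g in c("anxiety", "externalizing")) {
    sel <- included & assignments$group == g
    n_grp <- sum(sel)
    for (code in fam[[g]]) {
      n_code <- sum(vapply(dx[sel], function(d) code %in% d, logical(1)))
      diag_rows[[length(diag_rows) + 1]] <- data.frame(
        group = g, diagnosis = code, n = n_code,
        pct_of_sample = pct(n_code, n_inc),
        pct_within_group = if (n_grp) pct(n_code, n_grp) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(groups = groups, diagnoses = do.call(rbind, diag_rows),
                 n_included = n_inc, n_excluded = sum(!included),
                 exclusions = assignments[!included, , drop = FALSE]),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("group_summary:", x$n_included, "included,", x$n_excluded,
      "excluded\n")
  print(x$groups, row.names = FALSE)
  print(x$diagnoses, row.names = FALSE)
  invisible(x)
}

#' Write a group summary as delimited text
#'
#' Writes the per-group and per-diagnosis tables to `<path>_groups.tsv` and
#' `<path>_diagnoses.tsv`.
#'
#' @param summary A `group_summary` from [summarize_groups()].
#' @param path Path prefix.
#' @export
write_group_summary <- function(summary, path) {
  stopifnot(inherits(summary, "group_summary"))
  utils::write.table(summary$groups, paste0(path, "_groups.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(summary$diagnoses, paste0(path, "_diagnoses.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read diagnosis records from delimited text
#'
#' Expects columns `participant_id` and `diagnoses` (semicolon-separated
#' codes).
#'
#' @param path Input file (tab-separated with header).
#' @return Data frame.
#' @export
read_diagnosis_records <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = "character")
  if (!all(c("participant_id", "diagnoses") %in% names(df))) {
    stop("read_diagnosis_records: need participant_id and diagnoses columns")
  }
  df
}
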