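# Convenience glue: from a list of recordings to the long-format feature
# table consumed by build_tensor().

#' Compute the per-(channel, band) feature table for a set of recordings
#'
#' Optionally crops each recording to an analysis window, decomposes every
#' channel into the six frequency bands and computes the twelve nonlinear
#' measures, returning one long-format table for [build_tensor()]. Recurrence
#' analysis scales quadratically with segment length, so population-scale
#' runs typically use a window of a few seconds (set `duration_s`).
#'
#' @param recordings List of `eeg_recording` objects.
#' @param start_s,duration_s Analysis window passed to [select_segment()];
#'   `duration_s = NULL` uses each full recording.
#' @param config A [feature_config()].
#' @param progress Print one line per recording (default FALSE).
#' @return Long data frame: `participant`, `age_code`, `channel`, `band`,
#'   `measure`, `value`; attribute `missing_log` aggregates per-recording
#'   failure reasons.
#' @export
compute_cohort_features <- function(recordings, start_s = 0,
                                    duration_s = NULL,
                                    config = feature_config(),
                                    progress = FALSE) {
  stopifnot(all(vapply(recordings, inherits, logical(1), "eeg_recording")))
  tabs <- vector("list", length(recordings))
  logs <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    if (!is.null(duration_s)) {
      rec <- select_segment(rec, start_s = start_s, duration_s = duration_s)
    }
    ft <- extract_features(rec, config)
    ft$participant <- rec$participant_id
    ft$age_code <- rec$age_code
    tabs[[i]] <- ft[, c("participant", "age_code", "channel", "band",
                        "measure", "value")]
    ml <- attr(ft, "missing_log")
    if (nrow(ml)) {
      ml$participant <- rec$participant_id
      logs[[i]] <- ml
    }
    if (progress) {
      message(sprintf("features %d/%d (%s)", i, length(recordings),
                      rec$participant_id))
    }
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  attr(out, "missing_log") <- if (length(logs)) do.call(rbind, logs) else
    data.frame(channel = character(0), band = character(0),
               reason = character(0), participant = character(0))
  out
}
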