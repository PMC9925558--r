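## MEP/EMG trial processing: peak-to-peak amplitude extraction, pre-pulse
## EMG exclusion, and the hand-status labelling that forms the HAND factor
## of the neurophysiological models.

#' Peak-to-peak MEP amplitude and pre-pulse EMG from a trace
#'
#' The MEP amplitude is the max-minus-min of the trace in the (10, 100] ms
#' window after the test pulse; pre-pulse activity is the root-mean-square
#' over the \[-50, 0) ms window immediately before the pulse. Windows are
#' sample-aligned at the given sampling rate.
#'
#' @param trace numeric EMG segment (mV).
#' @param test_pulse_index sample index of the test pulse within `trace`.
#' @param sampling_rate Hz (default 2000).
#' @return named numeric vector `c(amplitude, rms_pre)` in mV.
#' @export
extract_mep <- function(trace, test_pulse_index, sampling_rate = 2000) {
  i0 <- as.integer(test_pulse_index)
  n_pre <- round(0.050 * sampling_rate)
  post_lo <- i0 + floor(0.010 * sampling_rate) + 1L
  post_hi <- i0 + round(0.100 * sampling_rate)
  if (i0 - n_pre < 1L || post_hi > length(trace)) {
    stop("extract_mep: trace must cover [-50, +100] ms around the test pulse",
         call. = FALSE)
  }
  post <- trace[post_lo:post_hi]
  pre <- trace[(i0 - n_pre):(i0 - 1L)]
  c(amplitude = max(post) - min(post), rms_pre = sqrt(mean(pre^2)))
}

#' Flag MEP records contaminated by pre-pulse EMG
#'
#' A record is excluded from inference when the RMS EMG in the 50 ms window
#' before the test pulse strictly exceeds the threshold (0.025 mV); a value
#' exactly at the threshold is retained.
#'
#' @param meps MEP table with an `rms_pre` column (mV).
#' @param threshold mV, default 0.025.
#' @param quiet suppress the exclusion-count message.
#' @return `meps` with a logical `excluded` column.
#' @export
apply_emg_exclusion <- function(meps, threshold = 0.025, quiet = FALSE) {
  if (!"rms_pre" %in% names(meps)) {
    stop("apply_emg_exclusion: no rms_pre column", call. = FALSE)
  }
  meps$excluded <- meps$rms_pre > threshold
  if (!quiet) {
    message(sprintf("EMG exclusion: %d of %d records (%.1f%%) excluded",
                    sum(meps$excluded), nrow(meps),
                    100 * mean(meps$excluded)))
  }
  meps
}

#' Hand status of an MEP observation
#'
#' Maps cue, trial type, TMS timepoint and measured hand to the HAND-factor
#' level of the neurophysiological analyses: at the warning signal the
#' measurement is a task baseline; at the imperative signal the hand is of
#' unknown status under an uninformative cue, "maybe stopping" if it is the
#' cued hand and "definitely going" otherwise; IS150 measurements index
#' movement execution; and at SS150 the hand is "stopping" if it is the
#' signalled stopping hand and "continuing" otherwise. Vectorised; the
#' mapping is total over all valid combinations.
#'
#' @param cue "fixation", "MSL" or "MSR".
#' @param trial_type "go", "left_stop" or "right_stop".
#' @param tms_timepoint "WS", "IS", "IS150" or "SS150".
#' @param measured_hand "left" or "right".
#' @return character vector of hand statuses.
#' @export
label_hand_status <- function(cue, trial_type, tms_timepoint, measured_hand) {
  n <- max(length(cue), length(trial_type), length(tms_timepoint),
           length(measured_hand))
  cue <- rep_len(cue, n); trial_type <- rep_len(trial_type, n)
  tms_timepoint <- rep_len(tms_timepoint, n)
  measured_hand <- rep_len(measured_hand, n)
  if (any(tms_timepoint == "SS150" & trial_type == "go")) {
    stop("label_hand_status: SS150 cannot occur on go trials", call. = FALSE)
  }
  cued_hand <- ifelse(cue == "MSL", "left", ifelse(cue == "MSR", "right", NA))
  stop_hand <- ifelse(trial_type == "left_stop", "left",
                      ifelse(trial_type == "right_stop", "right", NA))
  out <- rep(NA_character_, n)
  out[tms_timepoint == "WS"] <- "WS_baseline"
  out[tms_timepoint == "IS150"] <- "IS150"
  is_is <- tms_timepoint == "IS"
  out[is_is & cue == "fixation"] <- "IS_unknown"
  out[is_is & !is.na(cued_hand) & measured_hand == cued_hand] <- "IS_maybe_stopping"
  out[is_is & !is.na(cued_hand) & measured_hand != cued_hand] <- "IS_definitely_going"
  is_ss <- tms_timepoint == "SS150"
  out[is_ss & measured_hand == stop_hand] <- "SS150_stopping"
  out[is_ss & measured_hand != stop_hand] <- "SS150_continuing"
  if (anyNA(out)) {
    stop("label_hand_status: unmapped (cue, trial_type, timepoint, hand) cell",
         call. = FALSE)
  }
  out
}

#' Assemble analysis-ready MEP observations
#'
#' Applies the pre-pulse EMG exclusion and (re)derives the hand-status label
#' and conditioned flag, yielding the table the Gamma log-link models
#' consume.
#'
#' @param meps MEP table (e.g. from [simulate_mep_table()]).
#' @param threshold EMG exclusion threshold (mV).
#' @param quiet suppress the exclusion message.
#' @return tibble of MEP observations with `hand_status`, `conditioned` and
#'   `excluded` columns.
#' @export
mep_observations <- function(meps, threshold = 0.025, quiet = TRUE) {
  meps <- as_tibble(meps)
  meps$conditioned <- meps$tms_type != "CSE"
  meps$hand_status <- label_hand_status(meps$cue, meps$trial_type,
                                        meps$tms_timepoint, meps$measured_hand)
  apply_emg_exclusion(meps, threshold = threshold, quiet = quiet)
}

#' Per-run EMG exclusion report
#'
#' @param meps table with an `excluded` column.
#' @return list with counts and the exclusion percentage.
#' @export
exclusion_report <- function(meps) {
  list(n_records = nrow(meps), n_excluded = sum(meps$excluded),
       pct_excluded = 100 * mean(meps$excluded))
}
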