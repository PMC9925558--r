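## Behavioural processing: fast-guess filtering, the standard task summary
## (omission/error rates, go and stop RTs, p(respond|stop), SSD), stopping
## interference, and SSRT by the integration method with validity
## exclusions under the independent race model.

trial_rt <- function(trials) {
  ## go rows: mean of the two synchronous presses; successful stop rows: the
  ## continuing hand's press
  ifelse(trials$trial_type == "go",
         rowMeans(cbind(trials$rt_left, trials$rt_right)),
         ifelse(trials$trial_type == "left_stop", trials$rt_right,
                trials$rt_left))
}

stopping_hand_rt <- function(trials) {
  ifelse(trials$trial_type == "left_stop", trials$rt_left, trials$rt_right)
}

#' Filter correct-response trials for RT analyses
#'
#' Retains correct go trials (synchronous bimanual presses) and successful
#' stop trials (stopping hand cancelled, continuing hand responded) whose RT
#' exceeds the fast-guess threshold, and attaches `rt` (ms from the
#' imperative signal; for go trials the mean of the two presses, for stop
#' trials the continuing hand's press) and, on stop rows, `rt_rel_ss = rt -
#' ssd`, the RT relative to the stop-signal.
#'
#' @param trials executed-trial table.
#' @param min_rt fast-guess threshold (ms); only RTs strictly greater are
#'   kept (default 200).
#' @return filtered tibble with `rt` and `rt_rel_ss` columns.
#' @export
filter_correct_rt <- function(trials, min_rt = 200) {
  trials <- as_tibble(trials)
  keep <- trials$outcome %in% c("go_correct", "stop_success")
  out <- trials[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    out$rt <- numeric(0)
    out$rt_rel_ss <- numeric(0)
    return(out)
  }
  if (any(out$trial_type != "go" & is.na(out$ssd))) {
    stop("filter_correct_rt: stop rows with missing SSD", call. = FALSE)
  }
  out$rt <- trial_rt(out)
  out <- out[!is.na(out$rt) & out$rt > min_rt, , drop = FALSE]
  out$rt_rel_ss <- ifelse(out$trial_type == "go", NA_real_, out$rt - out$ssd)
  out
}

#' Standard stop-signal task summary
#'
#' Per-condition descriptives over the main blocks, following the usual
#' reporting recommendations: go omission and go error percentages (errors =
#' incomplete + asynchronous responses), mean and SD of correct go RT,
#' probability of responding on stop trials (failed, premature and
#' wrong-hand stops over all stop trials), mean and SD of SSD, mean RT on
#' unsuccessful stop trials (stopping hand) and mean continuing-hand RT on
#' successful stop trials.
#'
#' @param trials full executed-trial table (unfiltered).
#' @return tibble, one row per condition.
#' @export
summarize_sst <- function(trials) {
  trials <- as_tibble(trials)
  main <- trials[trials$phase == "main", , drop = FALSE]
  respond_outcomes <- c("stop_fail", "stop_premature_response", "stop_wrong_hand")
  per_cond <- lapply(split(main, main$condition), function(d) {
    go_correct_rt <- trial_rt(d)[d$outcome == "go_correct"]
    is_stop <- d$trial_type != "go"
    n_stop <- sum(is_stop)
    tibble(
      condition = d$condition[1],
      go_omission_pct = 100 * sum(d$outcome == "go_missed") / sum(d$trial_type == "go"),
      go_error_pct = 100 * sum(d$outcome %in% c("go_incomplete", "go_async_error")) /
        sum(d$trial_type == "go"),
      mean_go_rt = mean(go_correct_rt),
      sd_go_rt = sd(go_correct_rt),
      p_respond_stop = if (n_stop == 0) NA_real_ else
        sum(d$outcome %in% respond_outcomes) / n_stop,
      mean_ssd = mean(d$ssd[is_stop], na.rm = TRUE),
      sd_ssd = sd(d$ssd[is_stop], na.rm = TRUE),
      mean_signal_respond_rt = mean(stopping_hand_rt(d)[
        d$outcome %in% c("stop_fail", "stop_premature_response")], na.rm = TRUE),
      mean_stop_success_continuing_rt = mean(trial_rt(d)[
        d$outcome == "stop_success"], na.rm = TRUE)
    )
  })
  out <- bind_rows(per_cond)
  if (any(is.na(out$p_respond_stop))) {
    warning("summarize_sst: a condition has no stop trials; p_respond_stop is NA",
            call. = FALSE)
  }
  out
}

#' Estimate SSRT for one subject, condition and hand (integration method)
#'
#' Implements the integration method with replacement of go omissions: the
#' probability of responding on the hand's stop trials, p, indexes the
#' sorted pool of that hand's correct go RTs (omissions replaced by the
#' maximum observed go RT); SSRT is the `ceiling(p * N)`-th go RT minus the
#' mean SSD. The estimate is marked invalid when p lies outside the
#' `0.25-0.75` range, or when the mean signal-respond RT exceeds the mean go RT (a
#' violation of the independent race model's assumptions).
#'
#' @param trials executed-trial table (one cohort or subject; main blocks
#'   are selected internally).
#' @param subject_id,condition,hand the estimation cell (`hand` is "left"
#'   or "right", i.e. the hand whose stop trials are scored).
#' @param wrong_hand_counts_response treat "stopped wrong hand" trials
#'   (the cued hand responded) as responses (default TRUE).
#' @param missed_in_denominator include stop trials without any response in
#'   the denominator of p (default TRUE).
#' @return one-row tibble: `subject_id`, `condition`, `hand`, `ssrt` (ms or
#'   NA), `p_respond`, `valid`, `exclusion_reason`.
#' @export
estimate_ssrt <- function(trials, subject_id, condition, hand,
                          wrong_hand_counts_response = TRUE,
                          missed_in_denominator = TRUE) {
  trials <- as_tibble(trials)
  sid <- subject_id
  d <- trials[trials$subject_id == sid & trials$phase == "main" &
                trials$condition == condition, , drop = FALSE]
  stop_type <- paste0(hand, "_stop")
  stops <- d[d$trial_type == stop_type, , drop = FALSE]
  gos <- d[d$trial_type == "go", , drop = FALSE]
  if (nrow(gos) == 0) {
    stop("estimate_ssrt: no go trials for ", sid, "/", condition, call. = FALSE)
  }
  result <- function(ssrt, p, reason) {
    tibble(subject_id = sid, condition = condition, hand = hand,
           ssrt = ssrt, p_respond = p, valid = is.na(reason) || reason == "none",
           exclusion_reason = ifelse(is.na(reason), "none", reason))
  }
  respond_outcomes <- c("stop_fail", "stop_premature_response")
  if (wrong_hand_counts_response) {
    respond_outcomes <- c(respond_outcomes, "stop_wrong_hand")
  }
  n_resp <- sum(stops$outcome %in% respond_outcomes)
  denom <- nrow(stops) - if (missed_in_denominator) 0 else
    sum(stops$outcome == "stop_missed")
  if (denom == 0) return(result(NA_real_, NA_real_, "p_respond_out_of_range"))
  p <- n_resp / denom
  if (p < 0.25 || p > 0.75) {
    return(result(NA_real_, p, "p_respond_out_of_range"))
  }
  rt_col <- if (hand == "left") gos$rt_left else gos$rt_right
  pool <- rt_col[gos$outcome == "go_correct" & !is.na(rt_col)]
  n_omit <- sum(gos$outcome == "go_missed")
  if (length(pool) == 0) {
    stop("estimate_ssrt: empty go RT pool for ", sid, "/", condition, call. = FALSE)
  }
  pool <- c(pool, rep(max(pool), n_omit))
  n_go <- length(pool)
  nth <- min(max(ceiling(p * n_go), 1L), n_go)
  mean_ssd <- mean(stops$ssd, na.rm = TRUE)
  ssrt <- sort(pool)[nth] - mean_ssd
  sr_rt <- stopping_hand_rt(stops)[stops$outcome %in%
                                     c("stop_fail", "stop_premature_response")]
  if (length(sr_rt) > 0 && mean(sr_rt, na.rm = TRUE) > mean(pool)) {
    return(result(NA_real_, p, "race_model_violation"))
  }
  result(ssrt, p, "none")
}

#' SSRT estimates for every subject x condition x hand cell
#'
#' @param trials executed-trial table for a cohort.
#' @param ... passed to [estimate_ssrt()].
#' @return tibble with exactly one row per cell.
#' @export
estimate_ssrt_all <- function(trials, ...) {
  cells <- expand.grid(subject_id = unique(trials$subject_id),
                       condition = c("reactive", "proactive"),
                       hand = c("left", "right"),
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$subject_id, cells$condition, cells$hand), ]
  bind_rows(lapply(seq_len(nrow(cells)), function(i) {
    estimate_ssrt(trials, cells$subject_id[i], cells$condition[i],
                  cells$hand[i], ...)
  }))
}

#' Stopping-interference summary
#'
#' Per condition, compares the continuing hand's RT on successful stop
#' trials with correct go RT: the difference in ms and the percent
#' elongation (stopping interference), plus the same comparison with stop
#' RT taken relative to the stop-signal (where the continuing response is
#' typically faster than the go response).
#'
#' @param filtered table from [filter_correct_rt()].
#' @return tibble, one row per condition: `mean_go_rt`, `mean_stop_rt`,
#'   `interference_ms`, `interference_pct`, `mean_stop_rt_rel_ss`,
#'   `rel_ss_diff_ms`, `rel_ss_pct`.
#' @export
interference_table <- function(filtered) {
  filtered <- as_tibble(filtered)
  main <- filtered[filtered$phase == "main", , drop = FALSE]
  per_cond <- lapply(split(main, main$condition), function(d) {
    go <- d$rt[d$trial_type == "go"]
    st <- d$rt[d$trial_type != "go"]
    st_ss <- d$rt_rel_ss[d$trial_type != "go"]
    if (length(go) == 0 || length(st) == 0) {
      warning("interference_table: condition '", d$condition[1],
              "' lacks go or stop RTs", call. = FALSE)
    }
    tibble(
      condition = d$condition[1],
      mean_go_rt = mean(go),
      mean_stop_rt = mean(st),
      interference_ms = mean(st) - mean(go),
      interference_pct = 100 * (mean(st) / mean(go) - 1),
      mean_stop_rt_rel_ss = mean(st_ss),
      rel_ss_diff_ms = mean(st_ss) - mean(go),
      rel_ss_pct = 100 * (mean(st_ss) / mean(go) - 1)
    )
  })
  bind_rows(per_cond)
}
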