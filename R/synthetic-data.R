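## Generative model of the task: an independent race between a shifted
## lognormal bimanual go process and a fixed-latency stop process, with
## 1-up/1-down staircased stop-signal delays, lapses (omissions, incomplete
## and asynchronous presses, wrong-hand stops), proactive-cue go slowing,
## and Gamma-distributed MEP amplitudes whose means carry the planted
## corticospinal-excitability and interhemispheric-inhibition structure.

#' Population-level generative configuration for a simulated cohort
#'
#' Defaults are calibrated to the behaviour of healthy young adults on this
#' task: reactive go RTs with mean 430 ms and SD 89 ms (split into 84 ms of
#' within-subject and 30 ms of between-subject spread) from a shifted
#' lognormal with a 150 ms shift; proactive go slowing of 17 ms; stop
#' latencies of 268 ms (reactive) and 278 ms (proactive); a continuing-hand
#' interference multiplier of 1.22 (reactive) and 1.16 (proactive), i.e.
#' roughly 19% elongation overall with about one fifth less interference
#' under proactive cues; lapse rates giving ~0.3% go omissions and ~7% go
#' errors; baseline CSE around 2.15 mV with preparatory suppression and
#' stop-signal-related facilitation; SIHI ~0.69 and LIHI ~0.73 at baseline
#' with LIHI released towards (and beyond) 1 after the stop signal in the
#' continuing hand; and 2.2% of TMS trials contaminated by pre-pulse EMG.
#'
#' @param ... named overrides of any default element.
#' @return list of class `selstop_cohort_config`.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    go_rt_mean = 430, go_rt_sd_within = 84, go_rt_mean_sd_between = 30,
    go_shift = 150, sync_jitter_sd = 18,
    proactive_go_slowing = 17, proactive_go_slowing_sd = 5,
    ssrt_mean = c(reactive = 268, proactive = 278),
    ssrt_sd_between = 15, ssrt_trial_sd = 0,
    interference_mult = c(reactive = 1.22, proactive = 1.16),
    interference_sd_between = 0,
    p_omission = 0.003, p_incomplete = 0.02, p_wrong_hand = 0.01,
    mep_shape = 4, mep_scale_sd_between = 0.35, ihi_sd_between = 0.05,
    cse_mean = c(WS_baseline = 2.15, IS_unknown = 1.86,
                 IS_maybe_stopping = 1.63, IS_definitely_going = 1.65,
                 IS150 = 1.61, SS150_continuing = 2.13, SS150_stopping = 2.01),
    ihi_ratio = rbind(
      SIHI = c(WS_baseline = 0.69, IS_unknown = 0.72, IS_maybe_stopping = 0.73,
               IS_definitely_going = 0.72, IS150 = 0.74,
               SS150_continuing = 0.73, SS150_stopping = 0.71),
      LIHI = c(WS_baseline = 0.73, IS_unknown = 0.87, IS_maybe_stopping = 0.90,
               IS_definitely_going = 0.92, IS150 = 0.99,
               SS150_continuing = 1.12, SS150_stopping = 0.97)),
    p_emg_contaminated = 0.022,
    design = design_config()
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("cohort_config: unknown elements ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- "selstop_cohort_config"
  cfg
}

#' Generative parameters of one simulated participant
#'
#' @param go_mean,go_sd mean and SD (ms) of go finishing times; converted to
#'   shifted-lognormal `meanlog`/`sdlog` with the given `go_shift`.
#' @param go_shift nondecision shift (ms) of the go finishing-time
#'   distribution.
#' @param sync_jitter_sd SD (ms) of the per-hand asynchrony added to the
#'   common bimanual finishing time.
#' @param proactive_go_slowing additive go slowing (ms) under informative cues.
#' @param ssrt named stop latencies (ms), `c(reactive=, proactive=)`.
#' @param ssrt_trial_sd optional trial-to-trial SD (ms) of the stop latency
#'   (0 = deterministic stop process).
#' @param interference_mult named multiplicative delay of the continuing
#'   hand's re-initiated response on successful stop trials.
#' @param p_omission,p_incomplete,p_wrong_hand lapse probabilities.
#' @param cse_mean named mean unconditioned MEP amplitude (mV) per hand
#'   status.
#' @param ihi_ratio matrix (rows SIHI/LIHI, columns hand statuses) of
#'   conditioned/unconditioned mean ratios; values < 1 are inhibitory,
#'   values > 1 facilitatory.
#' @param mep_shape Gamma shape of MEP amplitudes (shape 4 = CV 0.5).
#' @param p_emg_contaminated probability that the 50 ms pre-pulse EMG window
#'   exceeds the 0.025 mV RMS exclusion threshold.
#' @return list of class `selstop_params`.
#' @export
subject_params <- function(go_mean = 430, go_sd = 84, go_shift = 150,
                           sync_jitter_sd = 18, proactive_go_slowing = 17,
                           ssrt = c(reactive = 268, proactive = 278),
                           ssrt_trial_sd = 0,
                           interference_mult = c(reactive = 1.22, proactive = 1.16),
                           p_omission = 0.003, p_incomplete = 0.02,
                           p_wrong_hand = 0.01,
                           cse_mean = cohort_config()$cse_mean,
                           ihi_ratio = cohort_config()$ihi_ratio,
                           mep_shape = 4, p_emg_contaminated = 0.022) {
  ln <- shifted_lognormal_pars(go_mean, go_sd, go_shift)
  p <- list(go_mean = go_mean, go_sd = go_sd, go_shift = go_shift,
            go_mu = ln$meanlog, go_sigma = ln$sdlog,
            sync_jitter_sd = sync_jitter_sd,
            proactive_go_slowing = proactive_go_slowing,
            ssrt = ssrt, ssrt_trial_sd = ssrt_trial_sd,
            interference_mult = interference_mult,
            p_omission = p_omission, p_incomplete = p_incomplete,
            p_wrong_hand = p_wrong_hand,
            cse_mean = cse_mean, ihi_ratio = ihi_ratio,
            mep_shape = mep_shape, p_emg_contaminated = p_emg_contaminated)
  stopifnot(p$go_sigma > 0, all(p$ssrt > 0), all(p$ihi_ratio > 0),
            all(unlist(p[c("p_omission", "p_incomplete", "p_wrong_hand",
                           "p_emg_contaminated")]) >= 0),
            all(unlist(p[c("p_omission", "p_incomplete", "p_wrong_hand",
                           "p_emg_contaminated")]) <= 1),
            all(p$interference_mult >= 1), p$proactive_go_slowing >= 0)
  class(p) <- "selstop_params"
  p
}

#' Draw one participant's parameters from the population model
#'
#' @param config a [cohort_config()].
#' @return a `selstop_params` list (uses the current RNG state).
#' @export
draw_subject_params <- function(config = cohort_config()) {
  stopifnot(inherits(config, "selstop_cohort_config"))
  go_mean <- rnorm(1, config$go_rt_mean, config$go_rt_mean_sd_between)
  go_mean <- max(go_mean, config$go_shift + 50)
  ssrt <- pmax(100, rnorm(2, config$ssrt_mean, config$ssrt_sd_between))
  names(ssrt) <- names(config$ssrt_mean)
  slow <- max(0, rnorm(1, config$proactive_go_slowing,
                       config$proactive_go_slowing_sd))
  interf <- pmax(1, config$interference_mult +
                   rnorm(2, 0, config$interference_sd_between))
  names(interf) <- names(config$interference_mult)
  cse <- config$cse_mean * exp(rnorm(1, 0, config$mep_scale_sd_between))
  ihi <- config$ihi_ratio * exp(rnorm(2, 0, config$ihi_sd_between))
  subject_params(go_mean = go_mean, go_sd = config$go_rt_sd_within,
                 go_shift = config$go_shift,
                 sync_jitter_sd = config$sync_jitter_sd,
                 proactive_go_slowing = slow, ssrt = ssrt,
                 ssrt_trial_sd = config$ssrt_trial_sd,
                 interference_mult = interf,
                 p_omission = config$p_omission,
                 p_incomplete = config$p_incomplete,
                 p_wrong_hand = config$p_wrong_hand,
                 cse_mean = cse, ihi_ratio = ihi,
                 mep_shape = config$mep_shape,
                 p_emg_contaminated = config$p_emg_contaminated)
}

#' One staircase update of the stop-signal delay
#'
#' 1-up/1-down tracking: the SSD decreases by one step after a stop trial on
#' which a response was made (making stopping easier) and increases by one
#' step after a successful stop (making it harder), with a floor of 50 ms.
#' Trials without any response leave the SSD unchanged.
#'
#' @param ssd current stop-signal delay (ms).
#' @param responded logical: was any response registered on the stop trial?
#'   `NA` (no response at all, a missed stop trial) leaves the SSD unchanged.
#' @param step staircase step (ms), default 50.
#' @param floor lower SSD limit (ms), default 50.
#' @return updated SSD (ms).
#' @export
update_staircase <- function(ssd, responded, step = 50, floor = 50) {
  if (is.na(responded)) return(ssd)
  if (responded) max(floor, ssd - step) else ssd + step
}

#' Classify a completed bimanual go response
#'
#' Synchrony rule: the two presses count as one synchronous bimanual
#' response when they are less than 50 ms apart; at or beyond 50 ms the
#' trial is an asynchrony error.
#'
#' @param rt_left,rt_right press times (ms from the imperative signal).
#' @param threshold asynchrony threshold (ms), default 50.
#' @return character vector: `"go_correct"` or `"go_async_error"`.
#' @export
classify_synchrony <- function(rt_left, rt_right, threshold = 50) {
  ifelse(abs(rt_left - rt_right) >= threshold, "go_async_error", "go_correct")
}

go_finish_time <- function(n, params, proactive) {
  params$go_shift + exp(rnorm(n, params$go_mu, params$go_sigma)) +
    if (proactive) params$proactive_go_slowing else 0
}

staircase_key <- function(condition, trial_type) {
  paste(condition, sub("_stop$", "", trial_type), sep = ".")
}

## Simulate all go trials of a schedule at once (no staircase involvement).
sim_go_trials <- function(spec, params) {
  n <- nrow(spec)
  base <- go_finish_time(n, params, FALSE) +
    ifelse(spec$condition == "proactive", params$proactive_go_slowing, 0)
  rt_l <- base + rnorm(n, 0, params$sync_jitter_sd)
  rt_r <- base + rnorm(n, 0, params$sync_jitter_sd)
  u <- runif(n)
  missed <- u < params$p_omission
  incomplete <- !missed & u < params$p_omission + params$p_incomplete
  lost_left <- runif(n) < 0.5
  outcome <- ifelse(missed, "go_missed",
             ifelse(incomplete, "go_incomplete",
                    classify_synchrony(rt_l, rt_r)))
  rt_l[missed | (incomplete & lost_left)] <- NA_real_
  rt_r[missed | (incomplete & !lost_left)] <- NA_real_
  tibble(rt_left = rt_l, rt_right = rt_r, ssd = NA_real_, outcome = outcome)
}

sim_stop_trial <- function(condition, trial_type, ssd, params) {
  proactive <- condition == "proactive"
  stop_left <- trial_type == "left_stop"
  out <- list(rt_left = NA_real_, rt_right = NA_real_, ssd = ssd,
              outcome = NA_character_, responded = NA)
  if (runif(1) < params$p_omission) {
    out$outcome <- "stop_missed"
    return(out)
  }
  base <- go_finish_time(1, params, proactive)
  t_stop <- base + rnorm(1, 0, params$sync_jitter_sd)
  t_cont <- base + rnorm(1, 0, params$sync_jitter_sd)
  set_rts <- function(out, t_stopping, t_continuing) {
    if (stop_left) {
      out$rt_left <- t_stopping; out$rt_right <- t_continuing
    } else {
      out$rt_right <- t_stopping; out$rt_left <- t_continuing
    }
    out
  }
  if (max(t_stop, t_cont) < ssd) {
    ## bimanual response completed before the stop-signal was shown
    out$outcome <- "stop_premature_response"
    out$responded <- TRUE
    return(set_rts(out, t_stop, t_cont))
  }
  if (runif(1) < params$p_wrong_hand) {
    out$outcome <- "stop_wrong_hand"
    out$responded <- TRUE
    return(set_rts(out, t_stop, NA_real_))
  }
  ssrt <- params$ssrt[[condition]]
  if (params$ssrt_trial_sd > 0) ssrt <- max(1, rnorm(1, ssrt, params$ssrt_trial_sd))
  if (t_stop > ssd + ssrt) {
    ## stop process wins: the cued hand is cancelled and the continuing
    ## response is re-initiated (uncoupled from the aborted bimanual plan),
    ## delayed multiplicatively by the stopping-interference effect
    out$outcome <- "stop_success"
    out$responded <- FALSE
    t_new <- params$interference_mult[[condition]] *
      go_finish_time(1, params, proactive)
    return(set_rts(out, NA_real_, t_new))
  }
  out$outcome <- "stop_fail"
  out$responded <- TRUE
  set_rts(out, t_stop, t_cont)
}

#' Simulate a single trial
#'
#' Runs one trial of the independent race model and updates the staircase
#' state. Intended for inspection and tests; [simulate_session()] is the
#' efficient whole-schedule path. Uses the current RNG state.
#'
#' @param spec one-row trial specification (see [build_schedule()]).
#' @param params a [subject_params()].
#' @param state named list of staircase SSDs keyed `condition.hand`; missing
#'   keys are initialised at 200 ms.
#' @param goonly_mean mean synchronous RT from the go-only block, used for
#'   the "Respond quicker" feedback threshold (mean + 250 ms); `NA` disables
#'   the check.
#' @return list with `result` (one-row tibble of the executed trial) and the
#'   updated `state`.
#' @export
simulate_trial <- function(spec, params, state = list(), goonly_mean = NA) {
  stopifnot(nrow(spec) == 1, inherits(params, "selstop_params"))
  if (spec$trial_type == "go") {
    res <- sim_go_trials(spec, params)
  } else {
    key <- staircase_key(spec$condition, spec$trial_type)
    if (is.null(state[[key]])) state[[key]] <- 200
    r <- sim_stop_trial(spec$condition, spec$trial_type, state[[key]], params)
    state[[key]] <- update_staircase(state[[key]], r$responded)
    res <- tibble(rt_left = r$rt_left, rt_right = r$rt_right, ssd = r$ssd,
                  outcome = r$outcome)
  }
  res <- bind_rows(cbind(spec, res))
  res$feedback <- feedback_label(res, goonly_mean)
  list(result = res, state = state)
}

## The on-screen feedback rules, vectorised over executed trials.
feedback_label <- function(trials, goonly_mean = NA) {
  rt_mean <- rowMeans(cbind(trials$rt_left, trials$rt_right))
  out <- character(nrow(trials))
  rt_txt <- sprintf("%.3f s", rt_mean / 1000)
  out[trials$outcome == "go_correct"] <- rt_txt[trials$outcome == "go_correct"]
  if (!is.na(goonly_mean)) {
    slow <- trials$outcome == "go_correct" & rt_mean > goonly_mean + 250
    out[slow] <- "Respond quicker"
  }
  out[trials$outcome == "go_async_error"] <- "Press simultaneously"
  out[trials$outcome == "go_incomplete"] <- "Incomplete"
  out[trials$outcome %in% c("go_missed", "stop_missed")] <- "Missed"
  out[trials$outcome == "stop_fail"] <- "Failed to stop"
  out[trials$outcome == "stop_wrong_hand"] <- "Stopped wrong hand"
  cont_rt <- ifelse(trials$trial_type == "left_stop", trials$rt_right,
                    trials$rt_left)
  succ <- trials$outcome == "stop_success"
  out[succ] <- sprintf("%.3f s", cont_rt[succ] / 1000)
  prem <- trials$outcome == "stop_premature_response"
  out[prem] <- rt_txt[prem]
  out
}

#' Simulate a full session from a trial schedule
#'
#' Go trials are simulated in bulk (they do not interact with the
#' staircases); stop trials are simulated sequentially in schedule order,
#' each reading and updating the per-hand, per-condition staircase, which is
#' initialised at 200 ms at the first stop trial of each condition (practice
#' stop trials therefore warm the staircase up before the main blocks). The
#' "Respond quicker" feedback threshold is the go-only-block mean RT plus
#' 250 ms.
#'
#' @param schedule tibble from [build_schedule()] / [assign_tms()].
#' @param params a [subject_params()].
#' @param rng_seed integer seed; identical seed, schedule and parameters
#'   reproduce the identical table.
#' @return tibble of executed trials: the schedule columns plus `trial_uid`,
#'   `rt_left`, `rt_right` (ms from IS onset), `ssd`, `outcome`, `feedback`.
#' @export
simulate_session <- function(schedule, params, rng_seed = 1L) {
  stopifnot(inherits(params, "selstop_params"))
  validate_schedule(schedule)
  schedule <- as_tibble(schedule)
  n <- nrow(schedule)
  withr::with_seed(as.integer(rng_seed), {
    res <- tibble(rt_left = rep(NA_real_, n), rt_right = NA_real_,
                  ssd = NA_real_, outcome = NA_character_)
    is_go <- schedule$trial_type == "go"
    if (any(is_go)) res[is_go, ] <- sim_go_trials(schedule[is_go, ], params)
    state <- list()
    for (i in which(!is_go)) {
      key <- staircase_key(schedule$condition[i], schedule$trial_type[i])
      if (is.null(state[[key]])) state[[key]] <- 200
      r <- sim_stop_trial(schedule$condition[i], schedule$trial_type[i],
                          state[[key]], params)
      state[[key]] <- update_staircase(state[[key]], r$responded)
      res$rt_left[i] <- r$rt_left
      res$rt_right[i] <- r$rt_right
      res$ssd[i] <- r$ssd
      res$outcome[i] <- r$outcome
    }
    out <- bind_rows(cbind(schedule, res))
    go_only_rt <- rowMeans(cbind(out$rt_left, out$rt_right))[
      out$phase == "go_only" & out$outcome == "go_correct"]
    goonly_mean <- if (length(go_only_rt)) mean(go_only_rt) else NA
    out$feedback <- feedback_label(out, goonly_mean)
    out$trial_uid <- paste(out$participant_id, out$block_index,
                           out$trial_index_in_block, sep = ":")
    out
  })
}

#' Simulate MEP records for one TMS trial
#'
#' CSE (unconditioned dual-coil) trials yield two records, one per hand;
#' conditioned SIHI/LIHI trials yield a single record in the hand receiving
#' the test pulse (LR pathways: left hand; RL pathways: right hand).
#' Amplitudes are Gamma with mean equal to the subject's unconditioned mean
#' for the trial's hand status, multiplied by the planted
#' conditioned/unconditioned ratio on conditioned trials. Uses the current
#' RNG state.
#'
#' @param spec one-row trial specification with `tms_type != "none"`.
#' @param params a [subject_params()].
#' @return tibble of one or two MEP records with columns `measured_hand`,
#'   `hand_status`, `conditioned`, `amplitude` (mV) and `rms_pre` (mV).
#' @export
simulate_mep <- function(spec, params) {
  stopifnot(nrow(spec) == 1)
  if (spec$tms_type == "none") {
    stop("simulate_mep: trial carries no TMS", call. = FALSE)
  }
  sim_mep_records(as_tibble(spec), params)
}

sim_mep_records <- function(spec, params) {
  cse <- spec[spec$tms_type == "CSE", ]
  cond <- spec[spec$tms_type != "CSE", ]
  recs <- bind_rows(
    mutate(cse, measured_hand = "left"),
    mutate(cse, measured_hand = "right"),
    mutate(cond, measured_hand = c("right", "left")[grepl("_LR$", tms_type) + 1L])
  )
  recs$conditioned <- recs$tms_type != "CSE"
  recs$hand_status <- label_hand_status(recs$cue, recs$trial_type,
                                        recs$tms_timepoint, recs$measured_hand)
  mu <- params$cse_mean[recs$hand_status]
  cls <- substr(recs$tms_type, 1, 4)
  is_cond <- which(recs$conditioned)
  mu[is_cond] <- mu[is_cond] *
    params$ihi_ratio[cbind(cls[is_cond], recs$hand_status[is_cond])]
  recs$amplitude <- rgamma(nrow(recs), shape = params$mep_shape,
                           rate = params$mep_shape / mu)
  contaminated <- runif(nrow(recs)) < params$p_emg_contaminated
  recs$rms_pre <- ifelse(contaminated,
                         0.025 + rexp(nrow(recs), 1 / 0.02),
                         runif(nrow(recs), 0, 0.02))
  recs
}

#' Simulate the MEP table for an executed session
#'
#' @param trials executed-trial table from [simulate_session()].
#' @param params a [subject_params()].
#' @param rng_seed integer seed.
#' @param main_only restrict to main-phase trials (default TRUE).
#' @return tidy MEP table, one row per measured hand and TMS trial.
#' @export
simulate_mep_table <- function(trials, params, rng_seed = 1L, main_only = TRUE) {
  tms <- trials[trials$tms_type != "none", ]
  if (main_only) tms <- tms[tms$phase == "main", ]
  if (nrow(tms) == 0) {
    stop("simulate_mep_table: no TMS-bearing trials; run assign_tms() first",
         call. = FALSE)
  }
  withr::with_seed(as.integer(rng_seed), {
    recs <- sim_mep_records(as_tibble(tms), params)
    recs <- arrange(recs, block_index, trial_index_in_block, measured_hand)
    keep <- c("participant_id", "trial_uid", "phase", "condition", "cue",
              "trial_type", "block_index", "trial_index_in_block", "tms_type",
              "tms_timepoint", "measured_hand", "hand_status", "conditioned",
              "amplitude", "rms_pre", "outcome")
    recs[, intersect(keep, names(recs))]
  })
}

#' Simulate a cohort: trial and MEP tables for n participants
#'
#' Draws each participant's generative parameters from the population model,
#' builds and TMS-allocates their schedule, simulates the session and the
#' MEP records. One master seed fans out deterministically to per-subject
#' parameter, schedule, session and MEP seeds.
#'
#' @param n_subjects number of participants (>= 1).
#' @param config a [cohort_config()].
#' @param rng_seed master integer seed.
#' @return list with `trials` (all executed trials), `meps` (all MEP
#'   records) and `params` (per-subject generative parameters).
#' @export
simulate_cohort <- function(n_subjects, config = cohort_config(), rng_seed = 1L) {
  stopifnot(inherits(config, "selstop_cohort_config"))
  if (n_subjects < 1) stop("simulate_cohort: n_subjects must be >= 1", call. = FALSE)
  seeds <- matrix(derive_seeds(rng_seed, 4L * n_subjects), ncol = 4L)
  trials <- vector("list", n_subjects)
  meps <- vector("list", n_subjects)
  params <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    id <- sprintf("S%02d", i)
    params[[i]] <- withr::with_seed(seeds[i, 1], draw_subject_params(config))
    sched <- build_schedule(id, config$design, rng_seed = seeds[i, 2])
    sched <- assign_tms(sched, config$design, rng_seed = seeds[i, 2])
    trials[[i]] <- simulate_session(sched, params[[i]], rng_seed = seeds[i, 3])
    meps[[i]] <- simulate_mep_table(trials[[i]], params[[i]], rng_seed = seeds[i, 4])
  }
  names(params) <- sprintf("S%02d", seq_len(n_subjects))
  out <- list(trials = bind_rows(trials), meps = bind_rows(meps), params = params)
  names(out$trials)[names(out$trials) == "participant_id"] <- "subject_id"
  names(out$meps)[names(out$meps) == "participant_id"] <- "subject_id"
  out
}

#' Synthesize an EMG trace around a test TMS pulse
#'
#' Builds a sampled EMG segment (2,000 Hz by default) containing pre-pulse
#' activity of a given RMS and a biphasic MEP-like deflection of a given
#' peak-to-peak amplitude, centred ~20-35 ms after the test pulse. Used to
#' exercise the trace-level peak-to-peak and RMS operators.
#'
#' @param amplitude peak-to-peak MEP amplitude (mV).
#' @param rms_pre RMS (mV) of a square-wave pre-pulse contamination (0 for a
#'   quiet baseline).
#' @param sampling_rate Hz.
#' @param pre_ms,post_ms trace extent around the pulse (ms).
#' @return list with `trace` (numeric, mV) and `test_pulse_index`.
#' @export
synth_emg_trace <- function(amplitude, rms_pre = 0, sampling_rate = 2000,
                            pre_ms = 60, post_ms = 110) {
  n_pre <- round(pre_ms * sampling_rate / 1000)
  n_post <- round(post_ms * sampling_rate / 1000)
  i0 <- n_pre + 1L
  t_ms <- (seq_len(n_pre + 1 + n_post) - i0) * 1000 / sampling_rate
  trace <- numeric(length(t_ms))
  ## biphasic deflection between 20 and 36 ms post pulse; the 16 ms period
  ## puts both extrema exactly on the 2,000 Hz sample grid
  w <- t_ms >= 20 & t_ms <= 36
  trace[w] <- (amplitude / 2) * sin(2 * pi * (t_ms[w] - 20) / 16)
  if (rms_pre > 0) {
    pre <- t_ms < 0 & t_ms >= -50
    trace[pre] <- rms_pre * rep_len(c(1, -1), sum(pre))
  }
  list(trace = trace, test_pulse_index = i0)
}
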