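## Shared fixtures, all built in code at test time.

## A trimmed design for fast session-level tests: one reactive and two
## proactive main blocks, no practice, no go-only block, and a TMS table
## scaled to fit (counts divisible across blocks).
small_design <- function() {
  alloc <- tms_allocation()
  alloc$n_total <- ifelse(alloc$condition == "reactive",
                          pmax(1L, alloc$n_total %/% 5L),
                          pmax(2L, alloc$n_total %/% 5L))
  design_config(go_only_trials = 10,
                reactive_practice = c(go = 0, left_stop = 0, right_stop = 0),
                reactive_main_blocks = 1,
                proactive_practice_per_cue = c(go = 0, stop = 0),
                proactive_main_blocks = 2,
                tms_allocation = alloc)
}

small_session <- function(seed = 1, params = subject_params(), id = "S01") {
  sched <- assign_tms(build_schedule(id, small_design(), seed),
                      small_design(), seed)
  tr <- simulate_session(sched, params, rng_seed = seed)
  tr$subject_id <- tr$participant_id
  tr
}

## Hand-built minimal trial rows for the processing rules.
toy_trial <- function(trial_type, outcome, rt_left = NA, rt_right = NA,
                      ssd = NA, condition = "reactive", subject_id = "S01") {
  tibble::tibble(subject_id = subject_id, phase = "main",
                 condition = condition,
                 cue = ifelse(condition == "reactive", "fixation",
                              ifelse(trial_type == "right_stop", "MSR", "MSL")),
                 trial_type = trial_type, block_index = 1L,
                 trial_index_in_block = 0L, tms_type = "none",
                 tms_timepoint = "none", rt_left = rt_left,
                 rt_right = rt_right, ssd = ssd, outcome = outcome,
                 feedback = "")
}

## Brute-force oracles for the posterior indices: direct counting for pd and
## an exhaustive scan over every contiguous window of the sorted draws for
## the shortest interval holding the requested mass.
oracle_hdi <- function(x, credible = 0.89) {
  s <- sort(x)
  n <- length(s)
  n_in <- ceiling(credible * n)
  best <- c(-Inf, Inf)
  for (i in 1:(n - n_in + 1)) {
    lo <- s[i]; hi <- s[i + n_in - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}
oracle_pd <- function(x, null = 0) {
  above <- sum(x > null)
  100 * max(above, length(x) - above) / length(x)
}

## One cohort at the study's full scale (27 participants), simulated once
## and shared by the acceptance checks that need it.
full_cohort_cache <- new.env(parent = emptyenv())
full_cohort <- function() {
  if (is.null(full_cohort_cache$cohort)) {
    full_cohort_cache$cohort <- simulate_cohort(27, cohort_config(),
                                                rng_seed = 20260924)
  }
  full_cohort_cache$cohort
}
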