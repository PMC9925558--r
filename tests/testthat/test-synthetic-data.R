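test_that("staircase follows the 1-up/1-down rule with a 50 ms floor", {
  ## responded = TRUE is a failed stop (SSD eases down); FALSE a success
  expect_equal(update_staircase(200, FALSE), 250)
  expect_equal(update_staircase(200, TRUE), 150)
  expect_equal(update_staircase(100, TRUE), 50)
  expect_equal(update_staircase(50, TRUE), 50)
  expect_equal(update_staircase(50, FALSE), 100)
  expect_equal(update_staircase(150, NA), 150)  # missed stop: unchanged
})

test_that("go outcomes follow the synchrony rule at the 50 ms boundary", {
  expect_equal(classify_synchrony(400, 448), "go_correct")
  expect_equal(classify_synchrony(400, 449), "go_correct")
  expect_equal(classify_synchrony(400, 450), "go_async_error")
  expect_equal(classify_synchrony(400, 451), "go_async_error")
  expect_equal(classify_synchrony(460, 400), "go_async_error")
  ## and the simulator's own go trials obey it
  tr <- small_session(seed = 2)
  go <- tr[tr$trial_type == "go" & !is.na(tr$rt_left) & !is.na(tr$rt_right), ]
  both <- go[go$outcome %in% c("go_correct", "go_async_error"), ]
  expect_equal(both$outcome, classify_synchrony(both$rt_left, both$rt_right))
})

test_that("lapse-free generator yields no go errors or omissions", {
  p <- subject_params(p_omission = 0, p_incomplete = 0, sync_jitter_sd = 0)
  tr <- small_session(seed = 3, params = p)
  go <- tr[tr$trial_type == "go", ]
  expect_true(all(go$outcome == "go_correct"))
  expect_true(all(abs(go$rt_left - go$rt_right) < 1e-9))
})

test_that("an unwinnable stop race fails every stop trial and floors the SSD", {
  p <- subject_params(ssrt = c(reactive = 1e9, proactive = 1e9),
                      p_omission = 0, p_wrong_hand = 0)
  tr <- small_session(seed = 4, params = p)
  stops <- tr[tr$trial_type != "go", ]
  expect_true(all(stops$outcome %in% c("stop_fail", "stop_premature_response")))
  ## staircase marches to and stays at the floor
  expect_equal(min(stops$ssd), 50)
  last_block <- stops[stops$block_index == max(stops$block_index), ]
  expect_true(mean(last_block$ssd == 50) > 0.8)
})

test_that("signal-respond RT is faster than go RT (race-model truncation)", {
  tr <- small_session(seed = 5)
  for (cond in unique(tr$condition[tr$phase == "main"])) {
    d <- tr[tr$phase == "main" & tr$condition == cond, ]
    go_rt <- rowMeans(cbind(d$rt_left, d$rt_right))[d$outcome == "go_correct"]
    sr <- d[d$outcome == "stop_fail", ]
    sr_rt <- ifelse(sr$trial_type == "left_stop", sr$rt_left, sr$rt_right)
    expect_lt(mean(sr_rt), mean(go_rt))
  }
})

test_that("premature and wrong-hand stop outcomes are classified and staircased", {
  ## finishing times (~60 ms) always beat an SSD of 200: premature response
  p <- subject_params(go_mean = 60, go_sd = 5, go_shift = 0,
                      proactive_go_slowing = 0, p_omission = 0,
                      p_incomplete = 0, p_wrong_hand = 0)
  spec <- build_schedule("S01", small_design(), 1)
  spec <- spec[spec$trial_type == "left_stop", ][1, ]
  withr::with_seed(9, {
    out <- simulate_trial(spec, p, state = list(reactive.left = 200))
  })
  expect_equal(out$result$outcome, "stop_premature_response")
  expect_false(is.na(out$result$rt_left) || is.na(out$result$rt_right))
  expect_equal(out$state$reactive.left, 150)  # counted as a response
  ## certain wrong-hand lapse at a reachable SSD
  p2 <- subject_params(p_wrong_hand = 1, p_omission = 0)
  withr::with_seed(10, {
    out2 <- simulate_trial(spec, p2, state = list(reactive.left = 50))
  })
  expect_equal(out2$result$outcome, "stop_wrong_hand")
  expect_false(is.na(out2$result$rt_left))  # the cued (stopping) hand pressed
  expect_true(is.na(out2$result$rt_right))
  expect_equal(out2$state$reactive.left, 50)  # response at the floor stays
})

test_that("successful stops have one RT and carry the interference delay", {
  p <- subject_params(p_omission = 0, p_incomplete = 0, p_wrong_hand = 0)
  tr <- small_session(seed = 6, params = p)
  succ <- tr[tr$outcome == "stop_success", ]
  expect_gt(nrow(succ), 10)
  one_rt <- xor(is.na(succ$rt_left), is.na(succ$rt_right))
  expect_true(all(one_rt))
  ## continuing hand is the uncued one
  expect_true(all(is.na(succ$rt_left[succ$trial_type == "left_stop"])))
  expect_true(all(is.na(succ$rt_right[succ$trial_type == "right_stop"])))
})

test_that("fixed seeds reproduce sessions and cohorts bit-identically", {
  p <- subject_params()
  sch <- assign_tms(build_schedule("S01", small_design(), 7),
                    small_design(), 7)
  expect_identical(simulate_session(sch, p, 7), simulate_session(sch, p, 7))
  cfg <- cohort_config(design = small_design())
  a <- simulate_cohort(2, cfg, rng_seed = 11)
  b <- simulate_cohort(2, cfg, rng_seed = 11)
  expect_identical(a$trials, b$trials)
  expect_identical(a$meps, b$meps)
  c <- simulate_cohort(2, cfg, rng_seed = 12)
  expect_false(identical(a$trials$rt_left, c$trials$rt_left))
})

test_that("MEP generator recovers planted conditioning ratios", {
  ihi <- cohort_config()$ihi_ratio
  ihi["SIHI", "WS_baseline"] <- 0.69
  p <- subject_params(ihi_ratio = ihi, mep_shape = 200,
                      p_emg_contaminated = 0)
  spec_ws_cse <- tibble::tibble(
    participant_id = "S01", phase = "main", condition = "reactive",
    cue = "fixation", trial_type = "go", block_index = 1L,
    trial_index_in_block = 0L, tms_type = "CSE", tms_timepoint = "WS")
  spec_ws_sihi <- spec_ws_cse
  spec_ws_sihi$tms_type <- "SIHI_LR"
  withr::with_seed(13, {
    uncond <- do.call(rbind, replicate(2000, simulate_mep(spec_ws_cse, p),
                                       simplify = FALSE))
    cond <- do.call(rbind, replicate(2000, simulate_mep(spec_ws_sihi, p),
                                     simplify = FALSE))
  })
  ratio <- mean(cond$amplitude) / mean(uncond$amplitude)
  expect_equal(ratio, 0.69, tolerance = 0.02)
  ## null conditioning: identical distributions
  p_null <- subject_params(ihi_ratio = ihi * 0 + 1, mep_shape = 200,
                           p_emg_contaminated = 0)
  withr::with_seed(14, {
    u0 <- do.call(rbind, replicate(1500, simulate_mep(spec_ws_cse, p_null),
                                   simplify = FALSE))
    c0 <- do.call(rbind, replicate(1500, simulate_mep(spec_ws_sihi, p_null),
                                   simplify = FALSE))
  })
  expect_equal(mean(c0$amplitude) / mean(u0$amplitude), 1, tolerance = 0.03)
  expect_error(simulate_mep(transform(spec_ws_cse, tms_type = "none"), p),
               "no TMS")
})

test_that("pre-pulse contamination occurs at the configured rate", {
  p1 <- subject_params(p_emg_contaminated = 1)
  tr <- small_session(seed = 8, params = p1)
  m1 <- simulate_mep_table(tr, p1, rng_seed = 8)
  expect_true(all(m1$rms_pre > 0.025))
  p0 <- subject_params(p_emg_contaminated = 0)
  m0 <- simulate_mep_table(tr, p0, rng_seed = 8)
  expect_true(all(m0$rms_pre <= 0.025))
})
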