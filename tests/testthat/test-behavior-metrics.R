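test_that("correct-RT filter keeps correct trials, drops fast guesses, derives rt_rel_ss", {
  tab <- dplyr::bind_rows(
    toy_trial("go", "go_correct", rt_left = 400, rt_right = 420),
    toy_trial("go", "go_correct", rt_left = 180, rt_right = 180),  # fast guess
    toy_trial("go", "go_async_error", rt_left = 400, rt_right = 460),
    toy_trial("left_stop", "stop_success", rt_right = 533, ssd = 161),
    toy_trial("left_stop", "stop_fail", rt_left = 380, rt_right = 390, ssd = 150)
  )
  f <- filter_correct_rt(tab)
  expect_equal(nrow(f), 2)
  expect_equal(f$rt, c(410, 533))
  expect_equal(f$rt_rel_ss, c(NA, 533 - 161))
  ## empty in, empty out
  expect_equal(nrow(filter_correct_rt(tab[0, ])), 0)
  ## stop rows without SSD are rejected
  bad <- toy_trial("left_stop", "stop_success", rt_right = 500, ssd = NA)
  expect_error(filter_correct_rt(bad), "SSD")
})

test_that("task summary matches hand counts on an enumerated toy table", {
  tab <- dplyr::bind_rows(
    toy_trial("go", "go_correct", 400, 410),
    toy_trial("go", "go_correct", 420, 430),
    toy_trial("go", "go_correct", 440, 450),
    toy_trial("go", "go_correct", 460, 470),
    toy_trial("go", "go_async_error", 400, 460),
    toy_trial("left_stop", "stop_fail", 390, 395, ssd = 100)
  )
  s <- summarize_sst(tab)
  expect_equal(s$go_error_pct, 20)
  expect_equal(s$go_omission_pct, 0)
  expect_equal(s$p_respond_stop, 1)
  expect_equal(s$mean_go_rt, mean(c(405, 425, 445, 465)))
  expect_equal(s$mean_ssd, 100)
  expect_equal(s$mean_signal_respond_rt, 390)  # stopping (left) hand
})

test_that("cohort-level summary hits the staircase design goal", {
  s <- summarize_sst(full_cohort()$trials)
  expect_equal(nrow(s), 2)
  expect_true(all(abs(s$p_respond_stop - 0.5) < 0.05))
  expect_true(all(s$mean_ssd > 100 & s$mean_ssd < 250))
  ## signal-respond faster than go in both conditions
  expect_true(all(s$mean_signal_respond_rt < s$mean_go_rt))
})

test_that("integration-method SSRT matches the hand-computed oracle", {
  go <- lapply(c(300, 350, 400, 450, 500), function(rt)
    toy_trial("go", "go_correct", rt, rt))
  stops <- c(
    lapply(1:5, function(i) toy_trial("left_stop", "stop_fail",
                                      rt_left = 320, rt_right = 330, ssd = 150)),
    lapply(1:5, function(i) toy_trial("left_stop", "stop_success",
                                      rt_right = 520, ssd = 150)))
  tab <- dplyr::bind_rows(c(go, stops))
  est <- estimate_ssrt(tab, "S01", "reactive", "left")
  ## p = 0.5, N = 5 -> n = ceil(2.5) = 3 -> 400 - 150 = 250
  expect_true(est$valid)
  expect_equal(est$p_respond, 0.5)
  expect_equal(est$ssrt, 250)
})

test_that("SSRT validity exclusions fire as specified", {
  go <- dplyr::bind_rows(lapply(c(300, 350, 400, 450, 500), function(rt)
    toy_trial("go", "go_correct", rt, rt)))
  mk_stops <- function(n_fail, n_succ, fail_rt = 320) dplyr::bind_rows(c(
    lapply(seq_len(n_fail), function(i)
      toy_trial("left_stop", "stop_fail", rt_left = fail_rt,
                rt_right = fail_rt, ssd = 150)),
    lapply(seq_len(n_succ), function(i)
      toy_trial("left_stop", "stop_success", rt_right = 520, ssd = 150))))
  ## p = 0.8 -> out of range
  e1 <- estimate_ssrt(dplyr::bind_rows(go, mk_stops(8, 2)), "S01",
                      "reactive", "left")
  expect_false(e1$valid)
  expect_equal(e1$exclusion_reason, "p_respond_out_of_range")
  expect_true(is.na(e1$ssrt))
  ## p = 0.2 -> out of range from below
  e2 <- estimate_ssrt(dplyr::bind_rows(go, mk_stops(2, 8)), "S01",
                      "reactive", "left")
  expect_equal(e2$exclusion_reason, "p_respond_out_of_range")
  ## mean signal-respond RT above mean go RT -> race-model violation
  e3 <- estimate_ssrt(dplyr::bind_rows(go, mk_stops(5, 5, fail_rt = 450)),
                      "S01", "reactive", "left")
  expect_false(e3$valid)
  expect_equal(e3$exclusion_reason, "race_model_violation")
  ## no stop trials at all
  e4 <- estimate_ssrt(go, "S01", "reactive", "left")
  expect_false(e4$valid)
  ## no go trials is a hard error
  expect_error(estimate_ssrt(mk_stops(5, 5), "S01", "reactive", "left"),
               "go trials")
})

test_that("SSRT shifts by exactly c when every go RT shifts by c", {
  tr <- small_session(seed = 21)
  base <- estimate_ssrt(tr, "S01", "reactive", "left")
  shifted <- tr
  is_go <- shifted$trial_type == "go"
  shifted$rt_left[is_go] <- shifted$rt_left[is_go] + 37
  shifted$rt_right[is_go] <- shifted$rt_right[is_go] + 37
  est <- estimate_ssrt(shifted, "S01", "reactive", "left")
  expect_equal(est$ssrt, base$ssrt + 37)
})

test_that("go omissions are replaced by the slowest go RT and never lower the estimate", {
  tr <- small_session(seed = 22)
  base <- estimate_ssrt(tr, "S01", "reactive", "left")
  with_omissions <- dplyr::bind_rows(
    tr, dplyr::bind_rows(replicate(10, toy_trial("go", "go_missed"),
                                   simplify = FALSE)))
  est <- estimate_ssrt(with_omissions, "S01", "reactive", "left")
  expect_gte(est$ssrt, base$ssrt)
})

test_that("every subject x condition x hand cell yields exactly one estimate", {
  cohort <- simulate_cohort(2, cohort_config(design = small_design()),
                            rng_seed = 31)
  est <- estimate_ssrt_all(cohort$trials)
  expect_equal(nrow(est), 2 * 2 * 2)
  expect_equal(anyDuplicated(est[c("subject_id", "condition", "hand")]), 0)
  expect_true(all(est$valid == (est$exclusion_reason == "none")))
  expect_true(all(est$valid == !is.na(est$ssrt)))
})

test_that("interference table recovers planted elongation and toy arithmetic", {
  tab <- dplyr::bind_rows(
    toy_trial("go", "go_correct", 400, 400),
    toy_trial("go", "go_correct", 400, 400),
    toy_trial("left_stop", "stop_success", rt_right = 480, ssd = 150))
  it <- interference_table(filter_correct_rt(tab))
  expect_equal(it$interference_ms, 80)
  expect_equal(it$interference_pct, 20)
  ## null interference, no cue effects -> elongation ~ 0
  p_null <- subject_params(interference_mult = c(reactive = 1, proactive = 1),
                           proactive_go_slowing = 0)
  tr <- small_session(seed = 23, params = p_null)
  it0 <- interference_table(filter_correct_rt(tr))
  expect_true(all(abs(it0$interference_pct) < 5))
})
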