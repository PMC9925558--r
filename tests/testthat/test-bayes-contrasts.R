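fake_fit <- function(cells, draws, family = "gamma_log", sigma = NULL,
                     shift = 150) {
  colnames(draws) <- paste0("cell:", cells)
  if (!is.null(sigma)) draws <- cbind(draws, sigma = sigma)
  structure(list(spec = list(family = family, shift = shift), draws = draws,
                 cells = cells, rhat = rep(1, ncol(draws)),
                 n_obs = 0L, n_draws = nrow(draws)),
            class = "selstop_fit")
}

test_that("pd and the 89% HDI equal their brute-force oracles exactly", {
  withr::with_seed(100, {
    vectors <- list(
      rnorm(1e4), exp(rnorm(1e4, 0, 0.5)), rnorm(1e4, 2, 0.1),
      c(rnorm(5e3, -1, 0.3), rnorm(5e3, 1.5, 0.6)),  # bimodal, skewed
      rgamma(1e4, 2, 1) - 1)
  })
  for (x in vectors) {
    expect_equal(unname(hdi(x)), oracle_hdi(x))
    expect_equal(prob_direction(x), oracle_pd(x))
    expect_equal(prob_direction(x, null = 0.5), oracle_pd(x, 0.5))
  }
  expect_error(hdi(rnorm(50)), "at least 100")
})

test_that("the HDI of 12,000 standard-normal draws matches the analytic interval", {
  withr::with_seed(101, x <- rnorm(12000))
  h <- hdi(x)
  z <- qnorm(0.5 + 0.89 / 2)  # 1.598, central = HDI by unimodal symmetry
  expect_equal(unname(h), c(-z, z), tolerance = 0.05)
  expect_equal(prob_direction(x), 50, tolerance = 3)
})

test_that("the HDI+ROPE decision rule is total and matches containment", {
  accept <- summarize_contrast(
    posterior_draws(runif(1000, -0.01, 0.02), "log_odds"))
  expect_equal(accept$decision, "accept_null")
  expect_equal(accept$pct_hdi_in_rope, 100)
  reject <- summarize_contrast(
    posterior_draws(rnorm(1000, 20, 1), "percent_change"))
  expect_equal(reject$decision, "reject_null")
  expect_equal(reject$pct_hdi_in_rope, 0)
  expect_equal(reject$pd, 100)
  undec <- summarize_contrast(
    posterior_draws(rnorm(1000, 5, 3), "percent_change"))
  expect_equal(undec$decision, "undecided")
  expect_true(undec$pct_hdi_in_rope > 0 && undec$pct_hdi_in_rope < 100)
  ## invariant: ordering of the summary fields
  for (s in list(accept, reject, undec)) {
    expect_lte(s$hdi89_low, s$median)
    expect_gte(s$hdi89_high, s$median)
    expect_true(s$pd >= 50 && s$pd <= 100)
  }
})

test_that("contrasts transform the link scale as documented", {
  draws <- cbind(rep(log(2), 500), rep(log(2) + log(0.9), 500))
  fit <- fake_fit(c("a", "b"), draws)
  ## self-contrast: ratio identically 1
  self <- contrast(fit, "a", "a", scale = "ratio")
  expect_true(all(self$draws == 1))
  ## log difference of ln(0.9) -> exactly -10% change
  pct <- contrast(fit, "b", "a", scale = "percent_change")
  expect_true(all(abs(pct$draws - (-10)) < 1e-12))
  rat <- contrast(fit, "b", "a", scale = "ratio")
  expect_true(all(abs(rat$draws - 0.9) < 1e-12))
  ## weighted ratio-of-ratios via named weights
  fit4 <- fake_fit(c("c1", "u1", "c2", "u2"),
                   matrix(rep(log(c(1.12, 1, 0.87, 1)), each = 300), nrow = 300))
  ror <- contrast(fit4, a = c(c1 = 1, u2 = 1), b = c(c2 = 1, u1 = 1),
                  scale = "ratio")
  expect_equal(ror$draws[1], 1.12 / 0.87, tolerance = 1e-12)
  expect_error(contrast(fit, "a", "nope"), "unknown cells")
})

test_that("gaussian and gamma intercept-only fits recover simple truths", {
  withr::with_seed(200, {
    d1 <- tibble::tibble(y = rep(c(1, 2, 3), each = 30))
    spec1 <- model_spec("gaussian_identity", "y", random = "none",
                        chains = 2, warmup = 300, draws = 500)
    f1 <- fit_model(spec1, d1, rng_seed = 1)
    expect_equal(median(f1$draws[, "cell:(Intercept)"]), 2, tolerance = 0.15)
    expect_true(all(f1$rhat < 1.1, na.rm = TRUE))

    d2 <- tibble::tibble(y = rgamma(800, shape = 4, rate = 4 / 2.15))
    spec2 <- model_spec("gamma_log", "y", random = "none",
                        chains = 2, warmup = 300, draws = 500)
    f2 <- fit_model(spec2, d2, rng_seed = 2)
    expect_equal(median(exp(f2$draws[, "cell:(Intercept)"])), 2.15,
                 tolerance = 0.1)
  })
})

test_that("a two-level gamma fixture recovers the planted mean ratio", {
  withr::with_seed(201, {
    d <- tibble::tibble(
      y = c(rgamma(1500, 10, 10 / 1.12), rgamma(1500, 10, 10 / 0.87)),
      grp = rep(c("hi", "lo"), each = 1500))
  })
  spec <- model_spec("gamma_log", "y", fixed = "grp", random = "none",
                     chains = 2, warmup = 300, draws = 500)
  f <- fit_model(spec, d, rng_seed = 3)
  r <- contrast(f, "hi", "lo", scale = "ratio")
  s <- summarize_contrast(r, rope = c(0.95, 1.05))
  expect_equal(s$median, 1.287, tolerance = 0.03)
  expect_equal(s$decision, "reject_null")
})

test_that("shifted-lognormal fits recover response-scale means with a known shift", {
  withr::with_seed(202, {
    d <- tibble::tibble(
      rt = c(150 + exp(rnorm(1200, log(280), 0.31)),
             150 + exp(rnorm(1200, log(280) + log(1.191), 0.31))),
      role = rep(c("go", "stop"), each = 1200))
  })
  spec <- model_spec("shifted_lognormal_identity", "rt", fixed = "role",
                     random = "none", shift = 150,
                     chains = 2, warmup = 300, draws = 500)
  f <- fit_model(spec, d, rng_seed = 4)
  pct <- summarize_contrast(contrast(f, "stop", "go", scale = "percent_change"))
  ## planted: mean RT ratio (150+280*1.191) / (150+280) - 1 = 12.45%
  planted <- 100 * ((150 + 280 * 1.191) / (150 + 280) - 1)
  expect_equal(pct$median, planted, tolerance = 1.5)
  ms <- summarize_contrast(contrast(f, "stop", "go", scale = "ms"))
  expect_equal(ms$median, 280 * 0.191, tolerance = 8)
  expect_equal(ms$scale_tag, "ms")
})

test_that("a null logistic slope is inconsistent and practically equivalent to zero", {
  withr::with_seed(203, {
    d <- tibble::tibble(y = rbinom(1500, 1, 0.5), amplitude = rgamma(1500, 4, 2))
  })
  spec <- model_spec("bernoulli_logit", "y", covariates = "amplitude",
                     random = "none", chains = 2, warmup = 300, draws = 500)
  f <- fit_model(spec, d, rng_seed = 5)
  s <- summarize_contrast(posterior_draws(f$draws[, "slope:amplitude"],
                                          "log_odds"))
  expect_lt(s$pd, 95)
  expect_lt(abs(s$median), 0.2)
})

test_that("family preconditions are enforced", {
  expect_error(fit_model(model_spec("gamma_log", "y", random = "none"),
                         tibble::tibble(y = c(1, -1))), "positive")
  expect_error(fit_model(model_spec("bernoulli_logit", "y", random = "none"),
                         tibble::tibble(y = c(0, 2))), "0/1")
  expect_error(fit_model(model_spec("shifted_lognormal_identity", "y",
                                    random = "none", shift = 150),
                         tibble::tibble(y = c(100, 400))), "shift")
  expect_error(fit_model(model_spec("gaussian_identity", "z", random = "none"),
                         tibble::tibble(y = 1)), "lacks columns")
})

test_that("split Rhat separates mixed from unmixed chains", {
  withr::with_seed(204, {
    good <- cbind(rnorm(500), rnorm(500))
    bad <- cbind(rnorm(500), rnorm(500) + 3)
  })
  expect_lt(split_rhat(good), 1.05)
  expect_gt(split_rhat(bad), 1.5)
})

test_that("posterior predictive check brackets the observed statistics", {
  withr::with_seed(205, d <- tibble::tibble(y = rgamma(600, 4, 2)))
  spec <- model_spec("gamma_log", "y", random = "none", chains = 2,
                     warmup = 300, draws = 400)
  f <- fit_model(spec, d, rng_seed = 6)
  ppc <- posterior_predictive_check(f, d, n_rep = 100)
  expect_true(all(ppc$observed >= ppc$rep_q05 - 0.2 &
                    ppc$observed <= ppc$rep_q95 + 0.2))
})
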