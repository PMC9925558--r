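## Bayesian mixed-model contrasts. Four response families cover the
## behavioural and neurophysiological analyses: shifted-lognormal (RTs),
## Gaussian (averaged SSRT), Gamma with log link (MEP amplitudes, where
## back-transformed contrasts are conditioned/unconditioned ratios) and
## Bernoulli with logit link (stopping success). Population-level effects
## use cell-means coding so that any reported effect is a linear contrast
## of cells. Sampling is delegated to JAGS; the posterior indices
## (probability of direction, 89% highest-density interval, % of HDI in
## ROPE and the HDI+ROPE decision) are computed here from the raw draws.

FAMILIES <- c("shifted_lognormal_identity", "gaussian_identity", "gamma_log",
              "bernoulli_logit")

#' Specify a Bayesian (G)LMM
#'
#' @param family one of `"shifted_lognormal_identity"`,
#'   `"gaussian_identity"`, `"gamma_log"`, `"bernoulli_logit"`.
#' @param response name of the response column.
#' @param fixed character vector of factor columns; the model estimates one
#'   population-level mean per combination of their levels (cell-means
#'   coding), so contrasts are formed directly between named cells.
#' @param covariates optional numeric columns entering as slopes (centred
#'   before sampling; slopes are unchanged by centring).
#' @param group grouping column for by-participant random intercepts.
#' @param random `"intercept"` (default) or `"none"`. Random slopes are
#'   deliberately not offered: the by-participant intercept is the part of
#'   the maximal structure that the reduced cohorts used here can support,
#'   and the simplification is logged on every fit.
#' @param shift fixed nondecision shift (ms) for the shifted-lognormal
#'   family: the model is a Gaussian on `log(y - shift)` and contrasts are
#'   formed on the implied response-scale means.
#' @param chains,warmup,draws MCMC layout; the default 8 chains x 1500
#'   warmup + 1500 kept draws yields 12,000 post-warmup draws.
#' @param prior_sd `NULL` for effectively flat population-level priors
#'   (normal with precision 1e-6); a number for a weakly-informative
#'   zero-centred normal SD, a fallback for hard fits.
#' @return list of class `selstop_model_spec`.
#' @export
model_spec <- function(family, response, fixed = character(0),
                       covariates = character(0), group = "subject_id",
                       random = c("intercept", "none"), shift = 150,
                       chains = 8, warmup = 1500, draws = 1500,
                       prior_sd = NULL) {
  family <- match.arg(family, FAMILIES)
  random <- match.arg(random)
  spec <- list(family = family, response = response, fixed = fixed,
               covariates = covariates, group = group, random = random,
               shift = shift, chains = as.integer(chains),
               warmup = as.integer(warmup), draws = as.integer(draws),
               prior_sd = prior_sd)
  stopifnot(spec$chains >= 1, spec$warmup >= 0, spec$draws >= 1)
  class(spec) <- "selstop_model_spec"
  spec
}

jags_model_string <- function(spec, has_covariates) {
  lik <- switch(spec$family,
    gaussian_identity = ,
    shifted_lognormal_identity =
      "    y[i] ~ dnorm(eta[i], tau)",
    gamma_log =
      "    y[i] ~ dgamma(shape, shape / exp(eta[i]))",
    bernoulli_logit =
      "    y[i] ~ dbern(ilogit(eta[i]))")
  eta <- "    eta[i] <- beta[cell[i]]"
  if (spec$random == "intercept") eta <- paste0(eta, " + u[subj[i]]")
  if (has_covariates) eta <- paste0(eta, " + inprod(X[i, ], slope)")
  prec <- if (is.null(spec$prior_sd)) "1.0E-6" else
    sprintf("%.8g", 1 / spec$prior_sd^2)
  aux <- switch(spec$family,
    gaussian_identity = ,
    shifted_lognormal_identity =
      "  tau ~ dgamma(1.0E-3, 1.0E-3)\n  sigma <- 1 / sqrt(tau)",
    gamma_log = "  shape ~ dunif(1.0E-2, 1.0E3)",
    bernoulli_logit = "")
  ## random intercepts carry a hard sum-to-zero constraint (the last one is
  ## derived), so under flat cell-mean priors every intercept stays
  ## likelihood-identified and no common mode drifts between chains; vague
  ## conjugate gamma priors on precisions give Gibbs-exact updates
  re <- if (spec$random == "intercept") paste0(
    "  for (j in 1:(J - 1)) { u[j] ~ dnorm(0, tau_u) }\n",
    "  u[J] <- -sum(u[1:(J - 1)])\n",
    "  tau_u ~ dgamma(1.0E-3, 1.0E-3)\n  sd_u <- 1 / sqrt(tau_u)") else ""
  cov <- if (has_covariates)
    sprintf("  for (p in 1:P) { slope[p] ~ dnorm(0, %s) }", prec) else ""
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n", lik, "\n", eta, "\n  }\n",
    sprintf("  for (k in 1:K) { beta[k] ~ dnorm(0, %s) }\n", prec),
    re, "\n", cov, "\n", aux, "\n}\n")
}

#' Fit a Bayesian (G)LMM and return its posterior draws
#'
#' Builds the cell-means design from the model specification, delegates
#' sampling to JAGS
#' (one independent chain per `spec$chains`, each seeded from `rng_seed` so
#' the fit is reproducible for a given data set, seed and JAGS version), and
#' returns the population-level draws together with a split-chain Rhat
#' convergence report; any parameter with Rhat >= 1.1 raises a structured
#' warning, never a silent pass.
#'
#' @param spec a [model_spec()].
#' @param data tidy table containing the response, factor, covariate and
#'   grouping columns.
#' @param rng_seed integer seed.
#' @return object of class `selstop_fit`: list with `draws` (matrix, one
#'   column per monitored parameter; cell means named `cell:<levels>`),
#'   `cells`, `rhat`, `spec`, `n_obs`.
#' @export
fit_model <- function(spec, data, rng_seed = 1L) {
  stopifnot(inherits(spec, "selstop_model_spec"))
  data <- as_tibble(data)
  miss <- setdiff(c(spec$response, spec$fixed, spec$covariates,
                    if (spec$random == "intercept") spec$group), names(data))
  if (length(miss)) {
    stop("fit_model: data lacks columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  y <- data[[spec$response]]
  if (is.logical(y)) y <- as.numeric(y)
  if (anyNA(y)) stop("fit_model: response contains NA", call. = FALSE)
  if (spec$family == "gamma_log" && any(y <= 0)) {
    stop("fit_model: gamma_log requires strictly positive responses",
         call. = FALSE)
  }
  if (spec$family == "bernoulli_logit" && !all(y %in% c(0, 1))) {
    stop("fit_model: bernoulli_logit requires a 0/1 response", call. = FALSE)
  }
  if (spec$family == "shifted_lognormal_identity") {
    if (any(y <= spec$shift)) {
      stop("fit_model: responses must exceed the shift (", spec$shift, " ms)",
           call. = FALSE)
    }
    y <- log(y - spec$shift)
  }
  cell <- if (length(spec$fixed)) {
    droplevels(interaction(data[spec$fixed], sep = ":", lex.order = TRUE))
  } else {
    factor(rep("(Intercept)", nrow(data)))
  }
  jdata <- list(y = y, N = length(y), cell = as.integer(cell),
                K = nlevels(cell))
  if (spec$random == "intercept") {
    subj <- factor(data[[spec$group]])
    if (nlevels(subj) < 2) {
      message("fit_model: single grouping level; dropping the random intercept")
      spec$random <- "none"
    } else {
      jdata$subj <- as.integer(subj)
      jdata$J <- nlevels(subj)
    }
  }
  has_cov <- length(spec$covariates) > 0
  if (has_cov) {
    X <- as.matrix(data[spec$covariates])
    X <- scale(X, center = TRUE, scale = FALSE)
    jdata$X <- X
    jdata$P <- ncol(X)
  }
  seeds <- derive_seeds(rng_seed, spec$chains)
  inits <- lapply(seeds, function(s) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
  })
  monitors <- c("beta",
                if (spec$family %in% c("gaussian_identity",
                                       "shifted_lognormal_identity")) "sigma",
                if (spec$family == "gamma_log") "shape",
                if (spec$random == "intercept") "sd_u",
                if (has_cov) "slope")
  code <- jags_model_string(spec, has_cov)
  model <- rjags::jags.model(textConnection(code), data = jdata,
                             n.chains = spec$chains, inits = inits,
                             n.adapt = max(100L, spec$warmup %/% 2L),
                             quiet = TRUE)
  stats::update(model, n.iter = max(0L, spec$warmup - spec$warmup %/% 2L),
                progress.bar = "none")
  samples <- rjags::coda.samples(model, variable.names = monitors,
                                 n.iter = spec$draws, progress.bar = "none")
  mats <- lapply(samples, as.matrix)
  combined <- do.call(rbind, mats)
  cn <- colnames(combined)
  for (k in seq_len(nlevels(cell))) {
    cn[cn == sprintf("beta[%d]", k)] <- paste0("cell:", levels(cell)[k])
  }
  if (nlevels(cell) == 1) cn[cn == "beta"] <- paste0("cell:", levels(cell)[1])
  if (has_cov) {
    for (p in seq_along(spec$covariates)) {
      cn[cn == sprintf("slope[%d]", p)] <- paste0("slope:", spec$covariates[p])
    }
    cn[cn == "slope"] <- paste0("slope:", spec$covariates[1])
  }
  colnames(combined) <- cn
  rhat <- vapply(seq_len(ncol(combined)), function(j) {
    split_rhat(do.call(cbind, lapply(mats, function(m) m[, j])))
  }, numeric(1))
  names(rhat) <- cn
  bad <- names(rhat)[!is.na(rhat) & rhat >= 1.1]
  if (length(bad)) {
    warning(sprintf("fit_model: convergence flagged (split Rhat >= 1.1) for: %s",
                    paste(sprintf("%s (%.2f)", bad, rhat[bad]), collapse = ", ")),
            call. = FALSE)
  }
  structure(list(spec = spec, draws = combined, cells = levels(cell),
                 rhat = rhat, n_obs = length(y),
                 n_draws = nrow(combined)),
            class = "selstop_fit")
}

#' @export
print.selstop_fit <- function(x, ...) {
  cat("Bayesian", x$spec$family, "fit:", x$n_obs, "observations,",
      length(x$cells), "cells,", x$n_draws, "post-warmup draws\n")
  cat("max split Rhat:", sprintf("%.3f", max(x$rhat, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Posterior-predictive summary of a fit
#'
#' Simulates replicate data sets from a thinned subset of the posterior and
#' compares their mean and SD with the observed response, for a quick
#' predictive check.
#'
#' @param fit a `selstop_fit`.
#' @param data the data the model was fitted to.
#' @param n_rep number of replicate data sets.
#' @return tibble with observed and replicate-quantile mean and SD.
#' @export
posterior_predictive_check <- function(fit, data, n_rep = 200) {
  spec <- fit$spec
  y <- data[[spec$response]]
  if (is.logical(y)) y <- as.numeric(y)
  cell <- if (length(spec$fixed)) {
    droplevels(interaction(data[spec$fixed], sep = ":", lex.order = TRUE))
  } else factor(rep("(Intercept)", nrow(data)))
  idx <- round(seq(1, fit$n_draws, length.out = n_rep))
  stats_rep <- t(vapply(idx, function(i) {
    eta <- fit$draws[i, paste0("cell:", as.character(cell))]
    yr <- switch(spec$family,
      gaussian_identity = rnorm(length(eta), eta, fit$draws[i, "sigma"]),
      shifted_lognormal_identity =
        spec$shift + exp(rnorm(length(eta), eta, fit$draws[i, "sigma"])),
      gamma_log = rgamma(length(eta), shape = fit$draws[i, "shape"],
                         rate = fit$draws[i, "shape"] / exp(eta)),
      bernoulli_logit = rbinom(length(eta), 1, stats::plogis(eta)))
    c(mean = mean(yr), sd = sd(yr))
  }, c(mean = 0, sd = 0)))
  tibble(statistic = c("mean", "sd"),
         observed = c(mean(y), sd(y)),
         rep_q05 = apply(stats_rep, 2, quantile, 0.05),
         rep_q50 = apply(stats_rep, 2, quantile, 0.50),
         rep_q95 = apply(stats_rep, 2, quantile, 0.95))
}

#' Wrap a vector of draws with its scale
#'
#' @param draws numeric vector of posterior draws of a contrast.
#' @param scale_tag one of `"ms"`, `"response"`, `"ratio"`,
#'   `"percent_change"`, `"log_odds"`, `"link"`.
#' @param null_value the scale's null (0 for differences, 1 for ratios).
#' @param reference reference response level (used for identity-link ROPEs
#'   defined as a percentage of the reference condition).
#' @return object of class `selstop_draws`.
#' @export
posterior_draws <- function(draws,
                            scale_tag = c("ms", "response", "ratio",
                                          "percent_change", "log_odds", "link"),
                            null_value = NULL, reference = NA_real_) {
  scale_tag <- match.arg(scale_tag)
  if (is.null(null_value)) {
    null_value <- if (scale_tag == "ratio") 1 else 0
  }
  stopifnot(is.numeric(draws), length(draws) >= 1)
  structure(list(draws = as.numeric(draws), scale_tag = scale_tag,
                 null_value = null_value, reference = reference,
                 n_draws = length(draws)),
            class = "selstop_draws")
}

#' Posterior contrast between cells of a fitted model
#'
#' Forms the per-draw difference between the average of the `a` cells and
#' the average of the `b` cells on the link scale, then moves it to the
#' requested reporting scale: for the Gamma log-link family, exponentiation
#' gives a ratio (`a`/`b`, e.g. a conditioned/unconditioned IHI ratio
#' change) and `100 * (ratio - 1)` a percent change; for the
#' shifted-lognormal family, response-scale cell means `shift + exp(mu +
#' sigma^2/2)` are contrasted so that percent changes refer to mean RTs
#' including the shift; identity-link contrasts stay in response units.
#'
#' @param fit a `selstop_fit`.
#' @param a,b cells to compare: character vectors (averaged with equal
#'   weight) or named numeric weight vectors for general linear
#'   combinations on the link scale, e.g. `c("SS150_continuing:conditioned"
#'   = 1, "IS:unconditioned" = 1)` against the crossed pair for a
#'   ratio-of-ratios contrast.
#' @param scale `"auto"` (family default: percent change for log links, ms
#'   for identity links, log-odds for the logistic) or one of `"ms"`,
#'   `"ratio"`, `"percent_change"`, `"log_odds"`, `"link"`.
#' @return a [posterior_draws()] object.
#' @export
contrast <- function(fit, a, b, scale = "auto") {
  stopifnot(inherits(fit, "selstop_fit"))
  as_weights <- function(x) {
    if (is.character(x)) setNames(rep(1 / length(x), length(x)), x) else x
  }
  a <- as_weights(a); b <- as_weights(b)
  bad <- setdiff(c(names(a), names(b)), fit$cells)
  if (length(bad)) {
    stop("contrast: unknown cells ", paste(bad, collapse = ", "),
         "; available: ", paste(fit$cells, collapse = ", "), call. = FALSE)
  }
  la <- drop(fit$draws[, paste0("cell:", names(a)), drop = FALSE] %*% a)
  lb <- drop(fit$draws[, paste0("cell:", names(b)), drop = FALSE] %*% b)
  family <- fit$spec$family
  if (scale == "auto") {
    scale <- switch(family,
                    gaussian_identity = "ms",
                    shifted_lognormal_identity = "percent_change",
                    gamma_log = "percent_change",
                    bernoulli_logit = "log_odds")
  }
  if (family == "shifted_lognormal_identity" &&
      scale %in% c("ms", "ratio", "percent_change", "response")) {
    ## contrasts on the response scale: weighted combinations of the implied
    ## cell-mean RTs (shift included), so percent changes refer to mean RT
    s2 <- fit$draws[, "sigma"]^2
    ea <- drop((fit$spec$shift +
                  exp(fit$draws[, paste0("cell:", names(a)), drop = FALSE] +
                        s2 / 2)) %*% a)
    eb <- drop((fit$spec$shift +
                  exp(fit$draws[, paste0("cell:", names(b)), drop = FALSE] +
                        s2 / 2)) %*% b)
    d <- switch(scale, ms = , response = ea - eb, ratio = ea / eb,
                percent_change = 100 * (ea / eb - 1))
    return(posterior_draws(d, if (scale == "response") "ms" else scale,
                           reference = median(eb)))
  }
  d <- la - lb
  out <- switch(scale,
    link = posterior_draws(d, "link"),
    log_odds = posterior_draws(d, "log_odds"),
    ms = , response = posterior_draws(d, "ms", reference = median(lb)),
    ratio = posterior_draws(exp(d), "ratio"),
    percent_change = posterior_draws(100 * (exp(d) - 1), "percent_change"),
    stop("contrast: unknown scale '", scale, "'", call. = FALSE))
  out
}

default_rope <- function(x) {
  switch(x$scale_tag,
    percent_change = c(-5, 5),
    ratio = c(0.95, 1.05),
    log_odds = c(-0.05, 0.05),
    ms = , response = {
      if (!is.finite(x$reference)) {
        stop("summarize_contrast: identity-link ROPE needs a reference ",
             "response level; supply rope= explicitly", call. = FALSE)
      }
      c(-1, 1) * 0.05 * abs(x$reference)
    },
    stop("summarize_contrast: no default ROPE for scale '", x$scale_tag,
         "'; supply rope=", call. = FALSE))
}

#' Summarise a posterior contrast with pd, HDI and the ROPE decision
#'
#' Reports the posterior median, the 89% highest-density interval (shortest
#' interval containing 89% of the draws), the probability of direction (pd,
#' % of draws on the median's side of the null), the percentage of the
#' HDI's draws falling inside the region of practical equivalence, and the
#' HDI+ROPE decision: the null is accepted when the HDI lies completely
#' inside the ROPE, rejected when completely outside, and no decision is
#' reached otherwise.
#'
#' Default ROPEs: +/-5 percentage points on the percent-change scale
#' (equivalently ratio 0.95-1.05), +/-0.05 on the log-odds scale, and for
#' identity-link (ms) contrasts +/-5% of the reference-condition posterior
#' median response.
#'
#' @param x a [posterior_draws()] object (or numeric vector, taken as a
#'   difference scale with null 0).
#' @param rope length-2 numeric ROPE; `NULL` for the scale's default.
#' @param credible HDI mass (default 0.89).
#' @return one-row tibble with `median`, `hdi89_low`, `hdi89_high`, `pd`,
#'   `pct_hdi_in_rope`, `rope_low`, `rope_high`, `decision`, `scale_tag`,
#'   `n_draws`.
#' @export
summarize_contrast <- function(x, rope = NULL, credible = 0.89) {
  if (is.numeric(x)) x <- posterior_draws(x, "ms", null_value = 0, reference = NA)
  stopifnot(inherits(x, "selstop_draws"))
  rope <- rope %||% default_rope(x)
  stopifnot(length(rope) == 2, rope[1] <= rope[2])
  d <- x$draws
  h <- hdi(d, credible)
  med <- median(d)
  in_hdi <- d >= h[1] & d <= h[2]
  pct_in_rope <- 100 * mean(d[in_hdi] >= rope[1] & d[in_hdi] <= rope[2])
  decision <- if (h[1] >= rope[1] && h[2] <= rope[2]) "accept_null"
    else if (h[2] < rope[1] || h[1] > rope[2]) "reject_null"
    else "undecided"
  tibble(median = med, hdi89_low = unname(h[1]), hdi89_high = unname(h[2]),
         pd = prob_direction(d, x$null_value),
         pct_hdi_in_rope = pct_in_rope,
         rope_low = rope[1], rope_high = rope[2],
         decision = decision, scale_tag = x$scale_tag,
         n_draws = x$n_draws)
}

#' Format a contrast summary the way results are reported
#'
#' @param s one-row tibble from [summarize_contrast()].
#' @param label contrast name.
#' @return a string `label: median [89% HDI], pd, % of HDI in ROPE, decision`.
#' @export
format_contrast <- function(s, label = "contrast") {
  sprintf("%s: %.3g [%.3g - %.3g], pd = %.1f%%, %.1f%% in ROPE, %s",
          label, s$median, s$hdi89_low, s$hdi89_high, s$pd,
          s$pct_hdi_in_rope, s$decision)
}

#' Does corticospinal excitability predict stopping success?
#'
#' Bayesian logistic regression of stopping success on CSE measured in the
#' "maybe stopping" (cued) hand on proactive stop trials, separately for the
#' IS and IS150 stimulation timepoints. Only unconditioned (CSE) records not
#' excluded by the EMG rule enter; trials ending in a successful stop code
#' as 1 and failed stops as 0. The slope (log-odds per mV) is summarised
#' against a +/-0.05 ROPE.
#'
#' @param meps MEP observation table (see [mep_observations()]) including
#'   stop-trial CSE records at IS/IS150.
#' @param timepoints which timepoints to fit (default IS and IS150).
#' @param chains,warmup,draws MCMC layout (smaller default than the main
#'   models: a single-slope logistic mixes quickly).
#' @param rng_seed integer seed.
#' @return tibble, one row per timepoint, with the slope summary columns of
#'   [summarize_contrast()].
#' @export
stopping_success_model <- function(meps, timepoints = c("IS", "IS150"),
                                   chains = 4, warmup = 500, draws = 1000,
                                   rng_seed = 1L) {
  meps <- as_tibble(meps)
  cued <- ifelse(meps$cue == "MSL", "left",
                 ifelse(meps$cue == "MSR", "right", NA))
  d <- meps[meps$condition == "proactive" & meps$trial_type != "go" &
              meps$tms_type == "CSE" &
              meps$tms_timepoint %in% timepoints &
              !is.na(cued) & meps$measured_hand == cued &
              !meps$excluded &
              meps$outcome %in% c("stop_success", "stop_fail"), , drop = FALSE]
  if (nrow(d) == 0) {
    stop("stopping_success_model: no eligible maybe-stopping CSE records",
         call. = FALSE)
  }
  d$success <- as.numeric(d$outcome == "stop_success")
  out <- lapply(timepoints, function(tp) {
    dt <- d[d$tms_timepoint == tp, , drop = FALSE]
    if (length(unique(dt$success)) < 2) {
      warning("stopping_success_model: all-", unique(dt$success),
              " outcomes at ", tp, " (complete separation)", call. = FALSE)
    }
    spec <- model_spec("bernoulli_logit", "success", covariates = "amplitude",
                       chains = chains, warmup = warmup, draws = draws)
    fit <- fit_model(spec, dt, rng_seed = rng_seed)
    slope <- posterior_draws(fit$draws[, "slope:amplitude"], "log_odds")
    cbind(tibble(tms_timepoint = tp, n_trials = nrow(dt)),
          summarize_contrast(slope, rope = c(-0.05, 0.05)))
  })
  bind_rows(out)
}
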