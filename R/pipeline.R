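## End-to-end orchestration: simulate -> summarize -> ssrt -> meps -> fit ->
## report, with a JSON manifest (config snapshot, seeds, digests, timings,
## convergence flags) so a run can be reproduced byte-for-byte.

#' Pipeline configuration
#'
#' The default is a reduced "smoke" profile (4 subjects, 2 chains, 600 kept
#' draws per chain) that exercises every stage in minutes; scale
#' `n_subjects`, `chains`, `warmup` and `draws` up for production runs.
#'
#' @param n_subjects cohort size.
#' @param cohort a [cohort_config()].
#' @param chains,warmup,draws MCMC layout for the fitting stage.
#' @param ... named overrides.
#' @return list of class `selstop_pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 4, cohort = cohort_config(),
                            chains = 2, warmup = 400, draws = 600, ...) {
  cfg <- list(n_subjects = as.integer(n_subjects), cohort = cohort,
              chains = as.integer(chains), warmup = as.integer(warmup),
              draws = as.integer(draws))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("pipeline_config: unknown elements ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- "selstop_pipeline_config"
  cfg
}

read_stage_csv <- function(out_dir, name) {
  path <- file.path(out_dir, name)
  if (!file.exists(path)) {
    stop("stage input missing: ", path, " (run the earlier stages first)",
         call. = FALSE)
  }
  as_tibble(read.csv(path))
}

#' Fit the stopping-interference RT model
#'
#' Shifted-lognormal mixed model of correct RTs (go trials: mean of the two
#' synchronous presses; successful stop trials: the continuing hand,
#' relative to the imperative signal) with CONDITION x TRIAL TYPE cell
#' means and by-participant intercepts.
#'
#' @param trials executed-trial table.
#' @param chains,warmup,draws MCMC layout.
#' @param shift nondecision shift (ms) of the RT model.
#' @param rng_seed integer seed.
#' @return a `selstop_fit` with cells `<condition>:<go|stop_continuing>`.
#' @export
fit_interference_model <- function(trials, chains = 2, warmup = 400,
                                   draws = 600, shift = 150, rng_seed = 1L) {
  d <- filter_correct_rt(trials)
  d <- d[d$phase == "main", , drop = FALSE]
  d$role <- ifelse(d$trial_type == "go", "go", "stop_continuing")
  spec <- model_spec("shifted_lognormal_identity", "rt",
                     fixed = c("condition", "role"), shift = shift,
                     chains = chains, warmup = warmup, draws = draws)
  fit_model(spec, d, rng_seed = rng_seed)
}

#' Stop-versus-go percent-change contrast (stopping interference)
#'
#' @param fit from [fit_interference_model()].
#' @return [posterior_draws()] of the percent elongation of continuing-hand
#'   stop RT over go RT, averaged over conditions.
#' @export
interference_contrast <- function(fit) {
  conds <- unique(sub(":.*", "", fit$cells))
  contrast(fit,
           a = paste0(conds, ":stop_continuing"),
           b = paste0(conds, ":go"),
           scale = "percent_change")
}

#' Fit the Gamma log-link model of interhemispheric inhibition
#'
#' MEP amplitudes of one pathway class (LIHI or SIHI) together with the
#' unconditioned CSE records, over either the movement execution and
#' cancellation pool (IS, IS150, SS150 continuing/stopping; correct
#' responses only, i.e. correct go trials and successful stops) or the
#' movement preparation pool (WS, IS by cue status). Cell means are HAND
#' status x TMS class, with by-participant intercepts; back-transformed
#' conditioned/unconditioned contrasts are IHI ratios.
#'
#' @param meps MEP observation table ([mep_observations()]).
#' @param pathway `"LIHI"` or `"SIHI"`.
#' @param pool `"execution"` or `"preparation"`.
#' @param chains,warmup,draws MCMC layout.
#' @param rng_seed integer seed.
#' @return a `selstop_fit` with cells `<status>:<conditioned|unconditioned>`.
#' @export
fit_ihi_model <- function(meps, pathway = c("LIHI", "SIHI"),
                          pool = c("execution", "preparation"),
                          chains = 2, warmup = 400, draws = 600,
                          rng_seed = 1L) {
  pathway <- match.arg(pathway)
  pool <- match.arg(pool)
  meps <- as_tibble(meps)
  keep_class <- meps$tms_type == "CSE" |
    substr(meps$tms_type, 1, 4) == pathway
  d <- meps[keep_class & !meps$excluded, , drop = FALSE]
  ## stop-trial CSE records at IS/IS150 exist only for the stopping-success
  ## logistic analysis and never enter the IHI models
  if (pool == "execution") {
    keep <- (d$trial_type == "go" & d$tms_timepoint %in% c("IS", "IS150") &
               d$outcome == "go_correct") |
      (d$trial_type != "go" & d$tms_timepoint == "SS150" &
         d$outcome == "stop_success")
    d <- d[keep, , drop = FALSE]
    d$status <- ifelse(startsWith(d$hand_status, "IS_"), "IS", d$hand_status)
  } else {
    d <- d[d$trial_type == "go" & d$tms_timepoint %in% c("WS", "IS"), ,
           drop = FALSE]
    d$status <- d$hand_status
  }
  d$tms_class <- ifelse(d$conditioned, "conditioned", "unconditioned")
  spec <- model_spec("gamma_log", "amplitude",
                     fixed = c("status", "tms_class"),
                     chains = chains, warmup = warmup, draws = draws)
  fit_model(spec, d, rng_seed = rng_seed)
}

#' IHI ratio and ratio-change contrasts from a fitted Gamma model
#'
#' `ihi_ratio_at(fit, status)` returns the conditioned/unconditioned ratio
#' at one HAND status; `ihi_ratio_change(fit, status_a, status_b)` the
#' ratio-of-ratios between two statuses (as a percent change when
#' `scale = "percent_change"`), e.g. the release of inhibition at SS150 in
#' the continuing hand relative to IS.
#'
#' @param fit from [fit_ihi_model()].
#' @param status,status_a,status_b HAND-status levels present in the fit.
#' @param scale reporting scale.
#' @return [posterior_draws()].
#' @export
ihi_ratio_at <- function(fit, status, scale = "ratio") {
  contrast(fit, a = paste0(status, ":conditioned"),
           b = paste0(status, ":unconditioned"), scale = scale)
}

#' @rdname ihi_ratio_at
#' @export
ihi_ratio_change <- function(fit, status_a, status_b,
                             scale = "percent_change") {
  contrast(fit,
           a = setNames(c(1, 1), paste0(c(status_a, status_b),
                                        c(":conditioned", ":unconditioned"))),
           b = setNames(c(1, 1), paste0(c(status_b, status_a),
                                        c(":conditioned", ":unconditioned"))),
           scale = scale)
}

stage_runner <- function(manifest, name, f) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(f(), error = function(e) e)
  manifest$timing[[name]] <- round(proc.time()[["elapsed"]] - t0, 2)
  if (inherits(res, "error")) {
    manifest$failed <- name
    manifest$error <- conditionMessage(res)
  }
  list(manifest = manifest, value = res)
}

#' Run the full analysis pipeline
#'
#' simulate -> summarize -> ssrt -> meps -> fit -> report. Produces
#' `trials.csv`, `meps.csv`, `sst_summary.json`, `ssrt_estimates.csv`,
#' `mep_observations.csv`, `contrast_summaries.csv`, `report.md` and
#' `manifest.json` in `out_dir`. Any stage failure halts the run, retains
#' the partial outputs and records a `failed` marker (with the stage name)
#' in the manifest.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param master_seed integer; fans out to simulation and sampler seeds.
#' @return the manifest (invisibly a list, also written as JSON).
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(), master_seed = 1L) {
  stopifnot(inherits(config, "selstop_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(master_seed, 4L)
  manifest <- list(package_version = as.character(utils::packageVersion("selstop")),
                   master_seed = as.integer(master_seed),
                   config = list(n_subjects = config$n_subjects,
                                 chains = config$chains,
                                 warmup = config$warmup, draws = config$draws,
                                 go_shift = config$cohort$go_shift),
                   timing = list(), convergence = list(), failed = NULL)
  finish <- function(manifest) {
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[!basename(files) %in% "manifest.json"]
    manifest$digests <- as.list(tools::md5sum(files))
    names(manifest$digests) <- basename(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    invisible(manifest)
  }

  ## simulate
  st <- stage_runner(manifest, "simulate", function() {
    cohort <- simulate_cohort(config$n_subjects, config$cohort, seeds[1])
    write.csv(cohort$trials, file.path(out_dir, "trials.csv"), row.names = FALSE)
    write.csv(cohort$meps, file.path(out_dir, "meps.csv"), row.names = FALSE)
    cohort
  })
  manifest <- st$manifest
  if (!is.null(manifest$failed)) return(finish(manifest))
  trials <- st$value$trials

  ## summarize
  st <- stage_runner(manifest, "summarize", function() {
    sst <- summarize_sst(trials)
    jsonlite::write_json(sst, file.path(out_dir, "sst_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    sst
  })
  manifest <- st$manifest
  if (!is.null(manifest$failed)) return(finish(manifest))

  ## ssrt
  st <- stage_runner(manifest, "ssrt", function() {
    est <- estimate_ssrt_all(trials)
    write.csv(est, file.path(out_dir, "ssrt_estimates.csv"), row.names = FALSE)
    est
  })
  manifest <- st$manifest
  if (!is.null(manifest$failed)) return(finish(manifest))

  ## meps
  st <- stage_runner(manifest, "meps", function() {
    obs <- mep_observations(read_stage_csv(out_dir, "meps.csv"))
    write.csv(obs, file.path(out_dir, "mep_observations.csv"), row.names = FALSE)
    jsonlite::write_json(exclusion_report(obs),
                         file.path(out_dir, "exclusion_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    obs
  })
  manifest <- st$manifest
  if (!is.null(manifest$failed)) return(finish(manifest))
  obs <- st$value

  ## fit
  st <- stage_runner(manifest, "fit", function() {
    shift <- config$cohort$go_shift
    fit_rt <- fit_interference_model(trials, chains = config$chains,
                                     warmup = config$warmup,
                                     draws = config$draws, shift = shift,
                                     rng_seed = seeds[2])
    fit_lihi <- fit_ihi_model(obs, "LIHI", "execution",
                              chains = config$chains, warmup = config$warmup,
                              draws = config$draws, rng_seed = seeds[3])
    rows <- bind_rows(
      cbind(tibble(effect = "stopping_interference_pct"),
            summarize_contrast(interference_contrast(fit_rt))),
      cbind(tibble(effect = "lihi_ss150_continuing_vs_is_pct"),
            summarize_contrast(ihi_ratio_change(fit_lihi, "SS150_continuing", "IS"))),
      cbind(tibble(effect = "lihi_ratio_at_is"),
            summarize_contrast(ihi_ratio_at(fit_lihi, "IS")))
    )
    succ <- withCallingHandlers(
      stopping_success_model(obs, chains = config$chains,
                             warmup = config$warmup, draws = config$draws,
                             rng_seed = seeds[4]),
      warning = function(w) {
        message("fit stage notice: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    succ$effect <- paste0("stopping_success_slope_", succ$tms_timepoint)
    rows <- bind_rows(rows, succ[, c("effect", names(rows)[-1])])
    write.csv(rows, file.path(out_dir, "contrast_summaries.csv"),
              row.names = FALSE)
    list(rows = rows,
         rhat = c(rt = max(fit_rt$rhat, na.rm = TRUE),
                  lihi = max(fit_lihi$rhat, na.rm = TRUE)))
  })
  manifest <- st$manifest
  if (!is.null(manifest$failed)) return(finish(manifest))
  manifest$convergence <- as.list(st$value$rhat)
  fit_rows <- st$value$rows

  ## report
  st <- stage_runner(manifest, "report", function() {
    rows <- fit_rows
    sst <- read_stage_csv(out_dir, "ssrt_estimates.csv")
    lines <- c(
      "# Response-selective stopping pipeline report", "",
      sprintf("Subjects: %d; master seed: %d", config$n_subjects,
              as.integer(master_seed)), "",
      "## Posterior contrasts (median [89% HDI], pd, % of HDI in ROPE)", "")
    for (i in seq_len(nrow(rows))) {
      lines <- c(lines, paste0("- ", format_contrast(rows[i, ], rows$effect[i])))
    }
    lines <- c(lines, "",
               sprintf("SSRT estimates: %d cells, %d valid, mean %.0f ms",
                       nrow(sst), sum(sst$valid),
                       mean(sst$ssrt, na.rm = TRUE)))
    writeLines(lines, file.path(out_dir, "report.md"))
    TRUE
  })
  manifest <- st$manifest
  finish(manifest)
}
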