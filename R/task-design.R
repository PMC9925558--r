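## Trial-schedule construction for the multicomponent stop-signal task:
## go-only warm-up, reactive (uninformative fixation cue) and proactive
## ("Maybe Stop Left/Right" cue) phases, with pseudorandomized allocation of
## dual-coil TMS measurements over trials.

TMS_TYPES <- c("CSE", "SIHI_LR", "LIHI_LR", "SIHI_RL", "LIHI_RL")
TMS_TIMEPOINTS <- c("WS", "IS", "IS150", "SS150")
HAND_STATUSES <- c("WS_baseline", "IS_unknown", "IS_maybe_stopping",
                   "IS_definitely_going", "IS150", "SS150_continuing",
                   "SS150_stopping")

#' Task design configuration
#'
#' Encodes the block structure of the task: a go-only familiarisation block,
#' a reactive practice block plus reactive main blocks, and a proactive
#' practice block plus proactive main blocks. Defaults reproduce the standard
#' session: 30 go-only trials; reactive practice of 30 trials (20 go, 5 left
#' stop, 5 right stop) then 5 main blocks of 60 trials (40 go, 10 left stop,
#' 10 right stop, i.e. 200/50/50 in total); proactive practice of 30 trials
#' (per cue 10 go, 5 stop) then 10 main blocks of 54 trials (per cue 18 go,
#' 9 stop, i.e. 270 trials per cue of which 180 go and 90 stop). Go and stop
#' trials are in a 2:1 ratio throughout the main blocks.
#'
#' @param reactive_first logical; run the reactive phase before the proactive
#'   one (condition order is counterbalanced across participants by the
#'   caller; this flag sets the order for a single schedule).
#' @param go_only_trials number of trials in the go-only block.
#' @param reactive_practice named counts `c(go=, left_stop=, right_stop=)`.
#' @param reactive_main_blocks number of reactive main blocks.
#' @param reactive_block per-block composition `c(go=, left_stop=, right_stop=)`.
#' @param proactive_practice_per_cue per-cue practice counts `c(go=, stop=)`.
#' @param proactive_main_blocks number of proactive main blocks.
#' @param proactive_block_per_cue per-block per-cue composition `c(go=, stop=)`.
#' @param tms_allocation allocation table as returned by [tms_allocation()].
#' @return a list of class `selstop_design`.
#' @export
design_config <- function(reactive_first = TRUE,
                          go_only_trials = 30,
                          reactive_practice = c(go = 20, left_stop = 5, right_stop = 5),
                          reactive_main_blocks = 5,
                          reactive_block = c(go = 40, left_stop = 10, right_stop = 10),
                          proactive_practice_per_cue = c(go = 10, stop = 5),
                          proactive_main_blocks = 10,
                          proactive_block_per_cue = c(go = 18, stop = 9),
                          tms_allocation = NULL) {
  cfg <- list(
    reactive_first = isTRUE(reactive_first),
    go_only_trials = as.integer(go_only_trials),
    reactive_practice = reactive_practice,
    reactive_main_blocks = as.integer(reactive_main_blocks),
    reactive_block = reactive_block,
    proactive_practice_per_cue = proactive_practice_per_cue,
    proactive_main_blocks = as.integer(proactive_main_blocks),
    proactive_block_per_cue = proactive_block_per_cue,
    tms_allocation = tms_allocation %||% tms_allocation_default()
  )
  counts <- c(cfg$go_only_trials, cfg$reactive_practice, cfg$reactive_block,
              cfg$proactive_practice_per_cue, cfg$proactive_block_per_cue,
              cfg$reactive_main_blocks, cfg$proactive_main_blocks)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("design_config: all trial and block counts must be non-negative integers",
         call. = FALSE)
  }
  for (nm in c("go", "left_stop", "right_stop")) {
    if (is.na(cfg$reactive_block[nm])) {
      stop("design_config: reactive_block must name counts for '", nm, "'",
           call. = FALSE)
    }
  }
  class(cfg) <- "selstop_design"
  cfg
}

#' Default TMS allocation table
#'
#' One row per allocation cell: how many trials of a given class (go/stop,
#' and stop side where relevant) receive a given TMS measure at a given
#' timepoint, per condition and cue. The default reproduces the standard
#' session: in the reactive condition, 10 stimulations per measure (CSE and
#' the four interhemispheric pathways) at each of WS, IS and IS150 on go
#' trials, and 20 per measure at SS150 on stop trials (half on left, half on
#' right stops), i.e. 250 TMS trials; in the proactive condition, per cue,
#' 10 per measure at WS/IS/IS150 on go trials and at SS150 on stop trials,
#' plus 20 CSE trials at each of IS and IS150 on stop trials (for the
#' stopping-success analysis), i.e. 480 TMS trials.
#'
#' @return tibble with columns `condition`, `cue`, `trial_class`,
#'   `stop_side`, `tms_type`, `tms_timepoint`, `n_total`.
#' @export
tms_allocation <- function() tms_allocation_default()

tms_allocation_default <- function() {
  rows <- list()
  go_tp <- c("WS", "IS", "IS150")
  ## reactive: go trials
  rows$rg <- expand.grid(condition = "reactive", cue = "fixation",
                         trial_class = "go", stop_side = NA_character_,
                         tms_type = TMS_TYPES, tms_timepoint = go_tp,
                         n_total = 10, stringsAsFactors = FALSE)
  ## reactive: stop trials at SS150, half each side
  rows$rs <- expand.grid(condition = "reactive", cue = "fixation",
                         trial_class = "stop", stop_side = c("left", "right"),
                         tms_type = TMS_TYPES, tms_timepoint = "SS150",
                         n_total = 10, stringsAsFactors = FALSE)
  ## proactive, per cue
  for (cue in c("MSL", "MSR")) {
    rows[[paste0("pg_", cue)]] <- expand.grid(
      condition = "proactive", cue = cue, trial_class = "go",
      stop_side = NA_character_, tms_type = TMS_TYPES,
      tms_timepoint = go_tp, n_total = 10, stringsAsFactors = FALSE)
    rows[[paste0("ps_", cue)]] <- expand.grid(
      condition = "proactive", cue = cue, trial_class = "stop",
      stop_side = NA_character_, tms_type = TMS_TYPES,
      tms_timepoint = "SS150", n_total = 10, stringsAsFactors = FALSE)
    rows[[paste0("pc_", cue)]] <- expand.grid(
      condition = "proactive", cue = cue, trial_class = "stop",
      stop_side = NA_character_, tms_type = "CSE",
      tms_timepoint = c("IS", "IS150"), n_total = 20, stringsAsFactors = FALSE)
  }
  as_tibble(do.call(rbind, rows))
}

new_trialspec <- function(participant_id, phase, condition, cue, trial_type,
                          block_index) {
  n <- length(trial_type)
  tibble(
    participant_id = rep_len(participant_id, n),
    phase = rep_len(phase, n),
    condition = rep_len(condition, n),
    cue = rep_len(cue, n),
    trial_type = trial_type,
    block_index = rep_len(as.integer(block_index), n),
    trial_index_in_block = seq_len(n) - 1L,
    tms_type = rep_len("none", n),
    tms_timepoint = rep_len("none", n)
  )
}

shuffle_block <- function(block) {
  block <- block[sample.int(nrow(block)), , drop = FALSE]
  block$trial_index_in_block <- seq_len(nrow(block)) - 1L
  block
}

#' Build the full trial schedule for one participant
#'
#' Deterministically constructs the ordered trial list: go-only block, then
#' (by default) reactive practice + main blocks followed by proactive
#' practice + main blocks, with trial order shuffled within each block by the
#' seed. The same seed and configuration always yield the identical schedule.
#'
#' @param participant_id identifier stored on every row.
#' @param config a [design_config()].
#' @param rng_seed integer seed controlling within-block shuffles.
#' @return tibble of trial specifications, one row per planned trial, with
#'   columns `participant_id`, `phase` (go_only/practice/main), `condition`,
#'   `cue`, `trial_type`, `block_index`, `trial_index_in_block`, `tms_type`,
#'   `tms_timepoint` (the TMS columns are "none" until [assign_tms()]).
#' @export
build_schedule <- function(participant_id, config = design_config(), rng_seed = 1L) {
  stopifnot(inherits(config, "selstop_design"))
  withr::with_seed(as.integer(rng_seed), {
    blocks <- list()
    bi <- 0L
    if (config$go_only_trials > 0) {
      blocks[[length(blocks) + 1L]] <- new_trialspec(
        participant_id, "go_only", "reactive", "fixation",
        rep("go", config$go_only_trials), bi)
      bi <- bi + 1L
    }
    make_reactive <- function(bi) {
      out <- list()
      rp <- config$reactive_practice
      if (sum(rp) > 0) {
        out[[1L]] <- shuffle_block(new_trialspec(
          participant_id, "practice", "reactive", "fixation",
          rep(c("go", "left_stop", "right_stop"), rp[c("go", "left_stop", "right_stop")]),
          bi))
        bi <- bi + 1L
      }
      rb <- config$reactive_block
      for (b in seq_len(config$reactive_main_blocks)) {
        out[[length(out) + 1L]] <- shuffle_block(new_trialspec(
          participant_id, "main", "reactive", "fixation",
          rep(c("go", "left_stop", "right_stop"), rb[c("go", "left_stop", "right_stop")]),
          bi))
        bi <- bi + 1L
      }
      list(blocks = out, bi = bi)
    }
    make_proactive <- function(bi) {
      out <- list()
      pp <- config$proactive_practice_per_cue
      if (sum(pp) > 0) {
        half <- function(cue, stop_type) {
          new_trialspec(participant_id, "practice", "proactive", cue,
                        rep(c("go", stop_type), pp[c("go", "stop")]), bi)
        }
        blk <- bind_rows(half("MSL", "left_stop"), half("MSR", "right_stop"))
        out[[1L]] <- shuffle_block(blk)
        bi <- bi + 1L
      }
      pb <- config$proactive_block_per_cue
      for (b in seq_len(config$proactive_main_blocks)) {
        half <- function(cue, stop_type) {
          new_trialspec(participant_id, "main", "proactive", cue,
                        rep(c("go", stop_type), pb[c("go", "stop")]), bi)
        }
        blk <- bind_rows(half("MSL", "left_stop"), half("MSR", "right_stop"))
        out[[length(out) + 1L]] <- shuffle_block(blk)
        bi <- bi + 1L
      }
      list(blocks = out, bi = bi)
    }
    phases <- if (config$reactive_first) list(make_reactive, make_proactive) else
      list(make_proactive, make_reactive)
    for (f in phases) {
      res <- f(bi)
      blocks <- c(blocks, res$blocks)
      bi <- res$bi
    }
    bind_rows(blocks)
  })
}

#' Per-cell trial counts of a schedule
#'
#' @param schedule tibble from [build_schedule()].
#' @return tibble with one row per (phase, condition, cue) and counts of go,
#'   left-stop, right-stop and TMS-bearing trials.
#' @export
schedule_counts <- function(schedule) {
  schedule %>%
    group_by(phase, condition, cue) %>%
    summarise(
      n_go = sum(trial_type == "go"),
      n_left_stop = sum(trial_type == "left_stop"),
      n_right_stop = sum(trial_type == "right_stop"),
      n_tms = sum(tms_type != "none"),
      .groups = "drop"
    )
}

#' Allocate TMS measures to trials of a schedule
#'
#' Distributes each allocation cell (measure x timepoint x trial class) of
#' the configuration's TMS table over the main blocks of the matching
#' condition/cue, giving every block an equal share (plus or minus one trial,
#' with any remainder placed in seeded randomly chosen blocks) and picking
#' the receiving trials within each block at random. This realises the
#' "pseudorandom" constraint: cell totals are exact and every block carries
#' an equal share of every measure/timepoint combination.
#'
#' @param schedule tibble from [build_schedule()] (TMS columns all "none").
#' @param config the [design_config()] used to build the schedule.
#' @param rng_seed integer seed for remainder placement and trial choice.
#' @return the schedule with `tms_type`/`tms_timepoint` filled in.
#' @export
assign_tms <- function(schedule, config = design_config(), rng_seed = 1L) {
  stopifnot(inherits(config, "selstop_design"))
  alloc <- config$tms_allocation
  schedule <- as_tibble(schedule)
  withr::with_seed(as.integer(rng_seed), {
    for (r in seq_len(nrow(alloc))) {
      a <- alloc[r, ]
      blocks <- sort(unique(schedule$block_index[
        schedule$phase == "main" & schedule$condition == a$condition]))
      nb <- length(blocks)
      if (nb == 0) {
        stop("assign_tms: no main blocks for condition '", a$condition, "'",
             call. = FALSE)
      }
      share <- rep(a$n_total %/% nb, nb)
      rem <- a$n_total %% nb
      if (rem > 0) {
        extra <- sample.int(nb, rem)
        share[extra] <- share[extra] + 1L
      }
      for (j in seq_len(nb)) {
        if (share[j] == 0) next
        eligible <- schedule$block_index == blocks[j] &
          schedule$cue == a$cue &
          schedule$tms_type == "none" &
          (if (a$trial_class == "go") schedule$trial_type == "go"
           else schedule$trial_type != "go")
        if (!is.na(a$stop_side)) {
          eligible <- eligible &
            schedule$trial_type == paste0(a$stop_side, "_stop")
        }
        idx <- which(eligible)
        if (length(idx) < share[j]) {
          stop("assign_tms: block ", blocks[j], " has only ", length(idx),
               " free ", a$trial_class, " trials for cell ", a$tms_type, "/",
               a$tms_timepoint, " (need ", share[j], ")", call. = FALSE)
        }
        pick <- if (length(idx) == 1) idx else sample(idx, share[j])
        schedule$tms_type[pick] <- a$tms_type
        schedule$tms_timepoint[pick] <- a$tms_timepoint
      }
    }
  })
  schedule
}

#' Pre-experiment TMS calibration sequence
#'
#' The block of 50 stimulations delivered at rest before the task (10 each of
#' CSE and the four interhemispheric measures) to verify that stimulation
#' parameters capture CSE, SIHI and LIHI. These are not task trials and are
#' excluded from all session TMS-trial counts.
#'
#' @param participant_id identifier.
#' @param rng_seed seed for the stimulation order.
#' @return tibble shaped like a schedule, `phase = "practice"`.
#' @export
build_calibration_tms <- function(participant_id, rng_seed = 1L) {
  withr::with_seed(as.integer(rng_seed), {
    spec <- new_trialspec(participant_id, "practice", "reactive", "fixation",
                          rep("go", 50), 0L)
    spec$tms_type <- sample(rep(TMS_TYPES, each = 10))
    spec$tms_timepoint <- "WS"
    spec
  })
}

#' Check schedule invariants
#'
#' Validates the structural invariants of a trial specification table:
#' go-only trials are plain go trials without TMS; reactive trials carry the
#' fixation cue and proactive trials an informative cue; informative cues
#' only precede stop trials of the cued hand; TMS at SS150 only occurs on
#' stop trials; and TMS type and timepoint are jointly present or absent.
#'
#' @param schedule tibble of trial specifications.
#' @return invisibly `TRUE`; otherwise an error naming the violated rule.
#' @export
validate_schedule <- function(schedule) {
  with(schedule, {
    if (any(phase == "go_only" & (trial_type != "go" | tms_type != "none")))
      stop("go_only trials must be plain go trials without TMS", call. = FALSE)
    if (any(condition == "reactive" & cue != "fixation"))
      stop("reactive trials must carry the fixation cue", call. = FALSE)
    if (any(condition == "proactive" & !cue %in% c("MSL", "MSR")))
      stop("proactive trials must carry an informative cue", call. = FALSE)
    if (any(cue == "MSL" & !trial_type %in% c("go", "left_stop")))
      stop("MSL cue is only valid on go and left-stop trials", call. = FALSE)
    if (any(cue == "MSR" & !trial_type %in% c("go", "right_stop")))
      stop("MSR cue is only valid on go and right-stop trials", call. = FALSE)
    if (any(tms_timepoint == "SS150" & trial_type == "go"))
      stop("SS150 TMS cannot occur on go trials", call. = FALSE)
    if (any((tms_type == "none") != (tms_timepoint == "none")))
      stop("tms_type and tms_timepoint must be jointly 'none'", call. = FALSE)
  })
  invisible(TRUE)
}
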