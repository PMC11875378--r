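#' Experiment specification
#'
#' Describes one block of simulated trials for a task protocol. Condition
#' fractions are realized exactly through shuffled assignment (no per-trial
#' coin flips), so the scheduled counts never drift.
#'
#' @param task `"decision"`, `"stop"`, `"switch"` or `"switch_noreward"`.
#' @param n_trials Number of trials.
#' @param trial_type `"instructed"`, `"choice"`, or `"mixed"` (instructed
#'   and choice trials interleaved in exact proportion
#'   `fraction_instructed`, as in the decision-making task); stop/switch
#'   blocks are usually run separately per type, mirroring the task's
#'   separate one- and two-target blocks.
#' @param fraction_instructed Fraction of instructed trials in `"mixed"`
#'   blocks.
#' @param fraction_regulated Fraction of trials carrying a stop/switch
#'   signal (0.33 in the human protocol; 0 for the decision task).
#' @param mode `"staircase"` (adaptive +/-50 ms delay) or `"fixed_delays"`.
#' @param fixed_delays Vector of SSD/SWSD values (ms) cycled over the
#'   regulated trials in `fixed_delays` mode.
#' @param initial_delay Starting SSD/SWSD for the staircase, ms.
#' @param distance_frac_range For `"switch_noreward"`: range of the random
#'   distance threshold as a fraction of the target distance.
#' @param rewards Reward points for choice targets, high then low. The
#'   internally guided variant uses equal values (free choice, no external
#'   contingency).
#' @param directions Target directions in degrees. Instructed trials use
#'   `directions[1]`; choice trials use both. One-target switches move the
#'   target to `switch_new_direction`.
#' @param switch_new_direction New target direction for one-target switches
#'   (default 60 degrees away from the original, matching the task's
#'   adjacent-target geometry).
#' @param seed Integer seed; per-trial substreams are derived from
#'   `(seed, trial index)`.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(task = c("decision", "stop", "switch", "switch_noreward"),
                            n_trials,
                            trial_type = c("instructed", "choice", "mixed"),
                            fraction_instructed = 0.5,
                            fraction_regulated = if (task == "decision") 0 else 0.33,
                            mode = c("staircase", "fixed_delays"),
                            fixed_delays = c(200, 350, 500, 650, 800),
                            initial_delay = 250,
                            distance_frac_range = c(0.012, 0.032),
                            rewards = if (task == "switch_noreward") c(8, 8)
                                      else c(10, 5),
                            directions = c(120, 60),
                            switch_new_direction = 60,
                            seed = 1L) {
  task <- match.arg(task)
  mode <- match.arg(mode)
  trial_type <- match.arg(trial_type)
  if (fraction_regulated < 0 || fraction_regulated > 1) {
    stop("fraction_regulated must lie in [0, 1]")
  }
  if (task == "decision" && fraction_regulated > 0) {
    stop("decision trials carry no regulation signal")
  }
  structure(
    list(task = task, n_trials = as.integer(n_trials), trial_type = trial_type,
         fraction_instructed = fraction_instructed,
         fraction_regulated = fraction_regulated, mode = mode,
         fixed_delays = fixed_delays, initial_delay = initial_delay,
         distance_frac_range = distance_frac_range, rewards = rewards,
         directions = directions, switch_new_direction = switch_new_direction,
         seed = as.integer(seed)),
    class = "experiment_spec"
  )
}

# Derive a per-trial RNG substream seed from (seed, trial index); kept well
# below 2^31.
trial_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 9973) %% 2147483587)
}

#' Schedule the trials of an experiment
#'
#' Draws fore-periods uniformly in 1000--1100 ms, assigns regulated trials
#' by exact count (rounded, with a warning when the fraction is not an
#' integer count) and shuffles the order. In `fixed_delays` mode the delays
#' are balanced across regulated trials (equal counts per delay).
#'
#' @param spec An [experiment_spec()].
#' @return A list of `trial_config` records, each with `task`, `trial_type`,
#'   `targets`, `regulation` (`"none"`, `"stop"` or `"switch"`), `delay`
#'   (ms, `NA` in staircase mode where the staircase supplies it),
#'   `distance_frac`, `fore_period` and `deadline` (1000 ms after onset;
#'   extended at run time by 1000 ms once a switch signal fires).
#' @export
schedule_trials <- function(spec) {
  set.seed(trial_seed(spec$seed, 0L))
  n <- spec$n_trials
  if (n == 0) return(list())
  n_reg <- spec$fraction_regulated * n
  if (abs(n_reg - round(n_reg)) > 1e-9) {
    warning("fraction_regulated * n_trials is not an integer; rounding")
  }
  n_reg <- as.integer(round(n_reg))
  regulated <- c(rep(TRUE, n_reg), rep(FALSE, n - n_reg))[sample.int(n)]
  delays <- rep(NA_real_, n)
  if (spec$mode == "fixed_delays" && n_reg > 0) {
    per <- rep(spec$fixed_delays, length.out = n_reg)
    delays[regulated] <- sample(per)
  }
  fore <- stats::runif(n, 1000, 1100)
  dist_frac <- stats::runif(n, spec$distance_frac_range[1],
                            spec$distance_frac_range[2])
  types <- if (spec$trial_type == "mixed") {
    n_instr <- as.integer(round(spec$fraction_instructed * n))
    c(rep("instructed", n_instr), rep("choice", n - n_instr))[sample.int(n)]
  } else {
    rep(spec$trial_type, n)
  }
  lapply(seq_len(n), function(i) {
    targets <- if (types[i] == "instructed") {
      list(list(direction = spec$directions[1], reward = spec$rewards[1]))
    } else {
      list(list(direction = spec$directions[1], reward = spec$rewards[1]),
           list(direction = spec$directions[2], reward = spec$rewards[2]))
    }
    regulation <- if (!regulated[i]) "none"
      else if (spec$task == "stop") "stop" else "switch"
    structure(
      list(task = spec$task, trial_type = types[i], index = i,
           targets = targets, regulation = regulation,
           delay = delays[i],
           distance_frac = if (spec$task == "switch_noreward") dist_frac[i] else NA,
           fore_period = fore[i], deadline = fore[i] + 1000,
           seed = trial_seed(spec$seed, i),
           switch_new_direction = spec$switch_new_direction),
      class = "trial_config"
    )
  })
}

# Build the event schedule for one trial config (delay injected by the
# caller in staircase mode).
build_schedule <- function(config, delay = config$delay) {
  onset <- config$fore_period
  stop_time <- NA
  switch_time <- NA
  switch_frac <- NA
  new_targets <- NULL
  if (config$regulation == "stop") {
    stop_time <- onset + delay
  } else if (config$regulation == "switch") {
    if (config$task == "switch_noreward") {
      switch_frac <- config$distance_frac
    } else {
      switch_time <- onset + delay
    }
    if (config$trial_type == "instructed") {
      new_targets <- list(list(direction = config$switch_new_direction,
                               reward = config$targets[[1]]$reward))
    } else if (config$task == "switch") {
      # reward-based: the high-reward target disappears
      rw <- vapply(config$targets, function(tg) tg$reward, numeric(1))
      new_targets <- config$targets[-which.max(rw)]
    } # switch_noreward choice: decided at signal time (closer target removed)
  }
  event_schedule(
    target_onset = onset, targets = config$targets,
    stop_time = stop_time, switch_time = switch_time,
    switch_distance_frac = switch_frac, new_targets = new_targets,
    deadline = config$deadline, task = config$task,
    trial_type = config$trial_type
  )
}

#' Stop-trial success
#'
#' A stop trial is successful iff the cursor never enters the target disc
#' before the deadline and its speed falls below the stop-speed criterion
#' (10% of the nominal peak speed) and stays there for at least 100 ms
#' before the deadline.
#'
#' @param trial A [run_model_trial()] result.
#' @param spec The [model_spec()] (for the speed criterion).
#' @return Logical.
#' @export
evaluate_stop_success <- function(trial, spec) {
  if (trial$reached) return(FALSE)
  tr <- trial$trajectory
  n <- nrow(tr)
  if (n < 2) return(TRUE)
  v <- sqrt(diff(tr$x_cm)^2 + diff(tr$y_cm)^2) / diff(tr$t_ms) * 1000
  crit <- spec$heading_speed_frac * spec$nominal_peak_speed
  below <- v < crit
  # longest run of consecutive below-criterion samples ending by the deadline
  run <- 0
  need <- ceiling(100 / spec$dt)
  for (b in below) {
    run <- if (b) run + 1 else 0
    if (run >= need) return(TRUE)
  }
  FALSE
}

#' Switch-trial success
#'
#' Successful iff, after the switch signal, the trajectory never enters the
#' removed (old) target's disc and the cursor enters the new target's disc
#' before the extended deadline.
#'
#' @param trial A [run_model_trial()] result of a switch trial.
#' @return Logical.
#' @export
evaluate_switch_success <- function(trial) {
  if (!trial$switched) return(FALSE)
  if (trial$old_disc_entered) return(FALSE)
  trial$reached
}

#' Staircase state
#'
#' @param value Current delay in ms (>= 0).
#' @param step Step size in ms (the task's 50 ms).
#' @return An object of class `staircase_state` with an empty history.
#' @export
staircase_state <- function(value = 250, step = 50) {
  stopifnot(value >= 0, step > 0)
  structure(list(value = value, step = step,
                 history = data.frame(value = numeric(0), success = logical(0))),
            class = "staircase_state")
}

#' One adaptive staircase update
#'
#' Success raises the delay by one step (the next regulated trial gets
#' harder); failure lowers it by one step, clamped at zero. This 1-up/1-down
#' rule drives the delay toward the value yielding ~50% success.
#'
#' @param state A [staircase_state()].
#' @param success Logical outcome of the regulated trial just adjudicated.
#' @return The updated `staircase_state`, history appended.
#' @export
update_staircase <- function(state, success) {
  state$history <- rbind(state$history,
                         data.frame(value = state$value, success = success))
  state$value <- if (success) state$value + state$step
    else max(0, state$value - state$step)
  state
}

#' Distance-threshold switch signal
#'
#' For internally guided switch trials: the signal fires at the first sample
#' whose cumulative path length from the origin exceeds
#' `threshold_fraction * target_distance`.
#'
#' @param trajectory Data frame with `x_cm`, `y_cm` (samples so far).
#' @param threshold_fraction Fraction of the target distance.
#' @param target_distance Target eccentricity in cm.
#' @return `TRUE` if the threshold has been exceeded.
#' @export
distance_threshold_signal <- function(trajectory, threshold_fraction,
                                      target_distance = 20.37) {
  if (nrow(trajectory) < 2) return(FALSE)
  path <- cumsum(sqrt(diff(trajectory$x_cm)^2 + diff(trajectory$y_cm)^2))
  any(path > threshold_fraction * target_distance)
}

#' Run one trial
#'
#' Builds the event schedule from the trial config (delays anchored at
#' target onset), seeds the trial's RNG substream, iterates the model to the
#' deadline and adjudicates success.
#'
#' @param model_spec A [model_spec()].
#' @param config A `trial_config` from [schedule_trials()].
#' @param delay Delay override (ms) for staircase mode.
#' @param record_fields Passed to [run_model_trial()].
#' @return A list: the [run_model_trial()] output plus `config`, `delay`,
#'   `success` flags (`reached`, `stopped`, `switched_ok`) and `rt`/`srt`
#'   extracted with the kinematic rules of the behavior module.
#' @export
run_trial <- function(model_spec, config, delay = config$delay,
                      record_fields = FALSE) {
  set.seed(config$seed)
  schedule <- build_schedule(config, delay)
  trial <- run_model_trial(model_spec, schedule, record_fields = record_fields)
  trial$config <- config
  trial$delay <- delay
  trial$stopped <- if (config$regulation == "stop") {
    evaluate_stop_success(trial, model_spec)
  } else NA
  trial$switched_ok <- if (config$regulation == "switch") {
    evaluate_switch_success(trial)
  } else NA

  traj <- trial$trajectory
  traj$onset <- schedule$target_onset
  vel <- tryCatch(smooth_and_differentiate(traj), error = function(e) NULL)
  trial$rt <- if (is.null(vel)) NA_real_ else
    compute_rt(vel, schedule$target_onset)
  trial$srt <- NA_real_
  if (config$regulation == "switch" && trial$switched && !is.null(vel)) {
    new_dir <- trial$final_state$targets[[1]]$direction
    trial$srt <- compute_srt(traj, vel, trial$final_state$signal_time, new_dir,
                             target_radius = model_spec$target_radius)
    trial$new_direction <- new_dir
  }
  trial
}

#' Run a full experiment
#'
#' Schedules all trials, runs them in order, threads the staircase through
#' the regulated trials (staircase mode), and returns one tidy row per
#' trial. Repeated runs with the same spec (same seed) are identical.
#'
#' @param spec An [experiment_spec()].
#' @param model_spec A [model_spec()].
#' @param keep_trajectories If `TRUE`, attach the list of per-trial
#'   trajectories as an attribute `"trajectories"`.
#' @return A tibble with one row per trial: `trial`, `task`, `trial_type`,
#'   `regulation`, `delay`, `fore_period`, `chosen_direction`, `reached`,
#'   `stopped`, `switched_ok`, `rt`, `srt`, `threshold_crossing_ms`.
#' @export
run_experiment <- function(spec, model_spec, keep_trajectories = FALSE) {
  configs <- schedule_trials(spec)
  stair <- staircase_state(value = spec$initial_delay)
  rows <- vector("list", length(configs))
  trajs <- if (keep_trajectories) vector("list", length(configs)) else NULL
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    delay <- cfg$delay
    if (cfg$regulation != "none" && spec$mode == "staircase" &&
        spec$task != "switch_noreward") {
      delay <- stair$value
    }
    tr <- run_trial(model_spec, cfg, delay = delay)
    if (cfg$regulation != "none" && spec$mode == "staircase" &&
        spec$task != "switch_noreward") {
      success <- if (cfg$regulation == "stop") tr$stopped else tr$switched_ok
      stair <- update_staircase(stair, isTRUE(success))
    }
    rows[[i]] <- tibble::tibble(
      trial = i, task = cfg$task, trial_type = cfg$trial_type,
      regulation = cfg$regulation, delay = if (is.null(delay)) NA_real_ else as.numeric(delay),
      fore_period = cfg$fore_period,
      chosen_direction = tr$chosen_direction,
      reached = tr$reached,
      stopped = if (is.na(tr$stopped[1])) NA else isTRUE(tr$stopped),
      switched_ok = if (is.na(tr$switched_ok[1])) NA else isTRUE(tr$switched_ok),
      rt = tr$rt, srt = tr$srt,
      threshold_crossing_ms = tr$threshold_crossing_ms,
      max_weight_dev = tr$max_weight_dev
    )
    if (keep_trajectories) trajs[[i]] <- tr$trajectory
  }
  out <- do.call(rbind, rows)
  attr(out, "staircase") <- stair
  if (keep_trajectories) attr(out, "trajectories") <- trajs
  out
}
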