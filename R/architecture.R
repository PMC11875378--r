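#' Model specification: fields, wiring and architecture variant
#'
#' Builds the full model configuration: one lattice and parameter set per
#' field (spatial sensory, expected outcome, reach cost, stop signal, pause,
#' reach planning), the planning field's lateral interaction kernel,
#' projection gains, pause engagement levels, the action initiation
#' threshold, and the cursor plant. The planning field receives excitatory
#' one-to-one input from the sensory and outcome fields and inhibitory input
#' from the cost field (one-to-one) and the pause field (one-to-all); the
#' stop field excites the pause field one-to-all.
#'
#' The three architecture variants differ only in when the pause field is
#' engaged during the switch task:
#' * `ARCH1` — pause engaged proactively during planning and (as a transient
#'   pulse) after the switch signal, in both instructed and choice trials.
#' * `ARCH2` — pause never engaged in the switch task; switching is carried
#'   entirely by the competition within the planning field.
#' * `ARCH3` — no proactive pause; the post-signal pulse fires only in
#'   instructed (one-target) switch trials.
#' In the stop task the pause field is proactively active during planning in
#' every variant and strongly driven (tonic) after the stop signal.
#'
#' All numeric defaults are this package's own calibration (documented in
#' the methods vignette); every one is overridable through `...`.
#'
#' @param variant `"ARCH1"`, `"ARCH2"` or `"ARCH3"`.
#' @param ... Named overrides of any default listed in the Details.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(variant = c("ARCH2", "ARCH1", "ARCH3"), ...) {
  variant <- match.arg(variant)
  defaults <- list(
    dt = 10,                      # ms; integration and control step
    n_dir = 181L,                 # directional lattices: 0..180 deg at 1 deg
    n_stop = 100L,                # unit-indexed stop field
    n_pause = 100L,               # unit-indexed pause field
    # field dynamics
    sensory  = field_params(tau = 80,  resting_level = -2, gain_slope = 1),
    outcome  = field_params(tau = 50,  resting_level = -3, gain_slope = 1),
    cost     = field_params(tau = 50,  resting_level = -2, gain_slope = 1),
    stop     = field_params(tau = 50,  resting_level = -3, gain_slope = 1),
    pause    = field_params(tau = 50,  resting_level = -3, gain_slope = 1),
    planning = field_params(tau = 90,  resting_level = -5, gain_slope = 0.7,
                            noise_sd = 0.08),
    # planning-field lateral kernel: local excitation + global inhibition
    planning_kernel = kernel_spec(
      exc_amplitude = 1.1, exc_width = 5,
      inh_amplitude = 0.42, form = "gaussian_plus_global"
    ),
    # drive shapes
    bump_width = 6,               # deg, Gaussian target bump width
    sensory_amp = 10,             # sensory bump height
    reward_gain = 1.0,            # outcome bump height per reward point
    stop_amp = 10,                # stop-field drive when the stop cue is on
    cost_baseline = 1,            # flat cost drive before movement onset
    cost_amp = 4,                 # cost increase toward directions away from heading
    cost_width = 45,              # deg
    # projection gains
    g_sensory = 6, g_outcome = 1.2, g_cost = 0.6,
    g_pause = 0.15,               # pause -> planning, one-to-all inhibitory
    g_stop_pause = 0.02,          # stop -> pause, one-to-all excitatory
    # pause engagement levels (external drive units on the pause field)
    pause_proactive = 0.7,        # tonic level while planning under stop anticipation
    pause_post_stop = 1.5,        # tonic level after a stop signal
    pause_post_switch = 6.0,      # pulse level after a switch signal
    pause_pulse_ms = 40,          # pulse duration
    # decision and execution
    initiation_threshold = 3.2,   # action initiation threshold on planning u
    plant = plant_params(mass = 1, dt = 10, motor_noise_sd = 20, damping = 8),
    cost_weights = default_cost_weights(),
    nominal_reach_ms = 500,       # nominal movement time spanned by a policy
    target_radius = 20.37,        # cm, target eccentricity
    target_disc_radius = 2.75,    # cm, acquisition disc (half the 5.5 cm cue)
    heading_speed_frac = 0.1,     # of nominal peak speed; defines heading onset
    nominal_peak_speed = 60       # cm/s, nominal peak cursor speed
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown model_spec fields: ",
                            paste(unknown, collapse = ", "))
  defaults[names(overrides)] <- overrides
  spec <- defaults
  spec$variant <- variant
  spec$lattice_dir <- field_lattice(spec$n_dir, 0, 180)
  spec$lattice_stop <- field_lattice(spec$n_stop, metric = FALSE)
  spec$lattice_pause <- field_lattice(spec$n_pause, metric = FALSE)
  spec$W_planning <- build_kernel(spec$planning_kernel, spec$lattice_dir)
  class(spec) <- "model_spec"
  spec
}

#' Encode targets as sensory and outcome drives
#'
#' Each target contributes a Gaussian bump centred on its direction: on the
#' sensory field with fixed height `sensory_amp`, on the outcome field with
#' height `reward_gain * reward` (linear in reward).
#'
#' @param targets List of `list(direction = degrees, reward = points)`
#'   records (empty list for no targets).
#' @param spec A [model_spec()].
#' @return List with `sensory` and `outcome` drive vectors.
#' @export
encode_targets <- function(targets, spec) {
  dirs <- spec$lattice_dir$preferred_values
  sensory <- numeric(spec$n_dir)
  outcome <- numeric(spec$n_dir)
  for (tg in targets) {
    if (tg$direction < 0 || tg$direction > 180) {
      stop("target direction must lie in [0, 180] degrees")
    }
    bump <- exp(-(dirs - tg$direction)^2 / (2 * spec$bump_width^2))
    sensory <- sensory + spec$sensory_amp * bump
    reward <- if (is.null(tg$reward)) 0 else tg$reward
    outcome <- outcome + spec$reward_gain * reward * bump
  }
  list(sensory = sensory, outcome = outcome)
}

#' Reach cost drive given the current movement heading
#'
#' Before movement onset (heading undefined) the cost drive is a flat
#' baseline. Once the cursor is moving, directions far from the current
#' heading are more costly: the drive rises with angular distance from the
#' heading, so the inhibitory cost projection penalizes direction changes.
#' Profiles for different headings are shifted copies of the same function
#' of `|direction - heading|`.
#'
#' @param current_heading Heading in degrees, or `NULL`/`NA` before onset.
#' @param spec A [model_spec()].
#' @return Cost-field drive vector.
#' @export
compute_reach_cost <- function(current_heading, spec) {
  if (is.null(current_heading) || is.na(current_heading)) {
    return(rep(spec$cost_baseline, spec$n_dir))
  }
  d <- abs(spec$lattice_dir$preferred_values - current_heading)
  spec$cost_baseline + spec$cost_amp * (1 - exp(-d^2 / (2 * spec$cost_width^2)))
}

#' Pause-field engagement level
#'
#' Returns the external drive on the pause field for a given architecture,
#' task, trial phase and trial type. The decision task never engages the
#' pause field. The stop task engages it proactively during planning (all
#' variants) and strongly after the stop signal. In the switch task the
#' engagement depends on the architecture (see [model_spec()]).
#'
#' @param variant `"ARCH1"`, `"ARCH2"` or `"ARCH3"`.
#' @param task `"decision"`, `"stop"` or `"switch"` (the internally guided
#'   `"switch_noreward"` behaves as `"switch"`).
#' @param phase `"planning"` (before the regulation signal) or
#'   `"post_signal"`.
#' @param trial_type `"instructed"` or `"choice"`.
#' @param spec A [model_spec()] supplying the numeric levels.
#' @return Scalar drive level.
#' @export
pause_drive <- function(variant, task, phase, trial_type,
                        spec = model_spec(variant)) {
  task <- if (task == "switch_noreward") "switch" else task
  stopifnot(variant %in% c("ARCH1", "ARCH2", "ARCH3"),
            task %in% c("decision", "stop", "switch"),
            phase %in% c("planning", "post_signal"),
            trial_type %in% c("instructed", "choice"))
  if (task == "decision") return(0)
  if (task == "stop") {
    return(if (phase == "planning") spec$pause_proactive else spec$pause_post_stop)
  }
  # switch task
  switch(variant,
    ARCH1 = if (phase == "planning") spec$pause_proactive else spec$pause_post_switch,
    ARCH2 = 0,
    ARCH3 = if (phase == "post_signal" && trial_type == "instructed")
      spec$pause_post_switch else 0
  )
}

#' Initialize the model state for one trial
#'
#' All fields start at their resting level, the cursor at the origin with
#' zero velocity.
#'
#' @param spec A [model_spec()].
#' @param schedule An [event_schedule()].
#' @return An object of class `model_state`.
#' @export
init_model <- function(spec, schedule) {
  rest <- function(p, n) field_state(rep(p$resting_level, n), 0)
  structure(
    list(
      fields = list(
        sensory = rest(spec$sensory, spec$n_dir),
        outcome = rest(spec$outcome, spec$n_dir),
        cost = rest(spec$cost, spec$n_dir),
        stop = rest(spec$stop, spec$n_stop),
        pause = rest(spec$pause, spec$n_pause),
        planning = rest(spec$planning, spec$n_dir)
      ),
      plant = plant_state(),
      targets = list(),            # visible targets (empty before onset)
      targets_on = FALSE,
      policies = list(),           # keyed by neuron index (character)
      policy_birth = integer(0),   # step at which each policy was created
      deadline = schedule$deadline,
      t = 0, step = 0L,
      moving = FALSE, stopped = FALSE, switched = FALSE,
      signal_seen = FALSE,         # stop or switch signal already delivered
      path_length = 0,
      heading = NA_real_,
      chosen_direction = NA_real_,
      threshold_crossing_ms = NA_real_,
      max_weight_dev = 0,          # worst |sum(d_j) - 1| over supra-threshold steps
      reached = FALSE, reached_direction = NA_real_,
      old_disc_entered = FALSE,
      events = list()
    ),
    class = "model_state"
  )
}

#' Event schedule for one trial
#'
#' @param target_onset Target presentation time in ms (end of fore-period).
#' @param targets List of `list(direction, reward)` shown at onset.
#' @param stop_time Stop-signal time in ms, or `NA`.
#' @param switch_time Switch-signal time in ms, or `NA` (mutually exclusive
#'   with `stop_time`).
#' @param switch_distance_frac For internally guided switch trials: the
#'   signal fires when the cursor's path length exceeds this fraction of the
#'   target distance (`NA` for time-based switches).
#' @param new_targets Target list that replaces `targets` at the switch
#'   signal (for two-target switches, the remaining target).
#' @param deadline Trial deadline in ms relative to trial start (extended by
#'   1000 ms when a switch signal fires).
#' @param task,trial_type Task context used for pause engagement.
#' @return An object of class `event_schedule`.
#' @export
event_schedule <- function(target_onset, targets,
                           stop_time = NA, switch_time = NA,
                           switch_distance_frac = NA,
                           new_targets = NULL,
                           deadline = target_onset + 1000,
                           task = "decision", trial_type = "instructed") {
  if (!is.na(stop_time) && (!is.na(switch_time) || !is.na(switch_distance_frac))) {
    stop("stop_time and switch_time are mutually exclusive")
  }
  if (!is.na(stop_time) && stop_time < target_onset) {
    stop("stop_time must be >= target_onset")
  }
  if (!is.na(switch_time) && switch_time < target_onset) {
    stop("switch_time must be >= target_onset")
  }
  structure(
    list(
      target_onset = target_onset, targets = targets,
      stop_time = stop_time, switch_time = switch_time,
      switch_distance_frac = switch_distance_frac,
      new_targets = new_targets, deadline = deadline,
      task = task, trial_type = trial_type
    ),
    class = "event_schedule"
  )
}

#' Deliver the switch signal to a running model
#'
#' Replaces the visible target set with the schedule's post-switch set: in
#' one-target trials the old target's drive is zeroed and the new target's
#' switched on; in two-target trials the removed (high-reward, or
#' closer-to-cursor) target's drive is zeroed while the remaining target's
#' drive is unchanged. The trial deadline is extended by 1000 ms. Pause
#' engagement after the signal is handled by [model_step()] via
#' [pause_drive()].
#'
#' @param model A `model_state` at the switch time.
#' @param schedule The trial's [event_schedule()].
#' @return The updated `model_state`.
#' @export
trigger_switch <- function(model, schedule) {
  if (is.na(schedule$switch_time) && is.na(schedule$switch_distance_frac)) {
    stop("trigger_switch called on a trial with no switch scheduled")
  }
  new_targets <- schedule$new_targets
  if (is.null(new_targets)) {
    # internally guided two-target variant: the target closer to the cursor
    # disappears and the other remains
    d <- vapply(model$targets, function(tg) {
      th <- tg$direction * pi / 180
      goal <- schedule_target_radius(schedule) * c(cos(th), sin(th))
      sqrt(sum((model$plant$position - goal)^2))
    }, numeric(1))
    new_targets <- model$targets[-which.min(d)]
  }
  kept_dirs <- vapply(new_targets, function(tg) tg$direction, numeric(1))
  model$old_targets <- Filter(
    function(tg) !(tg$direction %in% kept_dirs), model$targets
  )
  model$targets <- new_targets
  model$switched <- TRUE
  model$signal_seen <- TRUE
  model$signal_time <- model$t
  model$deadline <- model$deadline + 1000
  model$events$switch_signal <- model$t
  model
}

# target eccentricity used by trigger_switch; carried on the schedule when
# set, otherwise the task default
schedule_target_radius <- function(schedule) {
  if (!is.null(schedule$target_radius)) schedule$target_radius else 20.37
}

#' Advance the whole model by one time step
#'
#' One closed-loop step of length `spec$dt`: update the drive of every field
#' from the schedule and the cursor state, integrate all six fields, convert
#' the planning field's supra-threshold activity into desirability weights,
#' instantiate reach policies for newly active neurons, mix the active
#' policies and advance the cursor. Event flags (`moving`, `stopped`,
#' `switched`, target acquisition) are updated in place. Randomness (field
#' and motor noise) is drawn from R's global RNG; callers seed a per-trial
#' substream before the loop.
#'
#' @param model A `model_state`.
#' @param spec A [model_spec()].
#' @param schedule An [event_schedule()].
#' @return The advanced `model_state`.
#' @export
model_step <- function(model, spec, schedule) {
  dt <- spec$dt
  t_next <- model$t + dt
  task <- if (schedule$task == "switch_noreward") "switch" else schedule$task

  # -- scheduled events ------------------------------------------------------
  if (!model$targets_on && model$t >= schedule$target_onset &&
      length(schedule$targets) > 0) {
    model$targets <- schedule$targets
    model$targets_on <- TRUE
    model$events$target_onset <- schedule$target_onset
  }
  stop_on <- !is.na(schedule$stop_time) && model$t >= schedule$stop_time
  if (stop_on && !model$signal_seen) {
    model$signal_seen <- TRUE
    model$signal_time <- schedule$stop_time
    model$events$stop_signal <- schedule$stop_time
  }
  switch_due <- !model$switched &&
    ((!is.na(schedule$switch_time) && model$t >= schedule$switch_time) ||
     (!is.na(schedule$switch_distance_frac) &&
        model$path_length >
          schedule$switch_distance_frac * schedule_target_radius(schedule)))
  if (switch_due) model <- trigger_switch(model, schedule)

  # -- drives ----------------------------------------------------------------
  enc <- encode_targets(model$targets, spec)
  cost_drive <- compute_reach_cost(model$heading, spec)
  stop_drive <- if (stop_on) spec$stop_amp else 0
  phase <- if (model$signal_seen) "post_signal" else "planning"
  pause_level <- pause_drive(spec$variant, task, phase, schedule$trial_type, spec)
  if (phase == "post_signal" && task == "switch" &&
      model$t >= model$signal_time + spec$pause_pulse_ms) {
    pause_level <- 0  # the switch pulse is transient
  }

  f <- model$fields
  stop_rates <- gain_function(f$stop$u, spec$stop)
  pause_in <- pause_level +
    project(stop_rates, projection_spec("stop", "pause", "one_to_all",
                                        "excitatory", spec$g_stop_pause,
                                        n_target = spec$n_pause))
  pause_rates <- gain_function(f$pause$u, spec$pause)
  planning_in <-
    spec$g_sensory * gain_function(f$sensory$u, spec$sensory) +
    spec$g_outcome * gain_function(f$outcome$u, spec$outcome) -
    spec$g_cost * gain_function(f$cost$u, spec$cost) -
    spec$g_pause * sum(pause_rates)

  # -- integrate fields ------------------------------------------------------
  nd <- spec$n_dir
  f$sensory <- step_field(f$sensory, spec$sensory, NULL, enc$sensory,
                          if (spec$sensory$noise_sd > 0) stats::rnorm(nd) else 0, dt)
  f$outcome <- step_field(f$outcome, spec$outcome, NULL, enc$outcome,
                          if (spec$outcome$noise_sd > 0) stats::rnorm(nd) else 0, dt)
  f$cost <- step_field(f$cost, spec$cost, NULL, cost_drive,
                       if (spec$cost$noise_sd > 0) stats::rnorm(nd) else 0, dt)
  f$stop <- step_field(f$stop, spec$stop, NULL, stop_drive,
                       if (spec$stop$noise_sd > 0) stats::rnorm(spec$n_stop) else 0, dt)
  f$pause <- step_field(f$pause, spec$pause, NULL, pause_in,
                        if (spec$pause$noise_sd > 0) stats::rnorm(spec$n_pause) else 0, dt)
  f$planning <- step_field(f$planning, spec$planning, spec$W_planning,
                           planning_in,
                           if (spec$planning$noise_sd > 0) stats::rnorm(nd) else 0, dt)
  model$fields <- f

  # -- desirability and policies --------------------------------------------
  des <- normalize_desirability(f$planning$u, spec$initiation_threshold)
  model$desirability <- des
  if (des$M > 0) {
    model$max_weight_dev <- max(model$max_weight_dev, abs(sum(des$weights) - 1))
    if (!model$moving) {
      model$moving <- TRUE
      model$threshold_crossing_ms <- t_next - schedule$target_onset
      model$chosen_direction <-
        spec$lattice_dir$preferred_values[which.max(f$planning$u)]
      model$events$threshold_crossing <- model$t
    }
    remaining <- max(1L, as.integer((model$deadline - model$t) / dt))
    horizon <- min(as.integer(spec$nominal_reach_ms / dt), remaining)
    new_idx <- setdiff(des$active_indices, as.integer(names(model$policies)))
    if (length(new_idx) > 0) {
      key <- as.character(horizon)
      if (is.null(model$gain_cache)) model$gain_cache <- list()
      if (is.null(model$gain_cache[[key]])) {
        model$gain_cache[[key]] <-
          lqr_gains(horizon, spec$plant, spec$cost_weights)
      }
      for (i in new_idx) {
        model$policies[[as.character(i)]] <- make_reach_policy(
          spec$lattice_dir$preferred_values[i],
          target_radius = spec$target_radius,
          horizon = horizon, plant = spec$plant,
          gains = model$gain_cache[[key]]
        )
        model$policy_birth[as.character(i)] <- model$step
      }
    }
  }

  # -- mix and step the plant ------------------------------------------------
  if (des$M > 0) {
    keys <- as.character(des$active_indices)
    steps <- model$step - model$policy_birth[keys] + 1L
    action <- mix_policies(des, model$policies[keys], model$plant, steps)
  } else {
    action <- structure(c(0, 0), class = "control_action")
  }
  # motor noise perturbs executed forces only: the cursor is quiescent until
  # a reach policy is engaged
  noise2 <- if (spec$plant$motor_noise_sd > 0 && model$moving) {
    stats::rnorm(2)
  } else {
    c(0, 0)
  }
  prev_pos <- model$plant$position
  model$plant <- step_plant(model$plant, action, spec$plant, noise2)
  model$path_length <- model$path_length +
    sqrt(sum((model$plant$position - prev_pos)^2))

  speed <- sqrt(sum(model$plant$velocity^2))
  if (speed > spec$heading_speed_frac * spec$nominal_peak_speed) {
    model$heading <- atan2(model$plant$velocity[2],
                           model$plant$velocity[1]) * 180 / pi
  }

  # -- adjudication-relevant geometry ---------------------------------------
  for (tg in model$targets) {
    th <- tg$direction * pi / 180
    goal <- spec$target_radius * c(cos(th), sin(th))
    if (sqrt(sum((model$plant$position - goal)^2)) <= spec$target_disc_radius) {
      model$reached <- TRUE
      model$reached_direction <- tg$direction
      model$events$target_acquired <- t_next
      break
    }
  }
  if (model$switched && !is.null(model$old_targets)) {
    for (tg in model$old_targets) {
      th <- tg$direction * pi / 180
      goal <- spec$target_radius * c(cos(th), sin(th))
      if (sqrt(sum((model$plant$position - goal)^2)) <= spec$target_disc_radius) {
        model$old_disc_entered <- TRUE
      }
    }
  }

  model$t <- t_next
  model$step <- model$step + 1L
  model
}

#' Run the closed-loop model for one scheduled trial
#'
#' Iterates [model_step()] from trial start to the (possibly extended)
#' deadline or until the cursor acquires a target, recording the cursor
#' trajectory at the integration rate and, optionally, the planning-field
#' activity over time.
#'
#' @param spec A [model_spec()].
#' @param schedule An [event_schedule()].
#' @param record_fields If `TRUE`, also return the planning-field activity
#'   as a `steps x n_dir` matrix (rows at each `dt`).
#' @return A list with `trajectory` (data frame `t_ms`, `x_cm`, `y_cm`),
#'   `events`, flags, `chosen_direction`, `threshold_crossing_ms`, the final
#'   `model_state`, and `planning_trace` when requested. Times are relative
#'   to trial start; `events$target_onset` marks the end of the fore-period.
#' @export
run_model_trial <- function(spec, schedule, record_fields = FALSE) {
  model <- init_model(spec, schedule)
  max_steps <- as.integer((schedule$deadline + 1000) / spec$dt) + 2L
  traj <- matrix(NA_real_, max_steps + 1L, 3)
  traj[1, ] <- c(0, 0, 0)
  trace <- if (record_fields) matrix(NA_real_, max_steps, spec$n_dir) else NULL
  n_rec <- 1L
  while (model$t < model$deadline && !model$reached) {
    model <- model_step(model, spec, schedule)
    n_rec <- n_rec + 1L
    traj[n_rec, ] <- c(model$t, model$plant$position)
    if (record_fields) trace[n_rec - 1L, ] <- model$fields$planning$u
  }
  trajectory <- data.frame(
    t_ms = traj[seq_len(n_rec), 1],
    x_cm = traj[seq_len(n_rec), 2],
    y_cm = traj[seq_len(n_rec), 3]
  )
  out <- list(
    trajectory = trajectory,
    events = model$events,
    moving = model$moving,
    reached = model$reached,
    reached_direction = model$reached_direction,
    switched = model$switched,
    old_disc_entered = model$old_disc_entered,
    chosen_direction = model$chosen_direction,
    threshold_crossing_ms = model$threshold_crossing_ms,
    max_weight_dev = model$max_weight_dev,
    deadline = model$deadline,
    final_state = model
  )
  if (record_fields) out$planning_trace <- trace[seq_len(n_rec - 1L), , drop = FALSE]
  out
}
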