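#' Simulate a batch of unregulated trials and extract reaction times
#'
#' Runs `n` trials of the given task context (no stop/switch signal ever
#' fires) and returns the tidy trial table. Because per-trial RNG substreams
#' depend only on `(seed, trial index)`, batches run with the same `seed`
#' are noise-matched across task contexts and architectures: conditions that
#' differ only in pause engagement can be compared trial by trial. This is
#' the planning-phase RT comparison used throughout: the anticipation of a
#' stop or switch signal acts through the tonic pause level alone.
#'
#' @param task `"decision"`, `"stop"` or `"switch"`.
#' @param trial_type `"instructed"` or `"choice"`.
#' @param variant Architecture variant.
#' @param n Number of trials.
#' @param seed Batch seed.
#' @param spec Optional [model_spec()] override (its `variant` is replaced).
#' @return Tidy trial tibble from [run_experiment()].
#' @export
simulate_rt_batch <- function(task, trial_type, variant = "ARCH2", n = 50,
                              seed = 1L, spec = NULL) {
  if (is.null(spec)) spec <- model_spec(variant)
  ex <- experiment_spec(task = task, n_trials = n, trial_type = trial_type,
                        fraction_regulated = 0, seed = seed)
  run_experiment(ex, spec)
}

#' Simulate regulated switch trials and extract switch reaction times
#'
#' Runs `n` switch trials (every trial carries a switch signal) and returns
#' the trial table. Choice trials in which the model had already committed
#' to the low-reward target before the signal are excluded: removing the
#' high-reward target then demands no change of action, so no switch
#' response exists to time. Trials still undecided at the signal are kept
#' (the switch signal then redirects the ongoing plan).
#'
#' @param trial_type `"instructed"` (one-target) or `"choice"` (two-target).
#' @param variant Architecture variant.
#' @param n Number of regulated trials.
#' @param mode `"staircase"` (default; the task's adaptive SWSD, so the
#'   signal lands near each condition's own critical delay, as in the human
#'   protocol) or `"fixed_delays"`.
#' @param swsd Switch-signal delay in ms after target onset
#'   (`fixed_delays` mode).
#' @param seed Batch seed.
#' @param spec Optional [model_spec()] override.
#' @return Tidy trial tibble, one row per genuine switch trial.
#' @export
simulate_srt_batch <- function(trial_type, variant, n = 50,
                               mode = "staircase", swsd = 250,
                               initial_delay = 400,
                               seed = 1L, spec = NULL) {
  if (is.null(spec)) spec <- model_spec(variant)
  ex <- experiment_spec(task = "switch", n_trials = n, trial_type = trial_type,
                        fraction_regulated = 1, mode = mode,
                        fixed_delays = swsd, initial_delay = initial_delay,
                        seed = seed)
  res <- run_experiment(ex, spec)
  if (trial_type == "choice") {
    removed <- ex$directions[which.max(ex$rewards)]
    committed_low <- !is.na(res$chosen_direction) &
      !is.na(res$threshold_crossing_ms) &
      res$threshold_crossing_ms <= res$delay &
      angle_diff(res$chosen_direction, removed) >= 30
    res <- res[!committed_low, ]
  }
  res
}

#' Simulate the fixed-SSD stop-signal sweep
#'
#' One-target and two-target stop blocks with `n_per_ssd` regulated trials
#' at each SSD, mirroring the simulated sweep design (equal instructed and
#' choice trial counts, regulated trials balanced over the SSD list).
#'
#' @param variant Architecture variant.
#' @param n_per_ssd Regulated trials per SSD per block.
#' @param ssds SSD values in ms.
#' @param n_unregulated Additional unregulated trials per block.
#' @param seed Batch seed.
#' @param spec Optional [model_spec()] override.
#' @return List with `one_target` and `two_target` trial tibbles and the
#'   corresponding stop curves from [stop_probability_by_ssd()].
#' @export
simulate_stop_sweep <- function(variant = "ARCH2", n_per_ssd = 50,
                                ssds = c(200, 350, 500, 650, 800),
                                n_unregulated = 50, seed = 1L, spec = NULL) {
  if (is.null(spec)) spec <- model_spec(variant)
  run_block <- function(trial_type) {
    n_reg <- n_per_ssd * length(ssds)
    n <- n_reg + n_unregulated
    ex <- experiment_spec(task = "stop", n_trials = n, trial_type = trial_type,
                          fraction_regulated = n_reg / n,
                          mode = "fixed_delays", fixed_delays = ssds,
                          seed = seed)
    run_experiment(ex, spec)
  }
  one <- run_block("instructed")
  two <- run_block("choice")
  list(one_target = one, two_target = two,
       curve_one = stop_probability_by_ssd(one),
       curve_two = stop_probability_by_ssd(two))
}

#' Simulate a staircase block and measure its long-run success rate
#'
#' Runs a block of regulated trials whose delay is governed by the adaptive
#' +/-50 ms staircase (initial 250 ms, clamped at 0) and reports the
#' percentage of successful stops/switches over the final `window` trials —
#' the quantity the staircase is designed to hold near 50%.
#'
#' @param task `"stop"` or `"switch"`.
#' @param variant Architecture variant (`"ARCH3"` is the default for the
#'   switch task).
#' @param n_regulated Number of regulated trials (all trials in the block
#'   are regulated).
#' @param window Number of final trials over which the rate is measured.
#' @param seed Batch seed.
#' @param spec Optional [model_spec()] override.
#' @return List with `results` (trial tibble), `success_rate_pct` over the
#'   final window, and the final `staircase` state.
#' @export
simulate_staircase_convergence <- function(task = c("stop", "switch"),
                                           variant = if (task == "switch") "ARCH3" else "ARCH2",
                                           n_regulated = 320, window = 200,
                                           seed = 1L, spec = NULL) {
  task <- match.arg(task)
  if (is.null(spec)) spec <- model_spec(variant)
  ex <- experiment_spec(task = task, n_trials = n_regulated,
                        trial_type = "instructed",
                        fraction_regulated = 1, mode = "staircase", seed = seed)
  res <- run_experiment(ex, spec)
  success <- if (task == "stop") res$stopped else res$switched_ok
  tail_idx <- seq(max(1, length(success) - window + 1), length(success))
  list(results = res,
       success_rate_pct = 100 * mean(success[tail_idx]),
       staircase = attr(res, "staircase"))
}

#' Proportion of choice trials selecting the high-reward target
#'
#' @param n Number of choice decision trials.
#' @param seed Batch seed.
#' @param spec Optional [model_spec()] override.
#' @return List with `p_high`, `n_decided`, and the trial tibble.
#' @export
simulate_reward_bias <- function(n = 100, seed = 1L, spec = NULL) {
  if (is.null(spec)) spec <- model_spec("ARCH2")
  ex <- experiment_spec(task = "decision", n_trials = n, trial_type = "choice",
                        fraction_regulated = 0, seed = seed)
  res <- run_experiment(ex, spec)
  high <- ex$directions[which.max(ex$rewards)]
  decided <- !is.na(res$chosen_direction)
  list(p_high = mean(angle_diff(res$chosen_direction[decided], high) < 30),
       n_decided = sum(decided), results = res)
}
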