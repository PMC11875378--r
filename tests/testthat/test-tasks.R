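spec2t <- model_spec("ARCH2")

test_that("schedules realize condition counts exactly", {
  ex <- experiment_spec("decision", 100, "mixed", seed = 4)
  cfgs <- schedule_trials(ex)
  types <- vapply(cfgs, `[[`, character(1), "trial_type")
  expect_equal(sum(types == "instructed"), 50)
  expect_equal(sum(types == "choice"), 50)
  fp <- vapply(cfgs, `[[`, numeric(1), "fore_period")
  expect_true(all(fp >= 1000 & fp <= 1100))

  exs <- experiment_spec("stop", 300, "instructed",
                         fraction_regulated = 250 / 300,
                         mode = "fixed_delays", seed = 4)
  cfgs <- schedule_trials(exs)
  reg <- vapply(cfgs, function(cfg) cfg$regulation == "stop", logical(1))
  expect_equal(sum(reg), 250)
  delays <- vapply(cfgs[reg], `[[`, numeric(1), "delay")
  expect_true(all(table(delays) == 50))          # 5 SSDs x 50 trials

  expect_length(schedule_trials(experiment_spec("decision", 0)), 0)
  expect_warning(
    schedule_trials(experiment_spec("stop", 10, fraction_regulated = 0.33)),
    "rounding"
  )
  expect_error(experiment_spec("decision", 10, fraction_regulated = 0.3),
               "no regulation")
})

test_that("stop success requires no target contact and a full stop in time", {
  mk_trial <- function(xy, reached = FALSE) {
    t_ms <- seq(0, 1900, by = 10)
    list(reached = reached,
         trajectory = data.frame(t_ms = t_ms, x_cm = xy[, 1], y_cm = xy[, 2]))
  }
  n <- 191
  still <- mk_trial(cbind(rep(0, n), rep(0, n)))
  expect_true(evaluate_stop_success(still, spec2t))

  touched <- mk_trial(cbind(rep(0, n), rep(0, n)), reached = TRUE)
  expect_false(evaluate_stop_success(touched, spec2t))

  # decelerates to rest well short of the target: both criteria met
  y <- pmin(cumsum(c(0, rep(0.3, 60), rep(0, n - 61))), 15)
  short <- mk_trial(cbind(rep(0, n), y))
  expect_true(evaluate_stop_success(short, spec2t))

  # keeps moving at high speed until the recording ends: no stop
  moving <- mk_trial(cbind(rep(0, n), seq(0, 0.5 * (n - 1), by = 0.5)))
  expect_false(evaluate_stop_success(moving, spec2t))
})

test_that("switch success requires avoiding the old disc and reaching the new", {
  good <- list(switched = TRUE, old_disc_entered = FALSE, reached = TRUE)
  crossed <- list(switched = TRUE, old_disc_entered = TRUE, reached = TRUE)
  lost <- list(switched = TRUE, old_disc_entered = FALSE, reached = FALSE)
  expect_true(evaluate_switch_success(good))
  expect_false(evaluate_switch_success(crossed))
  expect_false(evaluate_switch_success(lost))
})

test_that("the staircase moves +/-50 ms and clamps at zero", {
  st <- staircase_state(value = 250, step = 50)
  st <- update_staircase(st, TRUE)
  expect_equal(st$value, 300)
  st <- update_staircase(st, FALSE)
  expect_equal(st$value, 250)
  st0 <- staircase_state(value = 0)
  st0 <- update_staircase(st0, FALSE)
  expect_equal(st0$value, 0)
  expect_equal(nrow(st0$history), 1)
  expect_false(st0$history$success[1])
})

test_that("the distance threshold fires at the stated path length", {
  still <- data.frame(x_cm = rep(0, 50), y_cm = rep(0, 50))
  expect_false(distance_threshold_signal(still, 0.02))

  moving <- data.frame(x_cm = seq(0, 1, length.out = 50), y_cm = 0)
  expect_true(distance_threshold_signal(moving, 0))
  # 2% of 20.37 cm = 0.4074 cm: fires once the path exceeds that
  expect_true(distance_threshold_signal(moving, 0.02, 20.37))
  short <- data.frame(x_cm = seq(0, 0.40, length.out = 50), y_cm = 0)
  expect_false(distance_threshold_signal(short, 0.02, 20.37))
})

test_that("run_trial adjudicates the canonical trial types", {
  ex <- experiment_spec("decision", 10, "instructed", seed = 6)
  cfgs <- schedule_trials(ex)
  reached <- vapply(cfgs, function(cfg) run_trial(spec2t, cfg)$reached, logical(1))
  expect_gte(mean(reached), 0.9)

  exs <- experiment_spec("stop", 5, "instructed", fraction_regulated = 1,
                         mode = "fixed_delays", fixed_delays = 0, seed = 6)
  stopped <- vapply(schedule_trials(exs), function(cfg) {
    isTRUE(run_trial(spec2t, cfg)$stopped)
  }, logical(1))
  expect_true(all(stopped))   # signal at onset: inhibition precedes crossing

  exw <- experiment_spec("switch", 2, "instructed", fraction_regulated = 1,
                         mode = "fixed_delays", fixed_delays = 300, seed = 6)
  tr <- run_trial(spec2t, schedule_trials(exw)[[1]])
  expect_equal(tr$deadline, tr$config$fore_period + 2000)  # extra 1.0 s
})

test_that("experiments are deterministic and thread the staircase", {
  ex <- experiment_spec("stop", 12, "instructed", fraction_regulated = 1,
                        mode = "staircase", seed = 9)
  r1 <- run_experiment(ex, spec2t)
  r2 <- run_experiment(ex, spec2t)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  # delay trace follows +/-50 of the recorded successes
  expected <- 250 + 50 * cumsum(ifelse(r1$stopped, 1, -1))
  expect_equal(r1$delay[-1], pmax(0, expected[-length(expected)]))
})
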