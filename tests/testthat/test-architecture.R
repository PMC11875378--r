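spec2 <- model_spec("ARCH2")

test_that("targets are encoded as Gaussian bumps scaled by reward", {
  enc0 <- encode_targets(list(), spec2)
  expect_true(all(enc0$sensory == 0) && all(enc0$outcome == 0))

  enc <- encode_targets(list(list(direction = 120, reward = 10)), spec2)
  expect_equal(which.max(enc$sensory), 121)          # neuron at 120 deg
  expect_equal(max(enc$sensory), spec2$sensory_amp)

  e10 <- encode_targets(list(list(direction = 60, reward = 10)), spec2)
  e5 <- encode_targets(list(list(direction = 60, reward = 5)), spec2)
  expect_equal(max(e10$outcome) / max(e5$outcome), 2)  # linear in reward

  expect_error(encode_targets(list(list(direction = 190, reward = 1)), spec2),
               "direction")
})

test_that("reach cost is flat before onset and rises away from the heading", {
  flat <- compute_reach_cost(NULL, spec2)
  expect_true(all(flat == spec2$cost_baseline))
  expect_identical(compute_reach_cost(NA, spec2), flat)

  c60 <- compute_reach_cost(60, spec2)
  expect_equal(which.min(c60), 61)
  expect_equal(which.max(c60), 181)                  # 120 deg away, lattice edge
  # profiles are shifted copies: equal |direction - heading| gives equal cost
  c0 <- compute_reach_cost(0, spec2)
  expect_equal(c0[1 + 40], c60[61 + 40])
  expect_equal(c0[1 + 100], c60[61 + 100])
})

test_that("pause engagement follows the architecture rules", {
  s <- spec2
  grid <- expand.grid(v = c("ARCH1", "ARCH2", "ARCH3"),
                      ph = c("planning", "post_signal"),
                      tt = c("instructed", "choice"),
                      stringsAsFactors = FALSE)
  # decision task: never engaged
  for (i in seq_len(nrow(grid))) {
    expect_equal(pause_drive(grid$v[i], "decision", grid$ph[i], grid$tt[i], s), 0)
  }
  # stop task: proactive while planning, strong after the signal, all variants
  for (v in c("ARCH1", "ARCH2", "ARCH3")) {
    expect_equal(pause_drive(v, "stop", "planning", "choice", s),
                 s$pause_proactive)
    expect_equal(pause_drive(v, "stop", "post_signal", "instructed", s),
                 s$pause_post_stop)
  }
  # switch task
  expect_equal(pause_drive("ARCH2", "switch", "planning", "choice", s), 0)
  expect_equal(pause_drive("ARCH2", "switch", "post_signal", "instructed", s), 0)
  expect_equal(pause_drive("ARCH1", "switch", "planning", "instructed", s),
               s$pause_proactive)
  expect_equal(pause_drive("ARCH1", "switch", "post_signal", "instructed", s),
               s$pause_post_switch)
  expect_equal(pause_drive("ARCH3", "switch", "planning", "instructed", s), 0)
  expect_equal(pause_drive("ARCH3", "switch", "post_signal", "instructed", s),
               s$pause_post_switch)
  expect_equal(pause_drive("ARCH3", "switch", "post_signal", "choice", s), 0)
  expect_equal(pause_drive("ARCH3", "switch_noreward", "post_signal", "choice", s), 0)
})

test_that("nothing moves before target onset", {
  sch <- event_schedule(target_onset = 1000,
                        targets = list(list(direction = 120, reward = 10)))
  set.seed(5)
  m <- init_model(spec2, sch)
  for (i in 1:99) m <- model_step(m, spec2, sch)
  expect_false(m$moving)
  expect_equal(m$plant$position, c(0, 0))
  expect_lt(max(m$fields$planning$u), 0)  # noise around rest, far below threshold
})

test_that("instructed trials select the cued direction and acquire the target", {
  hits <- 0L; within3 <- 0L
  n <- 20
  for (seed in seq_len(n)) {
    set.seed(seed)
    sch <- event_schedule(target_onset = 1000,
                          targets = list(list(direction = 120, reward = 10)),
                          deadline = 2000)
    tr <- run_model_trial(spec2, sch)
    hits <- hits + tr$reached
    if (!is.na(tr$chosen_direction) && abs(tr$chosen_direction - 120) <= 3) {
      within3 <- within3 + 1L
    }
  }
  expect_gte(hits, 0.9 * n)
  expect_gte(within3, 0.9 * n)
})

test_that("a stop signal at target onset prevents movement entirely", {
  for (seed in 1:5) {
    set.seed(seed)
    sch <- event_schedule(target_onset = 1000,
                          targets = list(list(direction = 120, reward = 10)),
                          stop_time = 1000, deadline = 2000,
                          task = "stop", trial_type = "instructed")
    tr <- run_model_trial(spec2, sch)
    expect_false(tr$moving)
    expect_equal(tr$trajectory$x_cm, rep(0, nrow(tr$trajectory)))
  }
})

test_that("trigger_switch swaps target drives per condition", {
  one <- event_schedule(target_onset = 0,
                        targets = list(list(direction = 120, reward = 10)),
                        switch_time = 0,
                        new_targets = list(list(direction = 60, reward = 10)),
                        task = "switch")
  m <- init_model(spec2, one)
  m$targets <- one$targets
  m2 <- trigger_switch(m, one)
  expect_equal(m2$targets[[1]]$direction, 60)
  expect_equal(vapply(m2$old_targets, `[[`, numeric(1), "direction"), 120)
  expect_equal(m2$deadline, one$deadline + 1000)
  expect_true(m2$switched)

  both <- list(list(direction = 120, reward = 10),
               list(direction = 60, reward = 5))
  two <- event_schedule(target_onset = 0, targets = both, switch_time = 0,
                        new_targets = both[2], task = "switch",
                        trial_type = "choice")
  m <- init_model(spec2, two)
  m$targets <- both
  m2 <- trigger_switch(m, two)
  expect_equal(m2$targets[[1]]$reward, 5)               # low-reward remains
  expect_equal(m2$old_targets[[1]]$direction, 120)      # high-reward removed

  none <- event_schedule(target_onset = 0, targets = both)
  expect_error(trigger_switch(init_model(spec2, none), none), "no switch")
})

test_that("planning activity is suppressed when a stop signal is anticipated", {
  # proactive pause lowers the planning field's pre-movement peak (stop task
  # unregulated trials vs decision trials, matched noise)
  n <- 30
  peak <- function(task) {
    vapply(seq_len(n), function(seed) {
      ex <- experiment_spec(task, n_trials = n, trial_type = "instructed",
                            fraction_regulated = 0, seed = 42)
      cfg <- schedule_trials(ex)[[seed]]
      tr <- run_trial(spec2, cfg, record_fields = TRUE)
      onset_step <- ceiling(cfg$fore_period / spec2$dt)
      window <- onset_step:min(onset_step + 25, nrow(tr$planning_trace))
      max(tr$planning_trace[window, ])
    }, numeric(1))
  }
  p_dec <- peak("decision")
  p_stop <- peak("stop")
  expect_lt(mean(p_stop), mean(p_dec))
})

test_that("switch planning under ARCH2 is indistinguishable from decision", {
  dec <- simulate_rt_batch("decision", "instructed", n = 15, seed = 8)
  sw <- simulate_rt_batch("switch", "instructed", "ARCH2", n = 15, seed = 8)
  expect_equal(sw$rt, dec$rt)        # pause = 0 in both, same substreams
  expect_equal(sw$threshold_crossing_ms, dec$threshold_crossing_ms)
})

test_that("desirability stays normalized through closed-loop trials", {
  res <- simulate_rt_batch("decision", "choice", n = 10, seed = 14)
  expect_lt(max(res$max_weight_dev), 1e-9)
})
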