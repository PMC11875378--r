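test_that("spline velocities recover known speed profiles", {
  t_ms <- seq(0, 1000, by = 10)
  still <- data.frame(t_ms = t_ms, x_cm = 0 * t_ms, y_cm = 0 * t_ms)
  v <- smooth_and_differentiate(still)
  expect_true(all(v$speed == 0))
  expect_true(all(is.na(v$heading)))

  # constant-velocity segment: slope recovered within 1%
  cv <- data.frame(t_ms = t_ms, x_cm = 0.012 * t_ms, y_cm = 0.009 * t_ms)
  v <- smooth_and_differentiate(cv)
  mid <- v$speed[20:80]
  expect_true(all(abs(mid - 15) / 15 < 0.01))   # 12^2+9^2 -> 15 cm/s

  # noiseless minimum-jerk: peak speed = 1.875 * amplitude / duration
  fx <- make_fixture_trajectory(onset = 300, duration = 500, amplitude = 20,
                                direction = 90, noise_sd = 0, seed = 1)
  v <- smooth_and_differentiate(fx)
  expect_equal(max(v$speed), 1.875 * 20 / 0.5, tolerance = 0.02)

  expect_error(smooth_and_differentiate(cv[1:3, ]), "4 samples")
})

test_that("RT extraction matches the dense-grid minimum-jerk oracle", {
  for (onset in c(150, 300, 450)) {
    for (noise in c(0, 0.05)) {
      fx <- make_fixture_trajectory(onset = onset, duration = 500,
                                    amplitude = 20, direction = 120,
                                    noise_sd = noise, seed = 3)
      rt <- compute_rt(smooth_and_differentiate(fx), onset)
      oracle <- minjerk_rt_oracle(onset, 500, 20)
      expect_lt(abs(rt - oracle), 10)     # one sample period at 100 Hz
    }
  }
})

test_that("RT is relative to peak speed and absent without movement", {
  t_ms <- seq(0, 800, by = 10)
  still <- data.frame(t_ms = t_ms, x_cm = 0 * t_ms, y_cm = 0 * t_ms)
  expect_true(is.na(compute_rt(smooth_and_differentiate(still), 100)))

  fx <- make_fixture_trajectory(onset = 200, duration = 400, amplitude = 15,
                                direction = 60, seed = 2)
  v <- smooth_and_differentiate(fx)
  rt1 <- compute_rt(v, 200)
  v_scaled <- v
  v_scaled$speed <- 3 * v$speed
  expect_equal(compute_rt(v_scaled, 200), rt1)
})

test_that("RT exclusions drop anticipations and 3-SD outliers once", {
  f <- filter_rts(c(90, 300, 310, 320))
  expect_equal(f$kept, c(300, 310, 320))
  expect_equal(f$excluded$reason, "faster_than_100ms")

  same <- filter_rts(rep(400, 20))
  expect_equal(same$kept, rep(400, 20))      # SD = 0 excludes nothing

  rts <- c(rep(300, 49), 900)                # mean 312, sd ~84.9: 900 is out
  f <- filter_rts(rts)
  expect_equal(f$kept, rep(300, 49))
  expect_equal(f$excluded$rt, 900)

  # idempotent on its own output
  f2 <- filter_rts(f$kept)
  expect_equal(f2$kept, f$kept)
  expect_equal(nrow(f2$excluded), 0)
})

test_that("SRT finds the redirection toward the new goal", {
  # already heading at the new target with above-criterion speed: SRT ~ 0
  t_ms <- seq(0, 1000, by = 10)
  th <- 60 * pi / 180
  straight <- data.frame(t_ms = t_ms,
                         x_cm = cos(th) * 0.02 * t_ms,
                         y_cm = sin(th) * 0.02 * t_ms)
  v <- smooth_and_differentiate(straight)
  expect_lte(compute_srt(straight, v, 500, 60), 10)

  # redirect fixture: SRT within one sample period of the cone-crossing
  # found on a densely sampled noiseless copy of the same path
  fx <- make_fixture_trajectory(onset = 200, duration = 500, amplitude = 20.37,
                                direction = 120, redirect_time = 500,
                                second_direction = 60, seed = 4)
  dense <- make_fixture_trajectory(onset = 200, duration = 500,
                                   amplitude = 20.37, direction = 120,
                                   redirect_time = 500, second_direction = 60,
                                   rate = 2000, seed = 4)
  v <- smooth_and_differentiate(fx)
  srt <- compute_srt(fx, v, 500, 60)
  vd <- smooth_and_differentiate(dense)
  srt_dense <- compute_srt(dense, vd, 500, 60)
  expect_lt(abs(srt - srt_dense), 10)

  # a path that never turns toward the new target yields no SRT
  away <- make_fixture_trajectory(onset = 200, duration = 500, amplitude = 20,
                                  direction = 170, seed = 5)
  va <- smooth_and_differentiate(away)
  expect_true(is.na(compute_srt(away, va, 400, 0)))
})

test_that("stop curves tally successes per SSD and conserve counts", {
  res <- tibble::tibble(
    regulation = rep("stop", 100),
    delay = rep(c(100, 200), each = 50),
    stopped = c(rep(TRUE, 50), rep(TRUE, 25), rep(FALSE, 25))
  )
  curve <- stop_probability_by_ssd(res)
  expect_equal(curve$ssd, c(100, 200))
  expect_equal(curve$p_stop, c(1, 0.5))
  expect_equal(sum(curve$n), 100)

  # brute-force tally oracle on a scrambled table
  set.seed(6)
  res2 <- res[sample.int(100), ]
  curve2 <- stop_probability_by_ssd(res2)
  for (i in seq_len(nrow(curve2))) {
    sel <- res2$delay == curve2$ssd[i]
    expect_equal(curve2$p_stop[i], sum(res2$stopped[sel]) / sum(sel))
  }
  empty <- stop_probability_by_ssd(res[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("fixture trajectories honor their ground truth", {
  fx <- make_fixture_trajectory(onset = 250, duration = 400, amplitude = 18,
                                direction = 45, noise_sd = 0, seed = 7)
  end <- fx[nrow(fx), ]
  expect_equal(c(end$x_cm, end$y_cm),
               18 * c(cos(pi / 4), sin(pi / 4)), tolerance = 1e-10)
  expect_true(all(fx$x_cm[fx$t_ms <= 250] == 0))

  again <- make_fixture_trajectory(onset = 250, duration = 400, amplitude = 18,
                                   direction = 45, noise_sd = 0.1, seed = 7)
  again2 <- make_fixture_trajectory(onset = 250, duration = 400, amplitude = 18,
                                    direction = 45, noise_sd = 0.1, seed = 7)
  expect_identical(again, again2)

  redir <- make_fixture_trajectory(onset = 200, duration = 400,
                                   amplitude = 20.37, direction = 120,
                                   redirect_time = 450, second_direction = 60,
                                   seed = 8)
  end <- redir[nrow(redir), ]
  goal2 <- 20.37 * c(cos(pi / 3), sin(pi / 3))
  expect_lt(sqrt(sum((c(end$x_cm, end$y_cm) - goal2)^2)), 2.75)
})

test_that("rt_summary pools filtered RTs per condition", {
  res <- tibble::tibble(
    task = rep(c("decision", "stop"), each = 10),
    trial_type = "instructed",
    rt = c(rep(400, 9), 90, rep(500, 10))
  )
  s <- rt_summary(res)
  expect_equal(s$n, c(9, 10))                 # the 90 ms RT was excluded
  expect_equal(s$mean, c(400, 500))
  expect_equal(s$se[2], 0)
})
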