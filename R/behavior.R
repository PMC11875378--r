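#' Smooth a trajectory and compute its velocity profile
#'
#' Fits a cubic smoothing spline to each coordinate as a function of time
#' and evaluates the spline's first derivative on the sample grid. Applied
#' identically to simulated and recorded joystick trajectories: this is the
#' single entry point of the kinematic pipeline.
#'
#' @param traj Data frame with columns `t_ms`, `x_cm`, `y_cm` (times
#'   strictly increasing, at least 4 samples).
#' @param smoothing Smoothing parameter passed to
#'   [stats::smooth.spline()]'s `spar`; `NULL` (default) selects it by
#'   generalized cross-validation, which recovers a noiseless minimum-jerk
#'   peak speed within 2%.
#' @return A data frame with `t_ms`, `speed` (cm/s), `heading` (degrees,
#'   `NA` where speed is negligible), `vx`, `vy`.
#' @export
smooth_and_differentiate <- function(traj, smoothing = NULL) {
  if (nrow(traj) < 4) stop("need at least 4 samples to smooth")
  if (any(diff(traj$t_ms) <= 0)) stop("sample times must be strictly increasing")
  t_s <- traj$t_ms / 1000
  deriv1 <- function(y) {
    if (stats::sd(y) < 1e-12) return(rep(0, length(y)))
    fit <- if (is.null(smoothing)) {
      stats::smooth.spline(t_s, y)
    } else {
      stats::smooth.spline(t_s, y, spar = smoothing)
    }
    stats::predict(fit, t_s, deriv = 1)$y
  }
  vx <- deriv1(traj$x_cm)
  vy <- deriv1(traj$y_cm)
  speed <- sqrt(vx^2 + vy^2)
  heading <- ifelse(speed > 1e-6, atan2(vy, vx) * 180 / pi, NA_real_)
  data.frame(t_ms = traj$t_ms, speed = speed, heading = heading,
             vx = vx, vy = vy)
}

#' Reaction time from a velocity profile
#'
#' RT is the interval between target onset and the first post-onset sample
#' whose speed exceeds 10% of the trial's maximum speed. The threshold is
#' relative, so uniform speed scaling leaves RT unchanged.
#'
#' @param vel Velocity profile from [smooth_and_differentiate()].
#' @param onset Target onset time in ms (on the profile's time base).
#' @param min_peak_speed Absolute floor (cm/s) below which the trial counts
#'   as "no movement" and RT is `NA`.
#' @return RT in ms, or `NA` if the cursor never moved.
#' @export
compute_rt <- function(vel, onset, min_peak_speed = 1) {
  vmax <- max(vel$speed)
  if (!is.finite(vmax) || vmax < min_peak_speed) return(NA_real_)
  idx <- which(vel$t_ms >= onset & vel$speed > 0.1 * vmax)
  if (length(idx) == 0) return(NA_real_)
  vel$t_ms[idx[1]] - onset
}

#' Apply the RT exclusion rules
#'
#' Drops RTs faster than 100 ms (anticipation), then — in a single pass,
#' with mean and SD computed on the remaining set — RTs more than 3
#' standard deviations from the mean. Idempotent on its own output.
#'
#' @param rts Numeric vector of RTs in ms (`NA`s are dropped and logged).
#' @return A list with `kept` (numeric) and `excluded` (data frame with
#'   `rt` and `reason`).
#' @export
filter_rts <- function(rts) {
  excluded <- data.frame(rt = numeric(0), reason = character(0))
  na <- is.na(rts)
  if (any(na)) {
    excluded <- rbind(excluded, data.frame(rt = rts[na], reason = "missing"))
    rts <- rts[!na]
  }
  fast <- rts < 100
  if (any(fast)) {
    excluded <- rbind(excluded,
                      data.frame(rt = rts[fast], reason = "faster_than_100ms"))
    rts <- rts[!fast]
  }
  if (length(rts) >= 2) {
    m <- mean(rts)
    s <- stats::sd(rts)
    out <- s > 0 & abs(rts - m) > 3 * s
    if (any(out)) {
      excluded <- rbind(excluded,
                        data.frame(rt = rts[out], reason = "outlier_3sd"))
      rts <- rts[!out]
    }
  }
  list(kept = rts, excluded = excluded)
}

# smallest absolute angular difference in degrees
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Switch reaction time
#'
#' SRT is the interval between the switch signal and the first post-signal
#' sample at which the cursor is moving (speed above 10% of the trial's
#' maximum) with heading inside a cone around the bearing from the cursor's
#' current position to the new target — i.e. the moment the cursor starts
#' to move towards the new target location. The bearing is evaluated per
#' sample because a mid-flight redirection approaches the new goal from a
#' displaced position, not from the origin.
#'
#' @param traj Trajectory data frame (`t_ms`, `x_cm`, `y_cm`), the same one
#'   the velocity profile was computed from.
#' @param vel Velocity profile from [smooth_and_differentiate()].
#' @param switch_time Switch-signal time in ms.
#' @param new_direction New target direction in degrees.
#' @param target_radius New target eccentricity in cm (goal point).
#' @param cone_tolerance Half-width of the heading cone, degrees.
#' @param min_peak_speed Absolute no-movement floor in cm/s.
#' @return SRT in ms, or `NA` if the criterion is never met.
#' @export
compute_srt <- function(traj, vel, switch_time, new_direction,
                        target_radius = 20.37,
                        cone_tolerance = 30, min_peak_speed = 1) {
  vmax <- max(vel$speed)
  if (!is.finite(vmax) || vmax < min_peak_speed) return(NA_real_)
  th <- new_direction * pi / 180
  goal <- target_radius * c(cos(th), sin(th))
  bearing <- atan2(goal[2] - traj$y_cm, goal[1] - traj$x_cm) * 180 / pi
  ok <- vel$t_ms >= switch_time &
    vel$speed > 0.1 * vmax &
    !is.na(vel$heading) &
    angle_diff(vel$heading, bearing) < cone_tolerance
  idx <- which(ok)
  if (length(idx) == 0) return(NA_real_)
  vel$t_ms[idx[1]] - switch_time
}

#' Stop-probability curve
#'
#' Groups regulated stop trials by SSD and computes the fraction adjudicated
#' as successful stops.
#'
#' @param results Tidy trial table from [run_experiment()] (needs `delay`,
#'   `stopped`, `regulation`).
#' @return A tibble with `ssd`, `p_stop`, `n`, ordered by SSD.
#' @export
stop_probability_by_ssd <- function(results) {
  stop_trials <- results[results$regulation == "stop" & !is.na(results$stopped), ]
  if (nrow(stop_trials) == 0) {
    return(tibble::tibble(ssd = numeric(0), p_stop = numeric(0), n = integer(0)))
  }
  ssd <- sort(unique(stop_trials$delay))
  tibble::tibble(
    ssd = ssd,
    p_stop = vapply(ssd, function(s) mean(stop_trials$stopped[stop_trials$delay == s]),
                    numeric(1)),
    n = vapply(ssd, function(s) sum(stop_trials$delay == s), integer(1))
  )
}

#' Summarize reaction times per condition
#'
#' Pools RTs (after [filter_rts()] exclusions) within each combination of
#' the given grouping columns and reports mean, SE and n — the tidy table
#' the human analyses feed to downstream statistics.
#'
#' @param results Tidy trial table with an `rt` column.
#' @param by Character vector of grouping column names.
#' @param column Which column to summarize (`"rt"` or `"srt"`).
#' @return A tibble with the grouping columns plus `mean`, `se`, `n`.
#' @export
rt_summary <- function(results, by = c("task", "trial_type"), column = "rt") {
  groups <- unique(results[by])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(results))
    for (b in by) sel <- sel & results[[b]] == groups[[b]][i]
    kept <- filter_rts(results[[column]][sel])$kept
    cbind(groups[i, , drop = FALSE],
          tibble::tibble(mean = mean(kept), se = stats::sd(kept) / sqrt(length(kept)),
                         n = length(kept)))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Minimum-jerk displacement profile
#'
#' Closed-form normalized minimum-jerk position along a straight path:
#' `s(p) = 10 p^3 - 15 p^4 + 6 p^5` for phase `p` in `[0, 1]`. Its peak
#' speed is `1.875 * amplitude / duration`.
#'
#' @param phase Movement phase in `[0, 1]` (clamped).
#' @return Normalized displacement in `[0, 1]`.
#' @export
minimum_jerk <- function(phase) {
  p <- pmin(pmax(phase, 0), 1)
  10 * p^3 - 15 * p^4 + 6 * p^5
}

#' Generate a synthetic joystick trajectory with known ground truth
#'
#' Emulates a recorded joystick trajectory: quiescent fore-period, a
#' minimum-jerk reach of given amplitude and direction, an optional
#' mid-flight redirection toward a second direction (a second minimum-jerk
#' segment from the redirect point to the second goal), additive Gaussian
#' sensor noise, sampled at a fixed rate.
#'
#' @param onset Movement onset in ms.
#' @param duration Movement duration in ms (per segment).
#' @param amplitude Reach amplitude in cm.
#' @param direction Reach direction in degrees.
#' @param redirect_time Redirection time in ms (`NA` for none; must exceed
#'   `onset`).
#' @param second_direction Direction of the redirected segment's goal.
#' @param noise_sd Positional noise SD in cm.
#' @param rate Sample rate in Hz.
#' @param total Total recording length in ms.
#' @param seed Integer seed (same seed, same trajectory).
#' @return A `t_ms`/`x_cm`/`y_cm` data frame with attribute `"ground_truth"`
#'   (the generating parameters).
#' @export
make_fixture_trajectory <- function(onset, duration, amplitude, direction,
                                    redirect_time = NA,
                                    second_direction = NA,
                                    noise_sd = 0, rate = 100,
                                    total = onset + 2.5 * duration,
                                    seed = 1L) {
  stopifnot(onset >= 0, amplitude > 0, duration > 0, rate > 0)
  set.seed(as.integer(seed))
  t_ms <- seq(0, total, by = 1000 / rate)
  th1 <- direction * pi / 180
  u1 <- c(cos(th1), sin(th1))
  pos <- outer(amplitude * minimum_jerk((t_ms - onset) / duration), u1)
  if (!is.na(redirect_time)) {
    stopifnot(redirect_time > onset, !is.na(second_direction))
    th2 <- second_direction * pi / 180
    goal2 <- amplitude * c(cos(th2), sin(th2))
    p0 <- amplitude * minimum_jerk((redirect_time - onset) / duration) * u1
    after <- t_ms >= redirect_time
    s2 <- minimum_jerk((t_ms[after] - redirect_time) / duration)
    pos[after, ] <- rep(p0, each = sum(after)) + outer(s2, goal2 - p0)
  }
  if (noise_sd > 0) pos <- pos + matrix(stats::rnorm(2 * length(t_ms), 0, noise_sd),
                                        ncol = 2)
  out <- data.frame(t_ms = t_ms, x_cm = pos[, 1], y_cm = pos[, 2])
  attr(out, "ground_truth") <- list(
    onset = onset, duration = duration, amplitude = amplitude,
    direction = direction, redirect_time = redirect_time,
    second_direction = second_direction, noise_sd = noise_sd,
    rate = rate, seed = seed
  )
  out
}
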