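#' Point-mass cursor parameters
#'
#' The simulated cursor is a 2D point mass with viscous damping, driven by
#' the mixed control force plus white motor noise.
#'
#' @param mass Mass (arbitrary units).
#' @param dt Control/integration step in ms.
#' @param motor_noise_sd Standard deviation of the additive force noise,
#'   applied per step at the configured `dt`.
#' @param damping Viscous damping coefficient in 1/s (>= 0).
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(mass = 1, dt = 10, motor_noise_sd = 0, damping = 8) {
  if (dt <= 0) stop("dt must be > 0")
  if (motor_noise_sd < 0) stop("motor_noise_sd must be >= 0")
  if (damping < 0) stop("damping must be >= 0")
  structure(
    list(mass = mass, dt = dt, motor_noise_sd = motor_noise_sd,
         damping = damping),
    class = "plant_params"
  )
}

#' Cursor state
#'
#' @param position 2D position in cm (origin at trial start).
#' @param velocity 2D velocity in cm/s.
#' @param t Time in ms.
#' @return An object of class `plant_state`.
#' @export
plant_state <- function(position = c(0, 0), velocity = c(0, 0), t = 0) {
  stopifnot(all(is.finite(position)), all(is.finite(velocity)))
  structure(list(position = position, velocity = velocity, t = t),
            class = "plant_state")
}

# Discrete per-axis dynamics of the damped point mass under semi-implicit
# Euler: v' = v + h (F/m - c v), p' = p + h v', with h = dt in seconds.
# State z = (p - goal, v), control u = F. Returns 2x2 A and 2x1 B.
plant_ab <- function(plant) {
  h <- plant$dt / 1000
  c_ <- plant$damping
  m <- plant$mass
  A <- matrix(c(1, 0, h * (1 - h * c_), 1 - h * c_), 2, 2)
  B <- matrix(c(h^2 / m, h / m), 2, 1)
  list(A = A, B = B)
}

#' Finite-horizon LQR gains via backward Riccati recursion
#'
#' Computes, for the damped point-mass axis dynamics, the per-step feedback
#' gains of the finite-horizon linear-quadratic regulator whose terminal cost
#' penalizes position and velocity error in goal-centred coordinates and
#' whose running cost penalizes effort (squared force). Because both axes
#' obey identical dynamics, one 2-state recursion serves both.
#'
#' @param horizon Number of control steps (>= 1).
#' @param plant A [plant_params()].
#' @param cost_weights List with non-negative `position`, `velocity` and
#'   strictly positive `effort` weights.
#' @return A `horizon x 2` matrix; row `k` holds the gain on
#'   (position error, velocity) at step `k`.
#' @export
lqr_gains <- function(horizon, plant, cost_weights) {
  if (horizon < 1) stop("horizon must be >= 1")
  if (cost_weights$effort <= 0) stop("effort weight must be > 0")
  if (cost_weights$position < 0 || cost_weights$velocity < 0) {
    stop("cost weights must be >= 0")
  }
  ab <- plant_ab(plant)
  A <- ab$A
  B <- ab$B
  R <- cost_weights$effort
  P <- diag(c(cost_weights$position, cost_weights$velocity))
  K <- matrix(0, horizon, 2)
  for (k in horizon:1) {
    BtP <- crossprod(B, P)
    Kk <- drop(BtP %*% A) / drop(R + BtP %*% B)
    K[k, ] <- Kk
    AmBK <- A - B %*% rbind(Kk)
    P <- crossprod(AmBK, P %*% AmBK) + cbind(Kk) %*% (R * rbind(Kk))
  }
  K
}

#' Make a reach policy toward one preferred direction
#'
#' A reach policy is the finite-horizon LQR feedback law steering the cursor
#' from its current state to the goal point at `target_radius` along the
#' policy's preferred direction (angles counterclockwise from +x).
#'
#' @param direction Preferred direction in degrees.
#' @param target_radius Goal distance from the origin in cm (default the
#'   task's 20.37 cm target eccentricity).
#' @param horizon Number of control steps.
#' @param cost_weights See [lqr_gains()].
#' @param plant A [plant_params()].
#' @param gains Optional precomputed gain matrix from [lqr_gains()] (the
#'   gains depend only on horizon and plant, not on direction, so they can be
#'   shared across policies instantiated at the same time).
#' @return An object of class `reach_policy` with fields
#'   `preferred_direction`, `goal`, `horizon` and `feedback_gains`.
#' @export
make_reach_policy <- function(direction, target_radius = 20.37, horizon,
                              cost_weights = default_cost_weights(),
                              plant = plant_params(), gains = NULL) {
  if (is.null(gains)) gains <- lqr_gains(horizon, plant, cost_weights)
  th <- direction * pi / 180
  structure(
    list(
      preferred_direction = direction,
      goal = target_radius * c(cos(th), sin(th)),
      horizon = as.integer(horizon),
      feedback_gains = gains
    ),
    class = "reach_policy"
  )
}

#' Default reach cost weights
#'
#' Terminal position error dominates, so that a completed reach ends inside
#' the 2.75 cm target disc; the small effort weight yields smooth
#' bell-shaped speed profiles.
#' @return List of `position`, `velocity`, `effort` weights.
#' @export
default_cost_weights <- function() {
  list(position = 1, velocity = 0.05, effort = 2e-6)
}

#' Evaluate one policy at a state
#'
#' Linear feedback on the goal-centred state using the step's gains. Steps
#' beyond the horizon clamp to the terminal gains, so a policy keeps holding
#' its goal after its nominal movement time has elapsed.
#'
#' @param policy A [make_reach_policy()] policy.
#' @param state A [plant_state()].
#' @param step Step index (1-based) into the gain schedule.
#' @return 2D force vector (class `control_action`).
#' @export
policy_action <- function(policy, state, step) {
  k <- min(max(step, 1L), policy$horizon)
  K <- policy$feedback_gains[k, ]
  err <- state$position - policy$goal
  f <- -(K[1] * err + K[2] * state$velocity)
  structure(f, class = "control_action")
}

#' Desirability-weighted policy mixture
#'
#' The performed action is the sum of the active policies' feedback forces
#' weighted by their relative desirability. With no active policy the force
#' is zero: the cursor does not move before a planning neuron crosses the
#' action initiation threshold.
#'
#' @param weights A desirability record from [normalize_desirability()] (or
#'   any list with a `weights` vector aligned with `policies`).
#' @param policies List of policies, aligned with `weights$weights`.
#' @param state A [plant_state()].
#' @param step Step index, scalar or one per policy.
#' @return 2D force vector (class `control_action`).
#' @export
mix_policies <- function(weights, policies, state, step) {
  w <- weights$weights
  if (length(w) == 0) return(structure(c(0, 0), class = "control_action"))
  if (length(w) != length(policies)) {
    stop("weights and policies must be aligned")
  }
  step <- rep_len(step, length(policies))
  f <- c(0, 0)
  for (j in seq_along(policies)) {
    f <- f + w[j] * unclass(policy_action(policies[[j]], state, step[j]))
  }
  structure(f, class = "control_action")
}

#' Advance the point-mass cursor one step
#'
#' Semi-implicit Euler: velocity is updated from force, noise and damping,
#' then position from the updated velocity.
#'
#' @param state A [plant_state()].
#' @param action 2D force vector.
#' @param plant A [plant_params()].
#' @param noise_draw 2D standard-normal draw (scaled by `motor_noise_sd`),
#'   or `c(0, 0)` for deterministic stepping.
#' @return The advanced `plant_state`.
#' @export
step_plant <- function(state, action, plant, noise_draw = c(0, 0)) {
  h <- plant$dt / 1000
  f <- unclass(action) + plant$motor_noise_sd * noise_draw
  v <- state$velocity + h * (f / plant$mass - plant$damping * state$velocity)
  p <- state$position + h * v
  plant_state(p, v, state$t + plant$dt)
}
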