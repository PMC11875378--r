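#' Field dynamics parameters
#'
#' Parameters of one dynamic neural field. With zero input and zero noise the
#' resting level is a fixed point of the dynamics.
#'
#' @param tau Time constant in ms (> 0).
#' @param resting_level Resting activation (typically < 0 so that baseline
#'   firing is near zero).
#' @param gain_slope Slope of the logistic output nonlinearity (1/activation).
#' @param gain_threshold Centre of the logistic (activation units).
#' @param noise_sd Standard deviation of the additive activation noise per
#'   sqrt(ms); the Euler step adds `noise_sd * sqrt(dt) * noise_draw`.
#' @return An object of class `field_params`.
#' @export
field_params <- function(tau, resting_level, gain_slope = 1,
                         gain_threshold = 0, noise_sd = 0) {
  if (tau <= 0) stop("tau must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(
      tau = tau, resting_level = resting_level,
      gain_slope = gain_slope, gain_threshold = gain_threshold,
      noise_sd = noise_sd
    ),
    class = "field_params"
  )
}

#' Field state
#'
#' @param u Activation vector, one entry per lattice neuron.
#' @param t Time in ms.
#' @return An object of class `field_state`.
#' @export
field_state <- function(u, t = 0) {
  stopifnot(all(is.finite(u)))
  structure(list(u = u, t = t), class = "field_state")
}

#' Sigmoidal firing-rate function
#'
#' Logistic output nonlinearity mapping activation to a firing rate in
#' `[0, 1]`, centred at `gain_threshold` with slope `gain_slope`.
#'
#' @param u Activation vector.
#' @param params A [field_params()].
#' @return Firing-rate vector in `[0, 1]`, monotone in `u`.
#' @export
gain_function <- function(u, params) {
  1 / (1 + exp(-params$gain_slope * (u - params$gain_threshold)))
}

#' Euler step of the field dynamics
#'
#' Advances `tau * du/dt = -u + resting_level + external_drive + K g(u)` by
#' one Euler step of length `dt`, then adds `noise_sd * sqrt(dt) * noise_draw`
#' (pass `noise_draw = 0` for deterministic integration). The stability
#' contract requires `dt <= tau / 5`.
#'
#' @param state A [field_state()].
#' @param params A [field_params()].
#' @param kernel Interaction-weight matrix from [build_kernel()], or `NULL`
#'   for a field with no lateral interactions.
#' @param external_drive Drive vector (same length as `u`).
#' @param noise_draw Standard-normal draw vector (or scalar 0).
#' @param dt Step in ms.
#' @return The advanced `field_state` with `t` increased by `dt`.
#' @export
step_field <- function(state, params, kernel, external_drive, noise_draw, dt) {
  u <- state$u
  n <- length(u)
  if (length(external_drive) == 1) external_drive <- rep(external_drive, n)
  if (length(external_drive) != n) {
    stop("external_drive length does not match field size")
  }
  if (dt > params$tau / 5) {
    stop("dt must be <= tau/5 for stable Euler integration")
  }
  lateral <- if (is.null(kernel)) 0 else drop(kernel %*% gain_function(u, params))
  du <- (-u + params$resting_level + external_drive + lateral) * (dt / params$tau)
  u_new <- u + du + params$noise_sd * sqrt(dt) * noise_draw
  field_state(u_new, state$t + dt)
}

#' Inter-field projection
#'
#' Maps a source field's firing rates onto a drive vector for the target
#' lattice. Topology `"one_to_one"` copies rate-by-rate (requires equal
#' lattice sizes); `"one_to_all"` drives every target neuron with the summed
#' source rate. Inhibitory projections enter with negative sign.
#'
#' @param source Source field id (informational).
#' @param target Target field id (informational).
#' @param topology `"one_to_one"` or `"one_to_all"`.
#' @param sign `"excitatory"` or `"inhibitory"`.
#' @param gain Non-negative gain.
#' @param n_target Target lattice size (needed for `"one_to_all"`).
#' @return An object of class `projection_spec`.
#' @export
projection_spec <- function(source, target,
                            topology = c("one_to_one", "one_to_all"),
                            sign = c("excitatory", "inhibitory"),
                            gain = 1, n_target = NULL) {
  topology <- match.arg(topology)
  sign <- match.arg(sign)
  if (gain < 0) stop("projection gain must be >= 0")
  if (topology == "one_to_all" && is.null(n_target)) {
    stop("one_to_all projection requires n_target")
  }
  structure(
    list(
      source = source, target = target, topology = topology,
      sign = sign, gain = gain, n_target = n_target
    ),
    class = "projection_spec"
  )
}

#' Apply a projection to source firing rates
#'
#' @param source_rates Firing-rate vector of the source field.
#' @param spec A [projection_spec()].
#' @return Drive vector on the target lattice.
#' @export
project <- function(source_rates, spec) {
  s <- if (spec$sign == "inhibitory") -1 else 1
  if (spec$topology == "one_to_one") {
    if (!is.null(spec$n_target) && spec$n_target != length(source_rates)) {
      stop("one_to_one projection requires equal lattice sizes")
    }
    s * spec$gain * source_rates
  } else {
    rep(s * spec$gain * sum(source_rates), spec$n_target)
  }
}

#' Relative desirability of supra-threshold planning neurons
#'
#' Neurons whose planning-field activation exceeds the action initiation
#' threshold are "active"; their activations, normalized to sum to one, are
#' the relative desirability weights of the corresponding reach policies in
#' the policy mixture.
#'
#' @param planning_u Planning-field activation vector.
#' @param initiation_threshold Action initiation threshold (activation units).
#' @return A list with `active_indices` (integer), `weights` (summing to 1
#'   when `M >= 1`) and `M` (number of active policies).
#' @export
normalize_desirability <- function(planning_u, initiation_threshold) {
  active <- which(planning_u > initiation_threshold)
  if (length(active) == 0) {
    return(list(active_indices = integer(0), weights = numeric(0), M = 0L))
  }
  a <- planning_u[active]
  list(active_indices = active, weights = a / sum(a), M = length(active))
}
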