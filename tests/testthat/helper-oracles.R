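# Closed-form solution of the noiseless leaky integrator
# tau du/dt = -u + h + S  from  u(0) = u0.
leaky_integrator_solution <- function(u0, h, S, tau, t) {
  (h + S) + (u0 - (h + S)) * exp(-t / tau)
}

# Independent finite-horizon LQR oracle: batch least squares over the open-
# loop action sequence. Minimizing
#   J = sum_k R u_k^2 + z_N' Qf z_N,  z_N = A^N z0 + sum_k A^(N-1-k) B u_k
# is linear least squares in u; the optimal first action is linear in z0 and
# its coefficient row is the horizon-N first-step feedback gain.
batch_lqr_first_gain <- function(horizon, A, B, R, Qf) {
  n <- nrow(A)
  G <- matrix(0, n, horizon)
  Apow <- diag(n)
  for (k in horizon:1) {     # column k multiplies u_{k}: A^(N-k) B
    G[, k] <- Apow %*% B
    Apow <- A %*% Apow
  }
  M <- Apow                   # A^N after the loop
  H <- R * diag(horizon) + t(G) %*% Qf %*% G
  F <- t(G) %*% Qf %*% M
  sol <- solve(H, F)          # u* = -sol %*% z0
  sol[1, ]                    # first-action gain row (u0 = -gain %*% z0)
}

# Minimum-jerk speed profile evaluated on a dense grid; returns the first
# time (ms) after onset at which speed exceeds 10% of its maximum.
minjerk_rt_oracle <- function(onset, duration, amplitude, grid_ms = 0.01) {
  t <- seq(0, onset + duration, by = grid_ms)
  p <- pmin(pmax((t - onset) / duration, 0), 1)
  speed <- amplitude / (duration / 1000) * 30 * p^2 * (1 - p)^2
  idx <- which(speed > 0.1 * max(speed))[1]
  t[idx] - onset
}

# Per-axis discrete dynamics of the damped point mass, built independently
# from the documented update rule: v' = v + h(F/m - c v); p' = p + h v'.
plant_ab_for_tests <- function(plant) {
  h <- plant$dt / 1000
  A <- rbind(c(1, h * (1 - h * plant$damping)),
             c(0, 1 - h * plant$damping))
  B <- cbind(c(h^2 / plant$mass, h / plant$mass))
  list(A = A, B = B)
}

# Tiny model spec for fast closed-loop tests: identical wiring, fewer noise
# sources untouched; used where full default dynamics are unnecessary.
fast_spec <- function(variant = "ARCH2", ...) {
  model_spec(variant, ...)
}
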