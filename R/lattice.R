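#' Construct a field lattice
#'
#' A lattice of neurons with preferred movement directions. Directional fields
#' (sensory, outcome, cost, planning) use 181 neurons spanning 0--180 degrees
#' at 1 degree spacing; the lattice is non-circular because targets only ever
#' occupy the upper half-plane. Unit-indexed fields with no spatial metric
#' (stop signal, pause) use a plain index lattice.
#'
#' @param n_neurons Number of neurons.
#' @param from,to Range of preferred directions in degrees. For unit-indexed
#'   lattices pass `metric = FALSE` and the preferred values are just indices.
#' @param metric Logical; `FALSE` for fields without a spatial metric.
#' @return An object of class `field_lattice` with elements `n_neurons`,
#'   `preferred_values` (degrees, strictly increasing) and `spacing`.
#' @examples
#' lat <- field_lattice(181, 0, 180)
#' lat$spacing
#' @export
field_lattice <- function(n_neurons, from = 0, to = 180, metric = TRUE) {
  stopifnot(n_neurons >= 2)
  if (metric) {
    preferred <- seq(from, to, length.out = n_neurons)
  } else {
    preferred <- seq_len(n_neurons)
  }
  structure(
    list(
      n_neurons = as.integer(n_neurons),
      preferred_values = preferred,
      spacing = preferred[2] - preferred[1],
      metric = metric
    ),
    class = "field_lattice"
  )
}

#' Specify a lateral interaction kernel
#'
#' Local excitation with surround inhibition, either as a difference of
#' Gaussians (`"mexican_hat"`) or as a Gaussian excitatory part minus a
#' constant global inhibition (`"gaussian_plus_global"`). In the latter form
#' `inh_amplitude` is the global constant and `inh_width` is ignored.
#'
#' @param exc_amplitude,inh_amplitude Non-negative amplitudes (dimensionless).
#' @param exc_width,inh_width Gaussian widths in degrees (> 0).
#' @param form `"mexican_hat"` or `"gaussian_plus_global"`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(exc_amplitude, exc_width,
                        inh_amplitude = 0, inh_width = 1,
                        form = c("mexican_hat", "gaussian_plus_global")) {
  form <- match.arg(form)
  if (exc_width <= 0) stop("exc_width must be > 0")
  if (form == "mexican_hat" && inh_width <= 0) stop("inh_width must be > 0")
  if (exc_amplitude < 0 || inh_amplitude < 0) {
    stop("kernel amplitudes must be >= 0")
  }
  structure(
    list(
      exc_amplitude = exc_amplitude, exc_width = exc_width,
      inh_amplitude = inh_amplitude, inh_width = inh_width,
      form = form
    ),
    class = "kernel_spec"
  )
}

#' Build the interaction-weight table for a lattice
#'
#' `W[i, k] = A_e G(d; w_e) - A_i G(d; w_i)` (mexican hat) or
#' `W[i, k] = A_e G(d; w_e) - A_i` (global inhibition), with
#' `d = |preferred_i - preferred_k|` and `G` a unit-height Gaussian. The
#' table is symmetric and depends only on the direction difference.
#'
#' @param spec A [kernel_spec()].
#' @param lattice A [field_lattice()].
#' @return An `n x n` numeric weight matrix.
#' @export
build_kernel <- function(spec, lattice) {
  stopifnot(inherits(spec, "kernel_spec"), inherits(lattice, "field_lattice"))
  d <- abs(outer(lattice$preferred_values, lattice$preferred_values, "-"))
  exc <- spec$exc_amplitude * exp(-d^2 / (2 * spec$exc_width^2))
  inh <- if (spec$form == "mexican_hat") {
    spec$inh_amplitude * exp(-d^2 / (2 * spec$inh_width^2))
  } else {
    spec$inh_amplitude
  }
  exc - inh
}
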