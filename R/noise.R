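#' Generate correlated white-noise input currents
#'
#' Draws the per-step input currents
#' \eqn{\eta_i = x_{dc} + \sigma(\sqrt{1-c}\,\xi_i + \sqrt{c}\,\xi)},
#' one column per neuron, with \eqn{\xi_i} private and \eqn{\xi} shared
#' standard white-noise terms.  Any two distinct columns have population
#' correlation `c` in their fluctuating parts.  Per-step samples use sd
#' `1/sqrt(dt)` so the integrated variance does not depend on the step size.
#'
#' Uses the current R random-number stream; call [set.seed()] for
#' reproducibility.
#'
#' @param spec A [noise_spec()].
#' @param n_steps Number of time steps (rows).
#' @param dt Time step (s) used for the white-noise discretization.
#' @return Numeric matrix `n_steps x n_neurons`.
#' @examples
#' set.seed(1)
#' eta <- generate_noise(noise_spec(c = 0.5, n_neurons = 2), n_steps = 1000)
#' cor(eta[, 1], eta[, 2])
#' @export
generate_noise <- function(spec, n_steps, dt = 0.001) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$c < 0 || spec$c > 1)
    stop("noise correlation 'c' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(n_steps) || n_steps < 1)
    stop("'n_steps' must be at least 1", call. = FALSE)
  n_steps <- as.integer(n_steps)
  n <- spec$n_neurons
  isd <- 1 / sqrt(dt)
  common <- stats::rnorm(n_steps, sd = isd)
  private <- matrix(stats::rnorm(n_steps * n, sd = isd), n_steps, n)
  spec$x_dc + spec$sigma *
    (sqrt(1 - spec$c) * private + sqrt(spec$c) * common)
}
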