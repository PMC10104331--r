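#' Analytic firing rate of a noisy LIF neuron
#'
#' Mean firing rate of a leaky integrate-and-fire neuron driven by a constant
#' current plus white noise, from the mean first-passage time of the
#' Ornstein-Uhlenbeck membrane process:
#' \deqn{\mu = \left[t_{ref} + \frac{1}{g_L}\int_0^\infty \frac{1}{u}
#'   \left(e^{-u^2 + 2 y_{th} u} - e^{-u^2 + 2 y_r u}\right) du\right]^{-1},}
#' with \eqn{y_{th} = (\theta - w x/g_L)/\bar\sigma},
#' \eqn{y_r = (v_r - w x/g_L)/\bar\sigma} and
#' \eqn{\bar\sigma = \sigma w/\sqrt{g_L}} (the normalizer is
#' \eqn{\sqrt{2\,\mathrm{Var}(v)}} of the free membrane).  The integrand's
#' \eqn{u \to 0} limit, \eqn{2(y_{th} - y_r)}, is handled explicitly.  At
#' `g_L = 1` the arguments reduce to \eqn{(\theta - w x)/(\sigma w)} and
#' \eqn{-w x/(\sigma w)}.
#'
#' The refractory term uses `params$refractory` (the clamp-at-reset
#' refractory adds exactly `t_ref` to every inter-spike interval).  When
#' `dt > 0`, a diffusion continuity correction raises the effective threshold
#' by \eqn{0.5826\,\sigma w \sqrt{dt}} to predict the rate of an
#' Euler-discretized simulation, which misses threshold crossings between
#' grid points (Broadie-Glasserman-Kou barrier correction); `dt = 0` (the
#' default) gives the continuous-time rate.
#'
#' @param params A [lif_params()].
#' @param w Input weight (must satisfy `sigma * w > 0`). Vectorized.
#' @param x_dc Constant (DC) input current.
#' @param sigma Continuous-time noise magnitude (see [noise_spec()]).
#' @param dt Discretization step of the simulation being predicted, or 0 for
#'   the continuous-time rate.
#' @return Firing rate(s) in 1/s; non-negative and finite.
#' @examples
#' analytic_firing_rate(lif_params(), w = 14, x_dc = 2.5)
#' @export
analytic_firing_rate <- function(params, w, x_dc, sigma = 10 * sqrt(0.001),
                                 dt = 0) {
  stopifnot(inherits(params, "lif_params"))
  if (any(sigma * w <= 0))
    stop("'sigma * w' must be positive (noise-driven regime)", call. = FALSE)
  vapply(w, function(wi) {
    sig_w <- sigma * wi
    sbar <- sig_w / sqrt(params$g_L)
    mu_v <- wi * x_dc / params$g_L
    th_eff <- params$theta + if (dt > 0) 0.5826 * sig_w * sqrt(dt) else 0
    y_th <- (th_eff - mu_v) / sbar
    y_r <- (params$v_r - mu_v) / sbar
    I <- siegert_integral(y_th, y_r)
    if (!is.finite(I)) return(0)  # unreachable threshold
    1 / (params$refractory + I / params$g_L)
  }, numeric(1))
}

# int_0^infty (1/u) (exp(-u^2 + 2 a u) - exp(-u^2 + 2 b u)) du, a >= b.
# Equivalent to sqrt(pi) * int_b^a exp(x^2)(1 + erf(x)) dx.
siegert_integral <- function(a, b) {
  if (a > 25) return(Inf)  # exp(a^2) overflows; rate is numerically zero
  f <- function(u) {
    small <- u < 1e-12
    out <- numeric(length(u))
    out[small] <- 2 * (a - b)
    us <- u[!small]
    out[!small] <- (exp(-us^2 + 2 * a * us) - exp(-us^2 + 2 * b * us)) / us
    out
  }
  # integrand peaks near u = max(a, 0); split so integrate() finds it
  cut <- max(a, 0) + 1
  r1 <- tryCatch(stats::integrate(f, 0, cut, rel.tol = 1e-9),
                 error = function(e) NULL)
  r2 <- tryCatch(stats::integrate(f, cut, Inf, rel.tol = 1e-9),
                 error = function(e) NULL)
  if (is.null(r1) || is.null(r2))
    stop("firing-rate quadrature failed to converge (y_th = ", signif(a, 4),
         ", y_r = ", signif(b, 4), ")", call. = FALSE)
  r1$value + r2$value
}

#' Per-window spike probability
#'
#' Probability that a neuron spikes at least once in a window of length
#' `params$T`, under the rare-event (Poisson-window) approximation
#' \eqn{E(H) = 1 - e^{-\mu T}} with \eqn{\mu} from
#' [analytic_firing_rate()].
#'
#' @inheritParams analytic_firing_rate
#' @return Spike probability in \[0, 1\]. Vectorized over `w`.
#' @export
spike_probability <- function(params, w, x_dc, sigma = 10 * sqrt(0.001),
                              dt = 0) {
  mu <- analytic_firing_rate(params, w, x_dc, sigma, dt = dt)
  1 - exp(-mu * params$T)
}

#' Gradient of the spike probability with respect to the input weight
#'
#' Central finite difference of the per-window spike probability
#' \eqn{E(H; w) = 1 - e^{-\mu(w) T}} with respect to `w`, with relative step
#' `rel_step * w` (step-halving agreement and a Monte-Carlo cross-check are
#' part of the test suite).  This is the \eqn{\partial E(H_i)/\partial w_i}
#' factor of the weight update.
#'
#' @inheritParams analytic_firing_rate
#' @param rel_step Relative finite-difference step. Default `1e-3`.
#' @return `d E(H) / d w`, vectorized over `w`.
#' @examples
#' spike_prob_gradient(lif_params(), w = 10, x_dc = 2.5)
#' @export
spike_prob_gradient <- function(params, w, x_dc, sigma = 10 * sqrt(0.001),
                                rel_step = 1e-3, dt = 0) {
  h <- rel_step * abs(w)
  h[h == 0] <- rel_step
  (spike_probability(params, w + h, x_dc, sigma, dt = dt) -
     spike_probability(params, w - h, x_dc, sigma, dt = dt)) / (2 * h)
}

# Memoised smooth interpolant of w -> E(H) over a weight range; used inside
# training loops where evaluating the quadrature every window would dominate
# runtime. Returns a function with a derivative argument.
spike_prob_interpolant <- function(params, x_dc, sigma, w_range = c(0.2, 25),
                                   n_grid = 160, dt = 0) {
  wg <- seq(w_range[1], w_range[2], length.out = n_grid)
  pg <- spike_probability(params, wg, x_dc, sigma, dt = dt)
  sf <- stats::splinefun(wg, pg, method = "monoH.FC")
  function(w, deriv = 0) sf(pmin(pmax(w, w_range[1]), w_range[2]), deriv = deriv)
}
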