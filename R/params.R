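#' Leaky integrate-and-fire parameters
#'
#' Bundles the membrane, synapse and integration constants of the LIF model
#' \deqn{\dot v_i = -g_L v_i + w_i \eta_i(t),}
#' with reset \eqn{v_i \to v_r} when \eqn{v_i \ge \theta}, an absolute
#' refractory period during which \eqn{v} is clamped at \eqn{v_r}, and a
#' synaptic trace \eqn{s_i} that decays with time constant `tau_s` and jumps
#' by `syn_jump` at each spike.  Time is in seconds throughout; `g_L` is in
#' 1/s (membrane time constant `1/g_L`).
#'
#' Simulated runs are segmented into trial windows of length `T`; `T` must be
#' an integer multiple of the Euler step `dt`.
#'
#' @param g_L Leak rate (1/s). Default 50 (20 ms membrane time constant).
#' @param theta Spike threshold (dimensionless voltage). Default 1.
#' @param v_r Reset voltage. Default 0.
#' @param refractory Absolute refractory period (s). Default 0.003.
#' @param dt Euler integration step (s). Default 0.001.
#' @param T Trial window length (s). Default 0.05.
#' @param tau_s Synaptic trace time constant (s). Default 0.02.
#' @param syn_jump Synaptic trace increment per spike. The default 1 gives a
#'   unit-amplitude exponential kernel (stationary mean trace
#'   `rate * tau_s`); set `1/tau_s` for a unit-area kernel (stationary mean
#'   trace equal to the firing rate).
#' @return An object of class `lif_params`.
#' @examples
#' lif_params()
#' @export
lif_params <- function(g_L = 50, theta = 1, v_r = 0, refractory = 0.003,
                       dt = 0.001, T = 0.05, tau_s = 0.02, syn_jump = 1) {
  stopifnot(is.numeric(g_L), length(g_L) == 1L, is.finite(g_L), g_L > 0)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("'T' must be a single positive number", call. = FALSE)
  steps <- T / dt
  if (abs(steps - round(steps)) > 1e-8)
    stop("window length 'T' must be an integer multiple of 'dt'", call. = FALSE)
  if (!is.numeric(tau_s) || tau_s <= 0)
    stop("'tau_s' must be positive", call. = FALSE)
  if (!is.numeric(refractory) || refractory < 0)
    stop("'refractory' must be non-negative", call. = FALSE)
  if (!is.numeric(theta) || !is.numeric(v_r) || theta <= v_r)
    stop("'theta' must exceed 'v_r'", call. = FALSE)
  if (!is.numeric(syn_jump) || syn_jump <= 0)
    stop("'syn_jump' must be positive", call. = FALSE)
  structure(list(g_L = g_L, theta = theta, v_r = v_r, refractory = refractory,
                 dt = dt, T = T, tau_s = tau_s, syn_jump = syn_jump,
                 steps_per_window = as.integer(round(steps)),
                 ref_steps = as.integer(round(refractory / dt))),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat("LIF parameters:\n")
  cat(sprintf("  g_L = %g /s (tau_m = %g ms), theta = %g, v_r = %g\n",
              x$g_L, 1000 / x$g_L, x$theta, x$v_r))
  cat(sprintf("  refractory = %g ms, dt = %g ms, window T = %g ms (%d steps)\n",
              1000 * x$refractory, 1000 * x$dt, 1000 * x$T, x$steps_per_window))
  cat(sprintf("  tau_s = %g ms, syn_jump = %g\n", 1000 * x$tau_s, x$syn_jump))
  invisible(x)
}

#' Input-noise specification
#'
#' Describes the common-versus-private mixture of white-noise inputs.  Each
#' first-layer neuron receives
#' \deqn{\eta_i(t) = x_{dc} + \sigma(\sqrt{1-c}\,\xi_i(t) + \sqrt{c}\,\xi(t)),}
#' where \eqn{\xi_i} are private and \eqn{\xi} a shared unit-variance white
#' noise, so any two neurons' fluctuating inputs have correlation coefficient
#' `c`.  The shared term is what introduces confounding between neurons.
#'
#' `sigma` is the continuous-time noise magnitude (units 1/sqrt(s)): per-step
#' samples are drawn with sd `sigma/sqrt(dt)`, making the integrated variance
#' independent of the step size.  The default 0.3162 corresponds to per-step
#' N(0, 10) samples at a 1 ms step.
#'
#' @param x_dc Common DC input current.
#' @param sigma Noise magnitude (see Details). Default `10 * sqrt(0.001)`.
#' @param c Pairwise noise correlation, in \[0, 1\].
#' @param n_neurons Number of first-layer neurons receiving this input.
#' @param sigma2 Magnitude of the private white noise injected into
#'   second-layer neurons (deep networks only). Default 1.
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec(x_dc = 2.5, c = 0.5, n_neurons = 2)
#' @export
noise_spec <- function(x_dc = 2.5, sigma = 10 * sqrt(0.001), c = 0,
                       n_neurons = 2, sigma2 = 1) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0 || c > 1)
    stop("noise correlation 'c' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0)
    stop("'sigma' must be non-negative", call. = FALSE)
  stopifnot(is.numeric(x_dc), length(x_dc) == 1L, is.finite(x_dc),
            n_neurons >= 1, sigma2 >= 0)
  structure(list(x_dc = x_dc, sigma = sigma, c = c,
                 n_neurons = as.integer(n_neurons), sigma2 = sigma2),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("Noise: x_dc = %g, sigma = %g, c = %g, %d neuron(s)\n",
              x$x_dc, x$sigma, x$c, x$n_neurons))
  invisible(x)
}

#' Network weights
#'
#' Input weights of a one- or two-layer LIF network.  For a single layer,
#' `w1[i]` scales the noisy input of neuron i.  For a two-layer (deep)
#' network, `V` weighs the first-layer synaptic traces into the second layer
#' (`V[j, i]` from neuron i to neuron j) and `w2[j]` scales the total input
#' of second-layer neuron j.
#'
#' @param w1 Numeric vector of first-layer input weights.
#' @param V Optional matrix of first-to-second layer weights
#'   (`n2 x length(w1)`).
#' @param w2 Optional second-layer input weights (length `nrow(V)`);
#'   defaults to ones.
#' @return An object of class `network_weights`.
#' @examples
#' network_weights(c(10, 10))
#' @export
network_weights <- function(w1, V = NULL, w2 = NULL) {
  if (!is.numeric(w1) || length(w1) < 1L || any(!is.finite(w1)))
    stop("'w1' must be a finite numeric vector", call. = FALSE)
  n1 <- length(w1)
  n2 <- 0L
  if (!is.null(V)) {
    V <- as.matrix(V)
    if (ncol(V) != n1 || any(!is.finite(V)))
      stop("'V' must be a finite matrix with one column per first-layer neuron",
           call. = FALSE)
    n2 <- nrow(V)
    if (is.null(w2)) w2 <- rep(1, n2)
    if (length(w2) != n2 || any(!is.finite(w2)))
      stop("'w2' must be finite with one entry per second-layer neuron",
           call. = FALSE)
  } else if (!is.null(w2)) {
    stop("'w2' given without 'V'", call. = FALSE)
  }
  structure(list(w1 = as.numeric(w1), V = V,
                 w2 = if (n2 > 0) as.numeric(w2) else NULL,
                 n1 = n1, n2 = n2, n = n1 + n2),
            class = "network_weights")
}

#' @export
print.network_weights <- function(x, ...) {
  if (x$n2 == 0) {
    cat(sprintf("Network: single layer, %d neuron(s), w1 = %s\n", x$n1,
                paste(signif(x$w1, 4), collapse = ", ")))
  } else {
    cat(sprintf("Network: %d -> %d neurons (two layers)\n", x$n1, x$n2))
  }
  invisible(x)
}

#' Reward specification
#'
#' Defines how the end-of-window synaptic traces determine the scalar trial
#' reward.  Three kinds are supported:
#' \describe{
#'   \item{`"quadratic2"`}{Two-neuron cost
#'     \eqn{R = (a s_1 + b s_2 + b s_2^2 + x_r)^2} with defaults
#'     `a = -30`, `b = 20`, `x_r = -4`.}
#'   \item{`"linear_readout"`}{\eqn{R = |U \cdot s - Y|} over the first
#'     (hidden) layer traces.}
#'   \item{`"deep_readout"`}{\eqn{R = |U \cdot s^{(2)} - Y|} over the second
#'     layer traces.}
#' }
#'
#' @param kind One of `"quadratic2"`, `"linear_readout"`, `"deep_readout"`.
#' @param a,b,x_r Quadratic coefficients (`kind = "quadratic2"`).
#' @param U Readout weight vector (readout kinds).
#' @param Y_target Scalar readout target (readout kinds).
#' @return An object of class `reward_spec`.
#' @examples
#' reward_spec("quadratic2")
#' reward_spec("linear_readout", U = rep(1, 10), Y_target = 0.1)
#' @export
reward_spec <- function(kind = c("quadratic2", "linear_readout", "deep_readout"),
                        a = -30, b = 20, x_r = -4, U = NULL, Y_target = 0.1) {
  kind <- match.arg(kind)
  if (kind == "quadratic2") {
    stopifnot(is.finite(a), is.finite(b), is.finite(x_r))
  } else {
    if (is.null(U) || any(!is.finite(U)))
      stop("readout rewards need a finite weight vector 'U'", call. = FALSE)
    stopifnot(is.finite(Y_target))
  }
  structure(list(kind = kind, a = a, b = b, x_r = x_r,
                 U = if (!is.null(U)) as.numeric(U) else NULL,
                 Y_target = Y_target),
            class = "reward_spec")
}

#' @export
print.reward_spec <- function(x, ...) {
  switch(x$kind,
    quadratic2 = cat(sprintf(
      "Reward: (a s1 + b s2 + b s2^2 + x_r)^2 with a = %g, b = %g, x_r = %g\n",
      x$a, x$b, x$x_r)),
    linear_readout = cat(sprintf(
      "Reward: |U . s - Y| over %d hidden neurons, Y = %g\n",
      length(x$U), x$Y_target)),
    deep_readout = cat(sprintf(
      "Reward: |U . s(2) - Y| over %d output-layer neurons, Y = %g\n",
      length(x$U), x$Y_target)))
  invisible(x)
}
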