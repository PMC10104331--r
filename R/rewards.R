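#' Two-neuron quadratic reward
#'
#' Evaluates \eqn{R = (a s_1 + b s_2 + b s_2^2 + x_r)^2}.  This is a
#' non-negative cost surface whose zero set couples the two neurons' synaptic
#' outputs; training minimizes it.
#'
#' @param s1,s2 End-of-window synaptic traces of neurons 1 and 2 (vectors
#'   allowed).
#' @param spec A [reward_spec()] of kind `"quadratic2"`.
#' @return Numeric vector of rewards, always `>= 0`.
#' @examples
#' reward_quadratic(0, 0, reward_spec("quadratic2"))  # (-4)^2 = 16
#' @export
reward_quadratic <- function(s1, s2, spec = reward_spec("quadratic2")) {
  stopifnot(inherits(spec, "reward_spec"), spec$kind == "quadratic2")
  (spec$a * s1 + spec$b * s2 + spec$b * s2^2 + spec$x_r)^2
}

#' Linear readout reward
#'
#' Evaluates \eqn{R = |U \cdot s - Y|} for a synaptic trace vector `s`.
#'
#' @param s Numeric vector of synaptic traces (one per readout input).
#' @param spec A [reward_spec()] of kind `"linear_readout"` or
#'   `"deep_readout"`.
#' @return Scalar reward, `>= 0`.
#' @examples
#' reward_linear_readout(rep(0, 3), reward_spec("linear_readout",
#'   U = c(1, 2, 3), Y_target = 0.1))
#' @export
reward_linear_readout <- function(s, spec) {
  stopifnot(inherits(spec, "reward_spec"),
            spec$kind %in% c("linear_readout", "deep_readout"))
  if (length(spec$U) != length(s))
    stop("length of 's' does not match the readout weight vector 'U'",
         call. = FALSE)
  abs(sum(spec$U * s) - spec$Y_target)
}

# Evaluate the reward for every window given the S matrix (windows x neurons)
# of a simulated run. n1 = first-layer width (readout layer depends on kind).
eval_reward <- function(spec, S, n1) {
  switch(spec$kind,
    quadratic2 = {
      if (ncol(S) < 2) stop("quadratic2 reward needs two neurons", call. = FALSE)
      reward_quadratic(S[, 1], S[, 2], spec)
    },
    linear_readout = {
      if (length(spec$U) != n1)
        stop("'U' must match the hidden-layer width", call. = FALSE)
      abs(S[, seq_len(n1), drop = FALSE] %*% spec$U - spec$Y_target)[, 1]
    },
    deep_readout = {
      n2 <- ncol(S) - n1
      if (n2 < 1) stop("deep_readout needs a second layer", call. = FALSE)
      if (length(spec$U) != n2)
        stop("'U' must match the second-layer width", call. = FALSE)
      abs(S[, n1 + seq_len(n2), drop = FALSE] %*% spec$U - spec$Y_target)[, 1]
    })
}

#' Reward specification as a function of the trace vector
#'
#' Wraps a [reward_spec()] into a plain function `f(s)` of the full trace
#' vector (all neurons, layers concatenated), e.g. for use with
#' [finite_difference_reward()].
#'
#' @param spec A [reward_spec()].
#' @param n1 First-layer width (needed to locate the readout layer).
#' @return A function mapping a numeric trace vector to a scalar reward.
#' @export
as_reward_fn <- function(spec, n1 = if (spec$kind == "quadratic2") 2L else length(spec$U)) {
  force(spec); force(n1)
  function(s) eval_reward(spec, matrix(s, nrow = 1), n1)
}
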