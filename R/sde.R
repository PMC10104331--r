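#' Observed-dependence estimate of a neuron's effect on reward
#'
#' The naive estimator \eqn{\beta^{OD} = E(R | H = 1) - E(R | H = 0)}: the
#' difference in mean reward between windows in which the neuron spiked and
#' windows in which it did not.  Under correlated (confounded) inputs this
#' conflates the neuron's own causal effect with that of its co-active
#' neighbours; it is the baseline the spiking-discontinuity estimator is
#' compared against.
#'
#' @param trials A `spike_trials` data frame (see [simulate_run()]).
#' @param neuron Neuron index to estimate for.
#' @return The estimate, with attributes `se` (large-sample standard error
#'   from the two group variances), `n1` and `n0` (group sizes).
#' @examples
#' set.seed(1)
#' tr <- simulate_run(lif_params(), noise_spec(c = 0, n_neurons = 2),
#'                    network_weights(c(10, 10)), reward_spec("quadratic2"), 200)
#' observed_dependence(tr, 1)
#' @export
observed_dependence <- function(trials, neuron = 1) {
  d <- trials[trials$neuron == neuron, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for neuron ", neuron, call. = FALSE)
  r1 <- d$R[d$H == 1]
  r0 <- d$R[d$H == 0]
  if (length(r1) == 0 || length(r0) == 0)
    stop("observed dependence undefined: neuron ", neuron,
         " has only H = ", if (length(r1)) 1 else 0, " windows", call. = FALSE)
  est <- mean(r1) - mean(r0)
  se <- sqrt(stats::var(r1) / length(r1) + stats::var(r0) / length(r0))
  structure(est, se = se, n1 = length(r1), n0 = length(r0))
}

#' Fit the spiking-discontinuity estimator (SDE)
#'
#' Estimates the causal effect of one neuron's spiking on the trial reward
#' from the jump in mean reward across its spiking threshold, using only
#' trials whose maximum input drive `Z` fell within a window of half-width
#' `p` around the threshold `theta`.  Within that window, spiking is as good
#' as random, so the jump identifies the causal effect even under confounded
#' (correlated) inputs.
#'
#' Two local models of the reward are available:
#' \describe{
#'   \item{`order = 0` (piecewise constant)}{\eqn{\beta =
#'     E(R\,|\,\theta \le Z < \theta + p) - E(R\,|\,\theta - p < Z < \theta)};
#'     the below-window mean is the baseline \eqn{\gamma}.}
#'   \item{`order = 1` (piecewise linear)}{Ordinary least squares of
#'     \eqn{R = \gamma + \beta H + [\alpha_r H + \alpha_l (1 - H)](Z - \theta)}
#'     on the in-window trials; \eqn{\beta} is the fitted discontinuity at
#'     \eqn{Z = \theta}.  The linear correction tolerates larger windows.}
#' }
#'
#' The window convention is `(theta - p, theta)` below (open) and
#' `[theta, theta + p)` above (closed at `theta`: a trial with `Z = theta`
#' exactly is a spike trial).  With `side = "one_sided"` the above-window is
#' replaced by all spike trials (`Z >= theta`), a variant in which the neuron
#' need not distinguish barely- from well-above-threshold inputs.  With
#' `p = Inf` (and symmetric windows) the fit reduces exactly to
#' [observed_dependence()] for `order = 0`.
#'
#' @param trials A `spike_trials` data frame.
#' @param neuron Neuron index.
#' @param p Window half-width in drive units (same scale as `Z` and
#'   `theta`); `p > 0`, possibly `Inf`.
#' @param theta Spike threshold; defaults to the `theta` attribute of
#'   `trials`.
#' @param order 0 (piecewise constant) or 1 (piecewise linear).
#' @param side `"symmetric"` or `"one_sided"` (see Details).
#' @return An object of class `sde_fit` with components `coefficients`
#'   (`gamma`, `beta`, `alpha_r`, `alpha_l`), `se` (standard error of
#'   `beta`), `n_used`, `n_above`, `n_below`, and the in-window data.
#'   Supports `print()`, `summary()`, `coef()`, `predict()`, `residuals()`
#'   and `plot()`.
#' @examples
#' set.seed(1)
#' tr <- simulate_run(lif_params(), noise_spec(c = 0.5, n_neurons = 2),
#'                    network_weights(c(10, 10)), reward_spec("quadratic2"), 500)
#' fit <- sde_fit(tr, neuron = 1, p = 0.3)
#' coef(fit)
#' @export
sde_fit <- function(trials, neuron = 1, p, theta = NULL,
                    order = 0, side = c("symmetric", "one_sided")) {
  side <- match.arg(side)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0)
    stop("window half-width 'p' must be positive", call. = FALSE)
  if (is.null(theta)) theta <- attr(trials, "theta")
  if (is.null(theta) || is.na(theta))
    stop("'theta' not given and not recorded on the trial table", call. = FALSE)
  if (!order %in% c(0, 1)) stop("'order' must be 0 or 1", call. = FALSE)

  d <- trials[trials$neuron == neuron, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for neuron ", neuron, call. = FALSE)
  below <- d$Z > theta - p & d$Z < theta
  above <- if (side == "one_sided") d$Z >= theta else d$Z >= theta & d$Z < theta + p
  if (!any(above) || !any(below))
    stop("insufficient data: no trials ",
         if (!any(above)) "above" else "below",
         " threshold within the window (neuron ", neuron, ", p = ", p, ")",
         call. = FALSE)
  win <- below | above
  dw <- d[win, , drop = FALSE]

  if (order == 0) {
    r_ab <- dw$R[dw$Z >= theta]
    r_be <- dw$R[dw$Z < theta]
    gamma <- mean(r_be)
    beta <- mean(r_ab) - gamma
    se <- sqrt(stats::var(r_ab) / length(r_ab) + stats::var(r_be) / length(r_be))
    cf <- c(gamma = gamma, beta = beta, alpha_r = 0, alpha_l = 0)
  } else {
    if (nrow(dw) < 4)
      stop("insufficient data: piecewise-linear fit needs at least 4 in-window trials",
           call. = FALSE)
    if (length(unique(dw$H)) < 2)
      stop("insufficient data: both spike and no-spike trials required in window",
           call. = FALSE)
    Xd <- cbind(1, dw$H, dw$H * (dw$Z - theta), (1 - dw$H) * (dw$Z - theta))
    qrx <- qr(Xd, tol = 1e-10)
    if (qrx$rank < 4L)
      stop("design matrix rank deficient in window (rank ", qrx$rank,
           " of 4); widen 'p' or collect more trials", call. = FALSE)
    cf_raw <- qr.coef(qrx, dw$R)
    res <- dw$R - Xd %*% cf_raw
    dof <- nrow(dw) - 4L
    se <- if (dof > 0) {
      s2 <- sum(res^2) / dof
      XtXinv <- solve(crossprod(Xd))
      sqrt(s2 * XtXinv[2, 2])
    } else NA_real_
    cf <- c(gamma = cf_raw[1], beta = cf_raw[2],
            alpha_r = cf_raw[3], alpha_l = cf_raw[4])
  }

  structure(list(coefficients = cf, beta = unname(cf["beta"]), se = se,
                 p = p, theta = theta, order = order, side = side,
                 neuron = neuron, n_used = nrow(dw),
                 n_above = sum(dw$Z >= theta), n_below = sum(dw$Z < theta),
                 data = dw[, c("Z", "H", "R")], call = match.call()),
            class = "sde_fit")
}

#' @export
print.sde_fit <- function(x, ...) {
  cat(sprintf("Spiking discontinuity fit (piecewise %s, %s window)\n",
              if (x$order == 0) "constant" else "linear", x$side))
  cat(sprintf("  neuron %s, p = %g, theta = %g, n = %d (%d above / %d below)\n",
              x$neuron, x$p, x$theta, x$n_used, x$n_above, x$n_below))
  cat(sprintf("  causal effect beta = %.6g (se %.3g)\n", x$beta, x$se))
  invisible(x)
}

#' @export
coef.sde_fit <- function(object, ...) object$coefficients

#' @export
summary.sde_fit <- function(object, ...) {
  cf <- object$coefficients
  out <- data.frame(
    neuron = object$neuron, order = object$order, side = object$side,
    p = object$p, gamma = cf["gamma"], beta = cf["beta"],
    alpha_r = cf["alpha_r"], alpha_l = cf["alpha_l"],
    se = object$se, n_used = object$n_used, row.names = NULL)
  class(out) <- c("summary.sde_fit", "data.frame")
  out
}

#' Predict the local reward model of an SDE fit
#'
#' Evaluates \eqn{\gamma + \beta H + [\alpha_r H + \alpha_l (1-H)](Z-\theta)}
#' at new `(Z, H)` pairs.
#'
#' @param object An `sde_fit`.
#' @param newdata Data frame with columns `Z` and `H`; defaults to the
#'   in-window data of the fit.
#' @param ... Unused.
#' @return Numeric vector of model rewards.
#' @export
predict.sde_fit <- function(object, newdata = object$data, ...) {
  cf <- object$coefficients
  with(newdata,
       cf["gamma"] + cf["beta"] * H +
         (cf["alpha_r"] * H + cf["alpha_l"] * (1 - H)) * (Z - object$theta))
}

#' @export
residuals.sde_fit <- function(object, ...) {
  object$data$R - unname(predict(object))
}

#' Plot an SDE fit
#'
#' Scatter of in-window reward against maximum drive `Z`, with the fitted
#' piecewise reward model and the spiking threshold.
#'
#' @param x An `sde_fit`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.sde_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$Z, d$R, col = ifelse(d$H == 1, "firebrick", "steelblue"),
                 pch = 16, cex = 0.6, xlab = "max drive Z", ylab = "reward R",
                 main = sprintf("neuron %s: beta = %.3g", x$neuron, x$beta), ...)
  graphics::abline(v = x$theta, lty = 2, col = "grey40")
  cf <- x$coefficients
  zb <- seq(min(d$Z), x$theta, length.out = 50)
  za <- seq(x$theta, max(d$Z), length.out = 50)
  graphics::lines(zb, cf["gamma"] + cf["alpha_l"] * (zb - x$theta), lwd = 2,
                  col = "steelblue")
  graphics::lines(za, cf["gamma"] + cf["beta"] + cf["alpha_r"] * (za - x$theta),
                  lwd = 2, col = "firebrick")
  invisible(x)
}

#' Ground-truth causal effects from an unconfounded simulation
#'
#' Runs the same network with the noise correlation forced to zero and a
#' large number of windows, and estimates each neuron's causal effect with
#' the observed-dependence estimator, which is unbiased without confounding.
#' This is the reference against which estimators on confounded runs are
#' scored.
#'
#' @inheritParams simulate_run
#' @param neurons Which neurons to report (default: all first-layer neurons).
#' @return Data frame with columns `neuron`, `beta_true`, `se` (large-sample
#'   standard error, proportional to `1/sqrt(n_windows)`).
#' @export
ground_truth_effect <- function(params, noise, network, reward,
                                n_windows = 20000, neurons = NULL) {
  noise$c <- 0
  tr <- simulate_run(params, noise, network, reward, n_windows)
  if (is.null(neurons)) neurons <- seq_len(network$n1)
  out <- lapply(neurons, function(i) {
    od <- observed_dependence(tr, i)
    data.frame(neuron = i, beta_true = as.numeric(od), se = attr(od, "se"))
  })
  do.call(rbind, out)
}

#' Accuracy metrics for a vector of estimated causal effects
#'
#' @param beta_hat Estimated effects (one per neuron).
#' @param beta_true Reference (ground-truth) effects, same length.
#' @param eps Floor for the per-neuron relative-error denominator.
#' @return A list of class `effect_metrics`: `mse` (mean squared error),
#'   `alignment_deg` (angle between the two vectors, degrees; 0 means the
#'   estimate points exactly along the truth), and `rel_error`
#'   (`|beta_hat - beta_true| / max(|beta_true|, eps)` per neuron).
#' @examples
#' effect_metrics(c(1, 2), c(1, 2))
#' @export
effect_metrics <- function(beta_hat, beta_true, eps = 1e-6) {
  if (length(beta_hat) != length(beta_true))
    stop("'beta_hat' and 'beta_true' must have equal length", call. = FALSE)
  nt <- sqrt(sum(beta_true^2)); nh <- sqrt(sum(beta_hat^2))
  if (nt == 0 || nh == 0)
    stop("alignment undefined for a zero-norm effect vector", call. = FALSE)
  cosang <- sum(beta_hat * beta_true) / (nh * nt)
  structure(list(
    mse = mean((beta_hat - beta_true)^2),
    alignment_deg = acos(pmin(pmax(cosang, -1), 1)) * 180 / pi,
    rel_error = abs(beta_hat - beta_true) / pmax(abs(beta_true), eps)),
    class = "effect_metrics")
}

#' @export
print.effect_metrics <- function(x, ...) {
  cat(sprintf("MSE %.4g | alignment %.2f deg | mean rel. error %.3g\n",
              x$mse, x$alignment_deg, mean(x$rel_error)))
  invisible(x)
}

#' Tabulate SDE and observed-dependence estimates for several neurons
#'
#' Convenience wrapper: fits the requested estimators for each neuron of a
#' trial table and returns one row per (neuron, method).
#'
#' @param trials A `spike_trials` data frame.
#' @param neurons Neuron indices.
#' @param p Window half-width for the SDE fits.
#' @param theta Spike threshold (default: attribute of `trials`).
#' @param methods Subset of `c("od", "sde0", "sde1")`.
#' @return Data frame with columns `neuron`, `method`, `p`, `gamma`, `beta`,
#'   `alpha_l`, `alpha_r`, `n_used`, `se`.  Neurons/methods whose fit fails
#'   (e.g. a neuron that never spikes) are reported with `NA` estimates.
#' @export
estimate_effects <- function(trials, neurons = NULL, p, theta = NULL,
                             methods = c("od", "sde0", "sde1")) {
  if (is.null(theta)) theta <- attr(trials, "theta")
  if (is.null(neurons)) neurons <- sort(unique(trials$neuron))
  rows <- list()
  for (i in neurons) for (m in methods) {
    row <- data.frame(neuron = i, method = m, p = if (m == "od") NA_real_ else p,
                      gamma = NA_real_, beta = NA_real_, alpha_l = NA_real_,
                      alpha_r = NA_real_, n_used = NA_integer_, se = NA_real_)
    res <- tryCatch({
      if (m == "od") {
        od <- observed_dependence(trials, i)
        row$beta <- as.numeric(od); row$se <- attr(od, "se")
        row$n_used <- attr(od, "n1") + attr(od, "n0")
      } else {
        f <- sde_fit(trials, i, p = p, theta = theta,
                     order = if (m == "sde0") 0 else 1)
        cf <- coef(f)
        row$gamma <- cf["gamma"]; row$beta <- cf["beta"]
        row$alpha_l <- cf["alpha_l"]; row$alpha_r <- cf["alpha_r"]
        row$n_used <- f$n_used; row$se <- f$se
      }
      row
    }, error = function(e) row)
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
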