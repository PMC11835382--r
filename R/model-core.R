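# Feed-forward computation and per-spine calcium accounting for the
# calcitron: a perceptron-like neuron with four calcium sources.

#' Construct calcitron neuron parameters
#'
#' Bundles the feed-forward parameters of the calcitron (weights, bias,
#' activation) with the four calcium-source coefficients. The neuron computes
#' `y_hat = g(sum_i w_i x_i + b)` and each dendritic spine accumulates calcium
#' from a local source (`alpha`, per unit presynaptic input), a heterosynaptic
#' source (`beta`, per unit of aggregate weighted input), the backpropagating
#' action potential (`gamma`, per unit output) and a supervisory signal
#' (`delta`, per unit supervisor magnitude).
#'
#' Weights and inputs are restricted to be non-negative (excitatory synapses);
#' inhibition is absorbed into the bias `b`, which is therefore typically
#' non-positive.
#'
#' @param weights numeric vector of non-negative synaptic weights; its length
#'   defines the number of synapses `N`.
#' @param bias scalar bias term `b` (aggregate inhibition; usually <= 0).
#' @param activation `"step"` (spike output in \{0,1\}: fires strictly when the
#'   net input exceeds 0) or `"linear"` (rectified firing rate, `max(u, 0)`).
#' @param alpha,beta,gamma,delta non-negative calcium coefficients for the
#'   local, heterosynaptic, spike-dependent and supervisory sources.
#' @return an object of class `calcitron_params`.
#' @seealso [compute_output()], [compute_calcium()]
#' @export
#' @examples
#' p <- calcitron_params(rep(0.5, 10), bias = -1.8, alpha = 0.4, gamma = 0.45)
#' compute_output(p, c(1, 1, 1, 1, rep(0, 6)))
calcitron_params <- function(weights, bias = 0, activation = c("step", "linear"),
                             alpha = 0, beta = 0, gamma = 0, delta = 0) {
  activation <- match.arg(activation)
  weights <- as.numeric(weights)
  if (length(weights) < 1L) {
    stop("at least one synapse is required")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("synaptic weights must be finite and non-negative")
  }
  coefs <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (any(!is.finite(coefs)) || any(coefs < 0)) {
    stop("calcium coefficients (alpha, beta, gamma, delta) must be finite and non-negative")
  }
  if (!is.finite(bias)) stop("bias must be finite")
  structure(
    list(
      n_synapses = length(weights),
      weights = weights,
      bias = as.numeric(bias),
      activation = activation,
      alpha = as.numeric(alpha),
      beta = as.numeric(beta),
      gamma = as.numeric(gamma),
      delta = as.numeric(delta)
    ),
    class = "calcitron_params"
  )
}

#' @export
print.calcitron_params <- function(x, ...) {
  cat(sprintf(
    "<calcitron_params> N = %d, b = %g, g = %s\n  alpha = %g, beta = %g, gamma = %g, delta = %g\n",
    x$n_synapses, x$bias, x$activation, x$alpha, x$beta, x$gamma, x$delta
  ))
  invisible(x)
}

# shared input validation: length must match N, elements finite and >= 0
check_input <- function(params, x) {
  x <- as.numeric(x)
  if (length(x) != params$n_synapses) {
    stop(sprintf(
      "input length %d does not match the number of synapses N = %d",
      length(x), params$n_synapses
    ))
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("inputs must be finite and non-negative")
  }
  x
}

#' Compute the calcitron's output
#'
#' Applies the transfer function to the weighted sum of inputs plus bias,
#' `y_hat = g(sum_i w_i x_i + b)`. The step activation fires (returns 1)
#' strictly when the net input is above 0; equality does not fire. The linear
#' activation returns the rectified net input `max(u, 0)` (firing rates cannot
#' be negative). The supervisory signal never enters the output: supervision
#' shapes plasticity only.
#'
#' @param params a [calcitron_params()] object.
#' @param x input vector of length `N`, non-negative (binary in the spiking
#'   protocols, real-valued in rate-model use).
#' @return a scalar output: 0/1 for `"step"`, a non-negative rate for
#'   `"linear"`.
#' @export
compute_output <- function(params, x) {
  x <- check_input(params, x)
  u <- sum(params$weights * x) + params$bias
  switch(params$activation,
    step = as.numeric(u > 0),
    linear = max(u, 0)
  )
}

#' Per-spine calcium breakdown
#'
#' Computes the four calcium components and their totals for one timestep:
#' local `alpha * x_i` (weight-independent by construction: plasticity-gating
#' calcium enters through NMDA receptors, not the AMPA conductance that carries
#' the weight), heterosynaptic `beta * sum_j w_j x_j`, spike-dependent
#' `gamma * y_hat`, and supervisory `delta * z`. The three scalar sources sum
#' to a global component broadcast to every spine; total calcium at spine `i`
#' is `local_i + global`.
#'
#' `y_hat` is passed in rather than recomputed so that a single timestep has
#' exactly one forward evaluation; callers must supply the output matching
#' `(params, x)`.
#'
#' @param params a [calcitron_params()] object.
#' @param x input vector of length `N` (non-negative).
#' @param y_hat the output returned by [compute_output()] for this input.
#' @param z supervisor signal magnitude, `>= 0`.
#' @return an object of class `calcium_breakdown` with fields `local`
#'   (length-`N`), scalars `het`, `bap`, `sprv`, `global_`, and the length-`N`
#'   `total`.
#' @export
compute_calcium <- function(params, x, y_hat, z = 0) {
  x <- check_input(params, x)
  if (!is.numeric(y_hat) || length(y_hat) != 1L || !is.finite(y_hat) || y_hat < 0) {
    stop("y_hat must be a single non-negative number")
  }
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z) || z < 0) {
    stop("supervisor signal z must be a single non-negative number")
  }
  local <- params$alpha * x
  het <- params$beta * sum(params$weights * x)
  bap <- params$gamma * y_hat
  sprv <- params$delta * z
  global_ <- het + bap + sprv
  structure(
    list(
      local = local,
      het = het,
      bap = bap,
      sprv = sprv,
      global_ = global_,
      total = local + global_
    ),
    class = "calcium_breakdown"
  )
}

#' @export
print.calcium_breakdown <- function(x, ...) {
  cat(sprintf(
    "<calcium_breakdown> het = %g, bap = %g, sprv = %g (global = %g)\n",
    x$het, x$bap, x$sprv, x$global_
  ))
  cat("  total:", paste(signif(x$total, 4), collapse = " "), "\n")
  invisible(x)
}
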