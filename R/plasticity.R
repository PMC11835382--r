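# Calcium-to-weight-change maps: the linear step rule and the asymptotic
# fixed-point/learning-rate (FPLR) rule, with an optional post-potentiative
# neutral zone (PPNZ).

#' Plasticity thresholds on calcium concentration
#'
#' Defines the calcium regions that gate plasticity. Under the standard
#' (hippocampal/cortical) order `theta_d < theta_p`, calcium below `theta_d`
#' produces no change, calcium in the closed interval `[theta_d, theta_p]`
#' depresses, and calcium above `theta_p` potentiates. Under the reversed
#' (Purkinje-style) order `theta_p < theta_d` the middle region potentiates
#' and the upper region depresses; the middle region is closed at both ends,
#' mirroring the standard convention. The order is inferred from the two
#' values.
#'
#' An optional third threshold `theta_ppnz > max(theta_d, theta_p)` adds a
#' post-potentiative neutral zone: calcium so high that it ceases to induce
#' change (used by the label-supervisor perceptron). It is only supported
#' under the standard order.
#'
#' @param theta_d depression threshold (calcium units, >= 0).
#' @param theta_p potentiation threshold (calcium units, >= 0, different from
#'   `theta_d`).
#' @param theta_ppnz optional post-potentiative neutral-zone threshold.
#' @return an object of class `plasticity_thresholds` with an `order` field
#'   (`"standard"` or `"reversed"`).
#' @export
#' @examples
#' th <- plasticity_thresholds(0.5, 0.8)
#' classify_region(c(0.3, 0.5, 0.7, 0.9), th)
plasticity_thresholds <- function(theta_d, theta_p, theta_ppnz = NULL) {
  if (!is.numeric(theta_d) || !is.numeric(theta_p) ||
      !is.finite(theta_d) || !is.finite(theta_p) ||
      theta_d < 0 || theta_p < 0) {
    stop("theta_d and theta_p must be finite non-negative numbers")
  }
  if (theta_d == theta_p) {
    stop("degenerate thresholds: theta_d and theta_p must differ")
  }
  order <- if (theta_d < theta_p) "standard" else "reversed"
  if (!is.null(theta_ppnz)) {
    if (order != "standard") {
      stop("a post-potentiative neutral zone requires the standard threshold order")
    }
    if (!is.finite(theta_ppnz) || theta_ppnz <= max(theta_d, theta_p)) {
      stop("theta_ppnz must exceed both plasticity thresholds")
    }
    theta_ppnz <- as.numeric(theta_ppnz)
  }
  structure(
    list(
      theta_d = as.numeric(theta_d),
      theta_p = as.numeric(theta_p),
      theta_ppnz = theta_ppnz,
      order = order
    ),
    class = "plasticity_thresholds"
  )
}

#' @export
print.plasticity_thresholds <- function(x, ...) {
  cat(sprintf(
    "<plasticity_thresholds> order = %s, theta_d = %g, theta_p = %g%s\n",
    x$order, x$theta_d, x$theta_p,
    if (is.null(x$theta_ppnz)) "" else sprintf(", theta_ppnz = %g", x$theta_ppnz)
  ))
  invisible(x)
}

#' Classify calcium levels into plasticity regions
#'
#' Maps calcium concentrations to region labels: `"N"` (no change,
#' pre-depressive), `"D"` (depressive), `"P"` (potentiative) and `"PPNZ"`
#' (post-potentiative neutral zone, when a `theta_ppnz` threshold is present).
#' Standard order: `N` for `c < theta_d`, `D` on the closed interval
#' `[theta_d, theta_p]`, `P` for `c > theta_p` (up to and including
#' `theta_ppnz` if set), `PPNZ` strictly above `theta_ppnz`. Reversed order:
#' `N` below `theta_p`, `P` on `[theta_p, theta_d]`, `D` above `theta_d`.
#'
#' @param c numeric vector of non-negative calcium levels.
#' @param thresholds a [plasticity_thresholds()] object.
#' @return character vector of region labels, same length as `c`.
#' @export
classify_region <- function(c, thresholds) {
  stopifnot(inherits(thresholds, "plasticity_thresholds"))
  c <- as.numeric(c)
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("calcium levels must be finite and non-negative")
  }
  th <- thresholds
  out <- character(length(c))
  if (th$order == "standard") {
    out[c < th$theta_d] <- "N"
    out[c >= th$theta_d & c <= th$theta_p] <- "D"
    out[c > th$theta_p] <- "P"
    if (!is.null(th$theta_ppnz)) {
      out[c > th$theta_ppnz] <- "PPNZ"
    }
  } else {
    out[c < th$theta_p] <- "N"
    out[c >= th$theta_p & c <= th$theta_d] <- "P"
    out[c > th$theta_d] <- "D"
  }
  out
}

#' Linear plasticity rule parameters
#'
#' Step-function weight-change rule: depressive calcium subtracts `eta_d`
#' from the weight each timestep, potentiative calcium adds `eta_p`, other
#' regions leave the weight unchanged. Signed values are accepted and
#' normalized to positive magnitudes (some parameter tables bake the minus
#' sign of depression into the rate); the rule itself applies the sign.
#' Nothing in the linear rule bounds the weights.
#'
#' @param eta_d depression step magnitude per timestep (> 0; sign ignored).
#' @param eta_p potentiation step magnitude per timestep (> 0; sign ignored).
#' @return an object of class `linear_rule`.
#' @export
linear_rule <- function(eta_d, eta_p = eta_d) {
  eta_d <- abs(as.numeric(eta_d))
  eta_p <- abs(as.numeric(eta_p))
  if (!is.finite(eta_d) || !is.finite(eta_p) || eta_d <= 0 || eta_p <= 0) {
    stop("eta_d and eta_p must be finite nonzero magnitudes")
  }
  structure(list(eta_d = eta_d, eta_p = eta_p), class = "linear_rule")
}

#' FPLR (fixed-point/learning-rate) rule parameters
#'
#' Each calcium region is assigned a fixed point `F` (the weight value the
#' synapse moves toward) and a rate `eta` in `[0, 1]` (the fraction of the
#' remaining distance traversed per timestep; `eta = 1` jumps to the fixed
#' point in one step). The depressive fixed point `f_d` plays the role of
#' `w_min` and the potentiative fixed point `f_p` of `w_max`. Pre-depressive
#' drift is off by default (`eta_drift = 0`): synapses are stable at low
#' calcium. The PPNZ region defaults to no change (`eta_ppnz = 0`) whatever
#' its nominal fixed point.
#'
#' @param f_d,f_p fixed points of the depressive and potentiative regions
#'   (`w_min`, `w_max`).
#' @param eta_d,eta_p learning rates in `[0, 1]` for those regions.
#' @param f_drift,eta_drift fixed point and rate of the pre-depressive region;
#'   when drift is enabled (`eta_drift > 0`), `f_drift` must lie within
#'   `[w_min, w_max]`.
#' @param f_ppnz,eta_ppnz fixed point and rate of the post-potentiative
#'   neutral zone.
#' @return an object of class `fplr_rule` with convenience fields `w_min` and
#'   `w_max`.
#' @export
fplr_rule <- function(f_d = 0, f_p = 1, eta_d = 0.1, eta_p = eta_d,
                      f_drift = f_d, eta_drift = 0,
                      f_ppnz = f_p, eta_ppnz = 0) {
  rates <- c(eta_d = eta_d, eta_p = eta_p, eta_drift = eta_drift, eta_ppnz = eta_ppnz)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("all FPLR learning rates must lie in [0, 1]")
  }
  pts <- c(f_d = f_d, f_p = f_p, f_drift = f_drift, f_ppnz = f_ppnz)
  if (any(!is.finite(pts))) stop("fixed points must be finite")
  w_min <- min(f_d, f_p)
  w_max <- max(f_d, f_p)
  if (eta_drift > 0 && (f_drift < w_min || f_drift > w_max)) {
    stop("with drift enabled, f_drift must lie within [w_min, w_max]")
  }
  structure(
    list(
      f_d = as.numeric(f_d), eta_d = as.numeric(eta_d),
      f_p = as.numeric(f_p), eta_p = as.numeric(eta_p),
      f_drift = as.numeric(f_drift), eta_drift = as.numeric(eta_drift),
      f_ppnz = as.numeric(f_ppnz), eta_ppnz = as.numeric(eta_ppnz),
      w_min = w_min, w_max = w_max
    ),
    class = "fplr_rule"
  )
}

#' Weight change under the linear rule
#'
#' Returns the signed weight change for each calcium level: `0` in the `N`
#' and `PPNZ` regions, `-eta_d` in the depressive region, `+eta_p` in the
#' potentiative region.
#'
#' @param c numeric vector of non-negative calcium levels.
#' @param thresholds a [plasticity_thresholds()] object.
#' @param lin a [linear_rule()] object.
#' @return numeric vector of signed weight changes.
#' @export
omega_linear <- function(c, thresholds, lin) {
  stopifnot(inherits(lin, "linear_rule"))
  region <- classify_region(c, thresholds)
  step <- c(N = 0, D = -lin$eta_d, P = lin$eta_p, PPNZ = 0)
  unname(step[region])
}

#' One FPLR update step
#'
#' Moves each weight a fraction `eta(region)` of the way toward the region's
#' fixed point: `w' = w + eta * (F - w)`. Weights starting inside the envelope
#' of fixed points can never leave it, and `eta = 1` lands exactly on the
#' fixed point (switch-like, one-shot plasticity).
#'
#' @param w numeric vector of current weights.
#' @param c numeric vector of calcium levels (recycled against `w` only if
#'   scalar).
#' @param thresholds a [plasticity_thresholds()] object.
#' @param fplr an [fplr_rule()] object.
#' @return numeric vector of updated weights.
#' @export
fplr_step <- function(w, c, thresholds, fplr) {
  stopifnot(inherits(fplr, "fplr_rule"))
  w <- as.numeric(w)
  c <- as.numeric(c)
  if (length(c) == 1L) c <- rep(c, length(w))
  if (length(c) != length(w)) {
    stop("weight and calcium vectors must have equal length")
  }
  region <- classify_region(c, thresholds)
  eta <- c(N = fplr$eta_drift, D = fplr$eta_d, P = fplr$eta_p, PPNZ = fplr$eta_ppnz)
  fx <- c(N = fplr$f_drift, D = fplr$f_d, P = fplr$f_p, PPNZ = fplr$f_ppnz)
  w + unname(eta[region]) * (unname(fx[region]) - w)
}

#' Apply a plasticity rule across all synapses
#'
#' Element-wise application of the linear or FPLR rule to a weight vector and
#' its per-synapse total calcium; there is no cross-synapse coupling at this
#' layer (all interaction between synapses happens upstream, through the
#' shared global calcium).
#'
#' @param weights numeric vector of current weights.
#' @param calcium a [compute_calcium()] breakdown (its `total` field is used)
#'   or a numeric vector of per-synapse total calcium.
#' @param thresholds a [plasticity_thresholds()] object.
#' @param rule a [linear_rule()] or [fplr_rule()] object matching `mode`.
#' @param mode `"fplr"` or `"linear"`.
#' @return numeric vector of updated weights.
#' @export
apply_plasticity <- function(weights, calcium, thresholds, rule,
                             mode = c("fplr", "linear")) {
  mode <- match.arg(mode)
  total <- if (inherits(calcium, "calcium_breakdown")) calcium$total else as.numeric(calcium)
  if (length(total) != length(weights)) {
    stop("calcium vector length does not match the number of synapses")
  }
  switch(mode,
    fplr = {
      stopifnot(inherits(rule, "fplr_rule"))
      fplr_step(weights, total, thresholds, rule)
    },
    linear = {
      stopifnot(inherits(rule, "linear_rule"))
      as.numeric(weights) + omega_linear(total, thresholds, rule)
    }
  )
}
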