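# Enumeration and synthesis of the pre/post plasticity rules implementable by
# calcium control. A rule is a 3-letter code over {N, D, P}: the outcome at an
# active synapse without a postsynaptic spike (pre only), at an inactive
# synapse with a spike (post only), and at an active synapse with a spike
# (both). Because the "both" calcium is the *sum* of the pre and post calcium,
# and calcium is non-negative, only some of the 27 codes are reachable.

rule_letters <- c("N", "D", "P")

#' All 27 three-slot rule codes
#'
#' The full combinatoric taxonomy of pre/post rules: three outcomes (N, D, P)
#' for each of the three conditions (pre only, post only, both).
#'
#' @return character vector of the 27 codes, sorted.
#' @export
all_rule_codes <- function() {
  g <- expand.grid(pre = rule_letters, post = rule_letters, both = rule_letters,
                   stringsAsFactors = FALSE)
  sort(paste0(g$pre, g$post, g$both))
}

#' Combinatoric rule counts
#'
#' Sizes of the pre/post rule taxonomy: 3^3 = 27 codes over the three active
#' conditions, and 3^4 = 81 if a fourth "neither pre nor post" slot were
#' allowed (it is not modelled: synapses are assumed stable in the absence of
#' any activity, since zero activity yields zero calcium).
#'
#' @return list with integer fields `three_slot` and `four_slot`.
#' @export
combinatoric_counts <- function() {
  list(three_slot = 27L, four_slot = 81L)
}

# outcome letter for a region label: the PPNZ region induces no change
region_outcome <- function(region) {
  ifelse(region == "PPNZ", "N", region)
}

#' Rule code realised by a coefficient pair
#'
#' In the binary-input/binary-output regime the three conditions produce
#' calcium `alpha` (pre only), `gamma` (post only) and `alpha + gamma` (both).
#' This maps each to its plasticity region and renders the 3-letter code.
#'
#' @param alpha,gamma non-negative local and spike-dependent calcium
#'   coefficients.
#' @param thresholds a [plasticity_thresholds()] object.
#' @return a 3-character rule code such as `"NNP"`.
#' @export
#' @examples
#' th <- plasticity_thresholds(0.5, 0.8)
#' rule_outcomes(0.4, 0.45, th)  # classic "fire together, wire together"
rule_outcomes <- function(alpha, gamma, thresholds) {
  if (!is.finite(alpha) || !is.finite(gamma) || alpha < 0 || gamma < 0) {
    stop("alpha and gamma must be finite and non-negative")
  }
  thresholds <- strip_ppnz(thresholds)
  region <- classify_region(c(alpha, gamma, alpha + gamma), thresholds)
  paste(region_outcome(region), collapse = "")
}

# rule-space analysis is strictly over the two-threshold rule
strip_ppnz <- function(thresholds) {
  stopifnot(inherits(thresholds, "plasticity_thresholds"))
  if (is.null(thresholds$theta_ppnz)) {
    thresholds
  } else {
    plasticity_thresholds(thresholds$theta_d, thresholds$theta_p)
  }
}

# coefficient grid covering [0, 2 * max(threshold)] plus the exact threshold
# values and +/- eps offsets, so open/closed region boundaries are exercised
rule_grid_values <- function(thresholds, grid_resolution = 61L, eps = 1e-9) {
  hi <- 2 * max(thresholds$theta_d, thresholds$theta_p)
  vals <- c(
    seq(0, hi, length.out = grid_resolution),
    thresholds$theta_d, thresholds$theta_d - eps, thresholds$theta_d + eps,
    thresholds$theta_p, thresholds$theta_p - eps, thresholds$theta_p + eps,
    thresholds$theta_d / 2, thresholds$theta_p / 2,
    (thresholds$theta_d + thresholds$theta_p) / 2
  )
  sort(unique(vals[vals >= 0]))
}

#' Enumerate feasible rule codes by grid search
#'
#' Brute-force oracle over the coefficient plane: evaluates [rule_outcomes()]
#' on a dense `(alpha, gamma)` grid (including exact-threshold points and
#' epsilon offsets around them) and returns the set of distinct codes
#' attained.
#'
#' @param thresholds a [plasticity_thresholds()] object (a `theta_ppnz`, if
#'   present, is ignored: rule-space analysis uses the two-threshold rule).
#' @param grid_resolution number of base grid points per axis.
#' @return sorted character vector of feasible rule codes.
#' @export
#' @examples
#' enumerate_feasible_rules(plasticity_thresholds(0.5, 0.8))   # 13 codes
#' enumerate_feasible_rules(plasticity_thresholds(0.5, 1.2))   # 13 codes
enumerate_feasible_rules <- function(thresholds, grid_resolution = 61L) {
  thresholds <- strip_ppnz(thresholds)
  vals <- rule_grid_values(thresholds, grid_resolution)
  n <- length(vals)
  r1 <- region_outcome(classify_region(vals, thresholds))
  sums <- outer(vals, vals, "+")
  rs <- region_outcome(classify_region(as.vector(sums), thresholds))
  codes <- paste0(rep(r1, times = n), rep(r1, each = n), rs)
  sort(unique(codes))
}

# --- exact interval arithmetic over region value-intervals ------------------

# each region's set of attainable coefficient values, with endpoint closedness
region_value_intervals <- function(thresholds) {
  th <- thresholds
  if (th$order == "standard") {
    list(
      N = list(lo = 0, lo_closed = TRUE, hi = th$theta_d, hi_closed = FALSE),
      D = list(lo = th$theta_d, lo_closed = TRUE, hi = th$theta_p, hi_closed = TRUE),
      P = list(lo = th$theta_p, lo_closed = FALSE, hi = Inf, hi_closed = FALSE)
    )
  } else {
    list(
      N = list(lo = 0, lo_closed = TRUE, hi = th$theta_p, hi_closed = FALSE),
      P = list(lo = th$theta_p, lo_closed = TRUE, hi = th$theta_d, hi_closed = TRUE),
      D = list(lo = th$theta_d, lo_closed = FALSE, hi = Inf, hi_closed = FALSE)
    )
  }
}

interval_sum <- function(a, b) {
  list(
    lo = a$lo + b$lo, lo_closed = a$lo_closed && b$lo_closed,
    hi = a$hi + b$hi, hi_closed = is.finite(a$hi + b$hi) && a$hi_closed && b$hi_closed
  )
}

intervals_intersect <- function(a, b) {
  lo <- max(a$lo, b$lo)
  lo_closed <- if (a$lo > b$lo) a$lo_closed else if (b$lo > a$lo) b$lo_closed else a$lo_closed && b$lo_closed
  hi <- min(a$hi, b$hi)
  hi_closed <- if (a$hi < b$hi) a$hi_closed else if (b$hi < a$hi) b$hi_closed else a$hi_closed && b$hi_closed
  lo < hi || (lo == hi && lo_closed && hi_closed)
}

# exact feasible set for one threshold pair, by inequality/interval reasoning
feasible_rules_exact <- function(thresholds) {
  thresholds <- strip_ppnz(thresholds)
  iv <- region_value_intervals(thresholds)
  codes <- character(0)
  for (pre in rule_letters) {
    for (post in rule_letters) {
      s <- interval_sum(iv[[pre]], iv[[post]])
      for (both in rule_letters) {
        if (intervals_intersect(s, iv[[both]])) {
          codes <- c(codes, paste0(pre, post, both))
        }
      }
    }
  }
  sort(unique(codes))
}

# representative thresholds for each scenario; the feasible set only depends
# on the scenario (which side of 2*theta_middle-boundary the pair falls on)
scenario_thresholds <- function(order, scenario) {
  pick <- switch(scenario,
    dep_region_larger = c(0.5, 1.2),   # middle region wider than the lower N region
    predep_region_larger = c(0.5, 0.8),
    boundary = c(0.5, 1.0)
  )
  if (order == "standard") {
    plasticity_thresholds(theta_d = pick[1], theta_p = pick[2])
  } else {
    plasticity_thresholds(theta_d = pick[2], theta_p = pick[1])
  }
}

#' Closed-form feasible rule sets per threshold scenario
#'
#' Analytic (grid-free) feasible sets, derived by interval arithmetic from
#' the constraint that the "both" calcium is the sum of the "pre" and "post"
#' calcium. Two scenarios exist per threshold order, named after the standard
#' order: `"dep_region_larger"` (the middle region is wider than the region
#' below it, `theta_p - theta_d > theta_d`; excludes NNP, admits DDD) and
#' `"predep_region_larger"` (the converse; admits NNP, excludes DDD).
#' `"boundary"` (`theta_p = 2 * theta_d`) behaves like the first scenario
#' because the middle interval is closed. For the reversed order the same
#' names apply with the middle region being potentiative (the excluded codes
#' become NND and PPP). `"union"` pools both scenarios: 14 codes for either
#' order.
#'
#' @param order `"standard"` or `"reversed"` threshold order.
#' @param scenario one of `"union"`, `"dep_region_larger"`,
#'   `"predep_region_larger"`, `"boundary"`.
#' @return sorted character vector of feasible rule codes.
#' @export
feasible_rules_analytic <- function(order = c("standard", "reversed"),
                                    scenario = c("union", "dep_region_larger",
                                                 "predep_region_larger", "boundary")) {
  order <- match.arg(order)
  scenario <- match.arg(scenario)
  if (scenario == "union") {
    sort(unique(c(
      feasible_rules_exact(scenario_thresholds(order, "dep_region_larger")),
      feasible_rules_exact(scenario_thresholds(order, "predep_region_larger"))
    )))
  } else {
    feasible_rules_exact(scenario_thresholds(order, scenario))
  }
}

# scenario label for a concrete threshold pair
threshold_scenario <- function(thresholds) {
  th <- thresholds
  lo <- min(th$theta_d, th$theta_p)
  hi <- max(th$theta_d, th$theta_p)
  if (hi - lo > lo) "dep_region_larger" else if (hi - lo < lo) "predep_region_larger" else "boundary"
}

#' Synthesize a coefficient pair realising a rule code
#'
#' Searches the coefficient plane for a witness `(alpha, gamma)` whose
#' [rule_outcomes()] equals `code`, and returns the grid point maximally
#' distant from all region boundary lines (the verticals `alpha = theta`,
#' horizontals `gamma = theta`, and diagonals `alpha + gamma = theta`).
#' Infeasible codes yield an explicit marker, not an error.
#'
#' @param code a 3-letter rule code over \{N, D, P\}.
#' @param thresholds a [plasticity_thresholds()] object.
#' @param grid_resolution number of base grid points per axis.
#' @return list with fields `code`, `feasible`, `alpha`, `gamma` (NA when
#'   infeasible) and `scenario`.
#' @export
#' @examples
#' synthesize_coefficients("NNP", plasticity_thresholds(0.5, 0.8))
#' synthesize_coefficients("PPN", plasticity_thresholds(0.5, 0.8))$feasible
synthesize_coefficients <- function(code, thresholds, grid_resolution = 121L) {
  if (!is.character(code) || length(code) != 1L || !code %in% all_rule_codes()) {
    stop("code must be one of the 27 three-letter rule codes over {N, D, P}")
  }
  thresholds <- strip_ppnz(thresholds)
  scen <- threshold_scenario(thresholds)
  vals <- rule_grid_values(thresholds, grid_resolution)
  n <- length(vals)
  r1 <- region_outcome(classify_region(vals, thresholds))
  sums <- outer(vals, vals, "+")
  rs <- region_outcome(classify_region(as.vector(sums), thresholds))
  codes <- paste0(rep(r1, times = n), rep(r1, each = n), rs)
  hit <- which(codes == code)
  if (length(hit) == 0L) {
    return(list(code = code, feasible = FALSE, alpha = NA_real_, gamma = NA_real_,
                scenario = scen))
  }
  alpha <- vals[(hit - 1L) %% n + 1L]
  gamma <- vals[(hit - 1L) %/% n + 1L]
  lines_dist <- pmin(
    abs(alpha - thresholds$theta_d), abs(alpha - thresholds$theta_p),
    abs(gamma - thresholds$theta_d), abs(gamma - thresholds$theta_p),
    abs(alpha + gamma - thresholds$theta_d) / sqrt(2),
    abs(alpha + gamma - thresholds$theta_p) / sqrt(2)
  )
  best <- which.max(lines_dist)
  witness <- list(code = code, feasible = TRUE,
                  alpha = alpha[best], gamma = gamma[best], scenario = scen)
  stopifnot(rule_outcomes(witness$alpha, witness$gamma, thresholds) == code)
  witness
}
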