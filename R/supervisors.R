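# Supervisory-signal circuits and per-regime parameter validators. A
# supervisor is a small circuit outside the neuron that injects calcium
# (magnitude Z, entering the spine as delta * Z) based on the neuron's output
# and, for supervised tasks, a target label. Supervision never contributes to
# the neuron's output; it only shapes plasticity.

#' Specify a supervisory circuit
#'
#' Available kinds:
#' * `"none"`: no supervision, Z = 0.
#' * `"schedule"`: an externally imposed time-indexed Z sequence (e.g. plateau
#'   potentials at chosen timesteps for one-shot flip-flop learning).
#' * `"label"`: emits `z_p` whenever the target label is 1 (a "target"
#'   supervisor that simply broadcasts the label).
#' * `"critic"`: compares output to label and emits `z_p` on false negatives
#'   (label 1, no spike) and `z_d` on false positives (spike, label 0);
#'   silent on correct trials.
#' * `"homeostatic_potentiation_only"`: disinhibitory circuit that emits `z_p`
#'   when the output rate falls strictly below the lower target `y_min_star`
#'   (depression is handled internally by spike calcium).
#' * `"homeostatic_dual"`: additionally emits `z_d` when the rate rises
#'   strictly above the upper target `y_max_star`.
#'
#' The target band satisfies `0 <= y_min_star <= y_max_star <= y_max_phys`,
#' where `y_max_phys` is the physically attainable ceiling on the firing rate.
#'
#' @param kind supervisor kind (see above).
#' @param z_p,z_d non-negative potentiation / depression signal magnitudes.
#' @param y_min_star,y_max_star homeostatic target rate band.
#' @param y_max_phys physical ceiling on the firing rate.
#' @param schedule numeric vector of per-timestep Z values (for
#'   `kind = "schedule"`).
#' @return an object of class `supervisor_spec`.
#' @export
supervisor_spec <- function(kind = c("none", "schedule", "label", "critic",
                                     "homeostatic_potentiation_only", "homeostatic_dual"),
                            z_p = 1, z_d = 0,
                            y_min_star = 0, y_max_star = Inf, y_max_phys = Inf,
                            schedule = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(z_p) || z_p < 0 || !is.finite(z_d) || z_d < 0) {
    stop("supervisor magnitudes z_p and z_d must be finite and non-negative")
  }
  if (!(0 <= y_min_star && y_min_star <= y_max_star && y_max_star <= y_max_phys)) {
    stop("target band must satisfy 0 <= y_min_star <= y_max_star <= y_max_phys")
  }
  if (kind == "schedule") {
    if (is.null(schedule)) stop("a schedule supervisor requires a schedule")
    schedule <- as.numeric(schedule)
    if (any(!is.finite(schedule)) || any(schedule < 0)) {
      stop("scheduled Z values must be finite and non-negative")
    }
  }
  structure(
    list(kind = kind, z_p = z_p, z_d = z_d,
         y_min_star = y_min_star, y_max_star = y_max_star,
         y_max_phys = y_max_phys, schedule = schedule),
    class = "supervisor_spec"
  )
}

#' Emit the supervisory signal for one timestep
#'
#' Computes Z from the *same* timestep's output (and label, where relevant).
#' Since Z never affects the output there is no circularity; the resulting
#' calcium determines the weights of the next timestep. Homeostatic
#' comparisons are strict: an output exactly at a band edge draws no
#' supervision.
#'
#' @param spec a [supervisor_spec()] object.
#' @param y_hat the neuron's output this timestep.
#' @param y_target optional binary target label (required for `"label"` and
#'   `"critic"` kinds).
#' @param t timestep index (required for `"schedule"` kind).
#' @return a single non-negative Z value.
#' @export
emit_supervision <- function(spec, y_hat, y_target = NULL, t = NULL) {
  stopifnot(inherits(spec, "supervisor_spec"))
  switch(spec$kind,
    none = 0,
    schedule = {
      if (is.null(t) || t < 1L || t > length(spec$schedule)) {
        stop("schedule supervisor requires a timestep index t within the schedule")
      }
      spec$schedule[[t]]
    },
    label = {
      check_label(y_target)
      if (y_target == 1) spec$z_p else 0
    },
    critic = {
      check_label(y_target)
      if (y_target == 1 && y_hat == 0) {
        spec$z_p
      } else if (y_target == 0 && y_hat == 1) {
        spec$z_d
      } else {
        0
      }
    },
    homeostatic_potentiation_only = {
      if (y_hat < spec$y_min_star) spec$z_p else 0
    },
    homeostatic_dual = {
      if (y_hat < spec$y_min_star) {
        spec$z_p
      } else if (y_hat > spec$y_max_star) {
        spec$z_d
      } else {
        0
      }
    }
  )
}

check_label <- function(y_target) {
  if (is.null(y_target) || is.na(y_target) || !y_target %in% c(0, 1)) {
    stop("this supervisor kind requires a binary target label y_target in {0, 1}")
  }
  invisible(y_target)
}

# --- regime validators ------------------------------------------------------

regime_names <- c(
  "hebbian_nnp", "hebbian_ddp", "antihebb_nnd", "antihebb_ppd",
  "heterosynaptic_unsupervised", "one_shot_flip_flop",
  "homeostatic_global_internalD", "homeostatic_targeted_internalD",
  "homeostatic_global_dual", "homeostatic_targeted_dual",
  "perceptron_label", "perceptron_critic"
)

getp <- function(params, name) {
  v <- params[[name]]
  if (is.null(v) || (length(v) == 1L && is.na(v))) {
    stop(sprintf("regime validation requires parameter '%s'", name))
  }
  v
}

constraint_row <- function(desc, ok, required = TRUE) {
  data.frame(constraint = desc, satisfied = isTRUE(ok), required = required,
             stringsAsFactors = FALSE)
}

#' Validate a parameter bundle against a learning regime's inequalities
#'
#' Each regime that the calcitron can implement comes with a system of
#' inequalities on thresholds, calcium coefficients and supervisor magnitudes
#' (e.g. classic Hebbian "fire together, wire together" requires
#' `alpha < theta_d`, `gamma < theta_d` and `alpha + gamma > theta_p`). This
#' evaluates every inequality of the named regime and reports each
#' separately. For the label-supervisor perceptron, the required constraints
#' are the quadrant-by-quadrant region conditions of the supervised update
#' table; the coarser aggregate inequality `delta*Z_P + gamma > theta_ppnz`
#' is reported as an informational (non-required) row.
#'
#' Two homeostatic conditions are checked non-strictly (`theta_p >=
#' gamma * y_max_phys` and, in the targeted variant, `delta*z_p + alpha >=
#' theta_p`): because the depressive calcium interval is closed at `theta_p`,
#' calcium exactly at the threshold still depresses and never potentiates,
#' and the spike calcium `gamma * y_hat > 0` supplies the strict potentiation
#' margin whenever the neuron fires at all.
#'
#' @param regime one of `"hebbian_nnp"`, `"hebbian_ddp"`, `"antihebb_nnd"`,
#'   `"antihebb_ppd"`, `"heterosynaptic_unsupervised"`,
#'   `"one_shot_flip_flop"`, `"homeostatic_global_internalD"`,
#'   `"homeostatic_targeted_internalD"`, `"homeostatic_global_dual"`,
#'   `"homeostatic_targeted_dual"`, `"perceptron_label"`,
#'   `"perceptron_critic"`.
#' @param params named list (e.g. a [calcitron_config()]) carrying the fields
#'   the regime needs: `theta_d`, `theta_p`, `alpha`, `beta`, `gamma`,
#'   `delta`, and per regime `z`, `z_p`, `z_d`, `theta_ppnz`, `eta_d`,
#'   `eta_p`, `f_d`, `f_p`, `k`, `y_min_star`, `y_max_star`, `y_max_phys`.
#' @return data.frame with columns `constraint`, `satisfied`, `required`.
#'   Overall validity is `all(satisfied[required])` (see [regime_ok()]).
#' @export
validate_regime <- function(regime, params) {
  if (!is.character(regime) || length(regime) != 1L || !regime %in% regime_names) {
    stop(sprintf("unknown regime '%s'", paste(regime, collapse = ",")))
  }
  p <- params
  td <- getp(p, "theta_d"); tp <- getp(p, "theta_p")
  rows <- switch(regime,
    hebbian_nnp = {
      a <- getp(p, "alpha"); g <- getp(p, "gamma")
      rbind(
        constraint_row(sprintf("alpha < theta_d (%g < %g)", a, td), a < td),
        constraint_row(sprintf("gamma < theta_d (%g < %g)", g, td), g < td),
        constraint_row(sprintf("alpha + gamma > theta_p (%g > %g)", a + g, tp), a + g > tp)
      )
    },
    hebbian_ddp = {
      a <- getp(p, "alpha"); g <- getp(p, "gamma")
      rbind(
        constraint_row(sprintf("theta_d <= alpha <= theta_p (%g in [%g, %g])", a, td, tp),
                       a >= td && a <= tp),
        constraint_row(sprintf("theta_d <= gamma <= theta_p (%g in [%g, %g])", g, td, tp),
                       g >= td && g <= tp),
        constraint_row(sprintf("alpha + gamma > theta_p (%g > %g)", a + g, tp), a + g > tp)
      )
    },
    antihebb_nnd = {
      a <- getp(p, "alpha"); g <- getp(p, "gamma")
      rbind(
        constraint_row(sprintf("alpha < theta_d (%g < %g)", a, td), a < td),
        constraint_row(sprintf("gamma < theta_d (%g < %g)", g, td), g < td),
        constraint_row(sprintf("theta_d <= alpha + gamma <= theta_p (%g in [%g, %g])",
                               a + g, td, tp), a + g >= td && a + g <= tp)
      )
    },
    antihebb_ppd = {
      # reversed (Purkinje-style) thresholds: theta_p < theta_d
      a <- getp(p, "alpha"); g <- getp(p, "gamma")
      rbind(
        constraint_row(sprintf("reversed order theta_p < theta_d (%g < %g)", tp, td), tp < td),
        constraint_row(sprintf("theta_p <= alpha <= theta_d (%g in [%g, %g])", a, tp, td),
                       a >= tp && a <= td),
        constraint_row(sprintf("theta_p <= gamma <= theta_d (%g in [%g, %g])", g, tp, td),
                       g >= tp && g <= td),
        constraint_row(sprintf("alpha + gamma > theta_d (%g > %g)", a + g, td), a + g > td)
      )
    },
    heterosynaptic_unsupervised = {
      a <- getp(p, "alpha"); b <- getp(p, "beta"); k <- getp(p, "k")
      wmin <- getp(p, "f_d"); wmax <- getp(p, "f_p")
      rbind(
        constraint_row(sprintf("w_min < w_max (%g < %g)", wmin, wmax), wmin < wmax),
        constraint_row(sprintf("theta_d < beta*k*w_min (%g < %g)", td, b * k * wmin),
                       td < b * k * wmin),
        constraint_row(sprintf("beta*k*w_max < theta_p (%g < %g)", b * k * wmax, tp),
                       b * k * wmax < tp),
        constraint_row(sprintf("beta*k*w_min + alpha > theta_p (%g > %g)",
                               b * k * wmin + a, tp), b * k * wmin + a > tp)
      )
    },
    one_shot_flip_flop = {
      a <- getp(p, "alpha"); d <- getp(p, "delta"); z <- getp(p, "z")
      ed <- getp(p, "eta_d"); ep <- getp(p, "eta_p")
      rbind(
        constraint_row(sprintf("alpha < theta_d (%g < %g)", a, td), a < td),
        constraint_row(sprintf("theta_d < delta*Z < theta_p (%g in (%g, %g))",
                               d * z, td, tp), d * z > td && d * z < tp),
        constraint_row(sprintf("delta*Z + alpha > theta_p (%g > %g)", d * z + a, tp),
                       d * z + a > tp),
        constraint_row(sprintf("eta_d = 1 and eta_p = 1 (switch-like writes; got %g, %g)",
                               ed, ep), ed == 1 && ep == 1)
      )
    },
    homeostatic_global_internalD = {
      a <- getp(p, "alpha"); g <- getp(p, "gamma"); d <- getp(p, "delta")
      zp <- getp(p, "z_p")
      ys <- getp(p, "y_max_star"); ym <- getp(p, "y_max_phys")
      rbind(
        constraint_row(sprintf("alpha = 0 (global strategy; got %g)", a), a == 0),
        constraint_row(sprintf("gamma > theta_d / y_max_star (%g > %g)", g, td / ys),
                       g > td / ys),
        constraint_row(sprintf("theta_p >= gamma * y_max_phys (%g >= %g)", tp, g * ym),
                       tp >= g * ym),
        constraint_row(sprintf("delta*Z_P > theta_p (%g > %g)", d * zp, tp), d * zp > tp)
      )
    },
    homeostatic_targeted_internalD = {
      a <- getp(p, "alpha"); g <- getp(p, "gamma"); d <- getp(p, "delta")
      zp <- getp(p, "z_p")
      ys <- getp(p, "y_max_star"); ym <- getp(p, "y_max_phys")
      rbind(
        constraint_row(sprintf("0 < alpha < theta_d (%g in (0, %g))", a, td),
                       a > 0 && a < td),
        constraint_row(sprintf("gamma > (theta_d - alpha) / y_max_star (%g > %g)",
                               g, (td - a) / ys), g > (td - a) / ys),
        constraint_row(sprintf("theta_p >= gamma * y_max_phys + alpha (%g >= %g)",
                               tp, g * ym + a), tp >= g * ym + a),
        constraint_row(sprintf("delta*Z_P + alpha >= theta_p (%g >= %g)", d * zp + a, tp),
                       d * zp + a >= tp),
        constraint_row(sprintf("delta*Z_P < theta_d (%g < %g)", d * zp, td), d * zp < td)
      )
    },
    homeostatic_global_dual = {
      a <- getp(p, "alpha"); g <- getp(p, "gamma"); d <- getp(p, "delta")
      zp <- getp(p, "z_p"); zd <- getp(p, "z_d")
      rbind(
        constraint_row(sprintf("alpha = 0 (global strategy; got %g)", a), a == 0),
        constraint_row(sprintf("gamma = 0 (supervised depression; got %g)", g), g == 0),
        constraint_row(sprintf("delta*Z_P > theta_p (%g > %g)", d * zp, tp), d * zp > tp),
        constraint_row(sprintf("theta_d < delta*Z_D <= theta_p (%g in (%g, %g])",
                               d * zd, td, tp), d * zd > td && d * zd <= tp)
      )
    },
    homeostatic_targeted_dual = {
      a <- getp(p, "alpha"); g <- getp(p, "gamma"); d <- getp(p, "delta")
      zp <- getp(p, "z_p"); zd <- getp(p, "z_d")
      rbind(
        constraint_row(sprintf("0 < alpha < theta_d (%g in (0, %g))", a, td),
                       a > 0 && a < td),
        constraint_row(sprintf("gamma = 0 (supervised depression; got %g)", g), g == 0),
        constraint_row(sprintf("delta*Z_P + alpha > theta_p (%g > %g)", d * zp + a, tp),
                       d * zp + a > tp),
        constraint_row(sprintf("theta_d < delta*Z_D + alpha <= theta_p (%g in (%g, %g])",
                               d * zd + a, td, tp), d * zd + a > td && d * zd + a <= tp),
        constraint_row(sprintf("Z_D < Z_P < theta_d/delta (%g < %g < %g)", zd, zp, td / d),
                       zd < zp && d * zp < td)
      )
    },
    perceptron_label = {
      a <- getp(p, "alpha"); g <- getp(p, "gamma"); d <- getp(p, "delta")
      zp <- getp(p, "z_p"); tz <- getp(p, "theta_ppnz")
      rbind(
        constraint_row(sprintf("TN, active synapse in N: alpha < theta_d (%g < %g)",
                               a, td), a < td),
        constraint_row(sprintf("FP, active synapse in D: theta_d <= alpha + gamma <= theta_p (%g in [%g, %g])",
                               a + g, td, tp), a + g >= td && a + g <= tp),
        constraint_row(sprintf("FP, inactive synapse in N: gamma < theta_d (%g < %g)",
                               g, td), g < td),
        constraint_row(sprintf("FN, active synapse in P: theta_p < alpha + delta*Z_P <= theta_ppnz (%g in (%g, %g])",
                               a + d * zp, tp, tz), a + d * zp > tp && a + d * zp <= tz),
        constraint_row(sprintf("FN, inactive synapse in N: delta*Z_P < theta_d (%g < %g)",
                               d * zp, td), d * zp < td),
        constraint_row(sprintf("TP, active synapse in PPNZ: alpha + gamma + delta*Z_P > theta_ppnz (%g > %g)",
                               a + g + d * zp, tz), a + g + d * zp > tz),
        constraint_row(sprintf("TP, inactive synapse in N: gamma + delta*Z_P < theta_d (%g < %g)",
                               g + d * zp, td), g + d * zp < td),
        constraint_row(sprintf("[informational] aggregate form delta*Z_P + gamma > theta_ppnz (%g > %g)",
                               d * zp + g, tz), d * zp + g > tz, required = FALSE)
      )
    },
    perceptron_critic = {
      a <- getp(p, "alpha"); d <- getp(p, "delta")
      zp <- getp(p, "z_p"); zd <- getp(p, "z_d")
      rbind(
        constraint_row(sprintf("alpha < theta_d (%g < %g)", a, td), a < td),
        constraint_row(sprintf("delta*Z_P < theta_d (%g < %g)", d * zp, td), d * zp < td),
        constraint_row(sprintf("delta*Z_P + alpha > theta_p (%g > %g)", d * zp + a, tp),
                       d * zp + a > tp),
        constraint_row(sprintf("delta*Z_D < theta_d (%g < %g)", d * zd, td), d * zd < td),
        constraint_row(sprintf("theta_d < delta*Z_D + alpha <= theta_p (%g in (%g, %g])",
                               d * zd + a, td, tp), d * zd + a > td && d * zd + a <= tp)
      )
    }
  )
  rownames(rows) <- NULL
  rows
}

#' Overall pass/fail of a regime validation
#'
#' @param validation the data.frame returned by [validate_regime()].
#' @return TRUE iff every required constraint is satisfied.
#' @export
regime_ok <- function(validation) {
  all(validation$satisfied[validation$required])
}
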