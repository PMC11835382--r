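# Experiment configurations: one flat record bundling neuron parameters,
# plasticity thresholds/rule, supervisor settings and the input-stream spec.
# External YAML files use the conventional column names of simulation
# parameter tables (theta_D, F_D, eta_D, ..., Z_P); internally everything is
# lowercase.

config_key_map <- c(
  theta_D = "theta_d", F_D = "f_d", eta_D = "eta_d",
  theta_P = "theta_p", F_P = "f_p", eta_P = "eta_p",
  theta_PPNZ = "theta_ppnz", eta_PPNZ = "eta_ppnz", F_PPNZ = "f_ppnz",
  F_drift = "f_drift", eta_drift = "eta_drift",
  alpha = "alpha", beta = "beta", gamma = "gamma", delta = "delta",
  b = "b", g = "g", N = "n", Z = "z", Z_P = "z_p", Z_D = "z_d",
  y_min_star = "y_min_star", y_max_star = "y_max_star", y_max_phys = "y_max_phys",
  regime = "regime", mode = "mode", supervisor = "supervisor",
  init_weights = "init_weights", n_timesteps = "n_timesteps",
  seed = "seed", stream = "stream"
)

#' Construct an experiment configuration
#'
#' Bundles everything one simulation needs: plasticity thresholds and rule
#' parameters, calcium coefficients, neuron size/bias/activation, supervisor
#' kind and magnitudes, initial weights, stream specification and seed.
#' Unused calcium coefficients and supervisor magnitudes default to 0;
#' `theta_ppnz` is absent unless given. Signed depression rates are
#' normalized to positive magnitudes (the rule applies the sign).
#'
#' If `regime` names a known learning regime, the parameters are checked
#' against that regime's inequality system via [validate_regime()]
#' (`validate = "warn"` by default).
#'
#' @param regime regime name (see [validate_regime()]) or `"custom"`.
#' @param mode `"fplr"` or `"linear"` plasticity rule.
#' @param g activation kind, `"step"` or `"linear"`.
#' @param n number of synapses.
#' @param b bias (aggregate inhibition; usually <= 0).
#' @param theta_d,theta_p,theta_ppnz calcium thresholds.
#' @param f_d,eta_d,f_p,eta_p,f_drift,eta_drift,f_ppnz,eta_ppnz FPLR fixed
#'   points and rates per calcium region (rates also serve the linear rule).
#' @param alpha,beta,gamma,delta calcium-source coefficients.
#' @param z scheduled supervisor magnitude (for `supervisor = "schedule"`).
#' @param z_p,z_d potentiation/depression supervisor magnitudes.
#' @param supervisor supervisor kind, see [supervisor_spec()].
#' @param y_min_star,y_max_star,y_max_phys homeostatic target band and
#'   physical rate ceiling.
#' @param init_weights initial weights: scalar (recycled), length-`n` vector,
#'   or `NULL` for the midpoint of `[f_d, f_p]`.
#' @param n_timesteps number of timesteps (streams with intrinsic length,
#'   e.g. laps x locations, override this).
#' @param seed integer seed driving all randomness of the experiment.
#' @param stream named list describing the input stream: a `kind` in
#'   `"random_binary"`, `"signal_noise"`, `"circular_track"`, `"even_odd"`,
#'   `"classification"` plus that generator's arguments (see
#'   [build_stream()]).
#' @param validate `"warn"` (default), `"error"` or `"none"` for the regime
#'   inequality check.
#' @return an object of class `calcitron_config`.
#' @export
calcitron_config <- function(regime = "custom",
                             mode = c("fplr", "linear"),
                             g = c("step", "linear"),
                             n = NULL, b = 0,
                             theta_d, theta_p, theta_ppnz = NULL,
                             f_d = 0, eta_d = 0.1, f_p = 1, eta_p = abs(eta_d),
                             f_drift = f_d, eta_drift = 0,
                             f_ppnz = f_p, eta_ppnz = 0,
                             alpha = 0, beta = 0, gamma = 0, delta = 0,
                             z = 1, z_p = 0, z_d = 0,
                             supervisor = "none",
                             y_min_star = 0, y_max_star = Inf, y_max_phys = Inf,
                             init_weights = NULL, n_timesteps = 100, seed = 1,
                             stream = NULL,
                             validate = c("warn", "error", "none")) {
  mode <- match.arg(mode)
  g <- match.arg(g)
  validate <- match.arg(validate)
  eta_d <- abs(eta_d)
  eta_p <- abs(eta_p)
  cfg <- structure(
    list(
      regime = regime, mode = mode, g = g,
      n = if (is.null(n)) NULL else as.integer(n), b = as.numeric(b),
      theta_d = theta_d, theta_p = theta_p, theta_ppnz = theta_ppnz,
      f_d = f_d, eta_d = eta_d, f_p = f_p, eta_p = eta_p,
      f_drift = f_drift, eta_drift = eta_drift,
      f_ppnz = f_ppnz, eta_ppnz = eta_ppnz,
      alpha = alpha, beta = beta, gamma = gamma, delta = delta,
      z = z, z_p = z_p, z_d = z_d,
      supervisor = supervisor,
      # as.numeric so serialized "Inf" strings read back as infinities
      y_min_star = as.numeric(y_min_star), y_max_star = as.numeric(y_max_star),
      y_max_phys = as.numeric(y_max_phys),
      init_weights = if (is.null(init_weights)) NULL else as.numeric(unlist(init_weights)),
      n_timesteps = as.integer(n_timesteps), seed = as.integer(seed),
      stream = stream
    ),
    class = "calcitron_config"
  )
  # eagerly construct thresholds/rule so malformed configs fail at load time
  config_thresholds(cfg)
  config_rule(cfg)
  if (validate != "none" && regime %in% regime_names) {
    v <- validate_regime(regime, config_validation_params(cfg))
    if (!regime_ok(v)) {
      bad <- v$constraint[v$required & !v$satisfied]
      msg <- sprintf("regime '%s' constraints violated: %s",
                     regime, paste(bad, collapse = "; "))
      if (validate == "error") stop(msg) else warning(msg)
    }
  }
  cfg
}

# parameter bundle for validate_regime: config fields plus the stream
# sparsity k, which the heterosynaptic inequality chain needs
config_validation_params <- function(config) {
  p <- unclass(config)
  if (is.list(config$stream) && !is.null(config$stream$k)) p$k <- config$stream$k
  p
}

config_thresholds <- function(config) {
  plasticity_thresholds(config$theta_d, config$theta_p, config$theta_ppnz)
}

config_rule <- function(config) {
  if (config$mode == "fplr") {
    fplr_rule(
      f_d = config$f_d, f_p = config$f_p,
      eta_d = config$eta_d, eta_p = config$eta_p,
      f_drift = config$f_drift, eta_drift = config$eta_drift,
      f_ppnz = config$f_ppnz, eta_ppnz = config$eta_ppnz
    )
  } else {
    linear_rule(config$eta_d, config$eta_p)
  }
}

config_supervisor <- function(config, stream = NULL) {
  if (config$supervisor == "schedule") {
    sched <- if (!is.null(stream) && !is.null(stream$z_schedule)) {
      stream$z_schedule * config$z
    } else {
      rep(0, config$n_timesteps)
    }
    supervisor_spec("schedule", z_p = config$z_p, z_d = config$z_d, schedule = sched)
  } else {
    supervisor_spec(
      config$supervisor, z_p = config$z_p, z_d = config$z_d,
      y_min_star = config$y_min_star, y_max_star = config$y_max_star,
      y_max_phys = config$y_max_phys
    )
  }
}

#' @export
print.calcitron_config <- function(x, ...) {
  cat(sprintf(
    "<calcitron_config> regime = %s, mode = %s, g = %s, N = %s\n",
    x$regime, x$mode, x$g, if (is.null(x$n)) "?" else x$n
  ))
  cat(sprintf(
    "  thresholds: theta_d = %g, theta_p = %g%s\n", x$theta_d, x$theta_p,
    if (is.null(x$theta_ppnz)) "" else sprintf(", theta_ppnz = %g", x$theta_ppnz)
  ))
  cat(sprintf(
    "  coefficients: alpha = %g, beta = %g, gamma = %g, delta = %g; b = %g\n",
    x$alpha, x$beta, x$gamma, x$delta, x$b
  ))
  cat(sprintf("  supervisor: %s (Z = %g, Z_P = %g, Z_D = %g)\n",
              x$supervisor, x$z, x$z_p, x$z_d))
  invisible(x)
}

#' Load an experiment configuration from a YAML file
#'
#' Keys follow the conventional simulation-parameter column names
#' (`theta_D`, `F_D`, `eta_D`, `theta_P`, `F_P`, `eta_P`, `alpha`, `beta`,
#' `gamma`, `delta`, `b`, `g`, `N`, `Z`, `Z_P`, `Z_D`, `eta_PPNZ`,
#' `F_PPNZ`, `theta_PPNZ`) plus `regime`, `mode`, `supervisor`,
#' `init_weights`, `n_timesteps`, `seed`, `stream`, and the homeostatic band
#' keys. Unknown keys are rejected with a message naming them; missing
#' required keys (`theta_D`, `theta_P`) are reported by name. A signed
#' `eta_D` is normalized to its magnitude.
#'
#' @param path path to a YAML config file, or the bare name of a packaged
#'   example config (see `list_example_configs()`).
#' @param validate regime-validation behaviour, as in [calcitron_config()].
#' @return a [calcitron_config()] object.
#' @export
#' @examples
#' cfg <- load_config("hebbian_nnp")
#' cfg$alpha
load_config <- function(path, validate = c("warn", "error", "none")) {
  validate <- match.arg(validate)
  if (!file.exists(path)) {
    pkg_path <- system.file("configs", paste0(path, ".yaml"), package = "calcitron")
    if (nzchar(pkg_path)) path <- pkg_path
  }
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !is.list(raw)) stop("config file is empty or not a mapping")
  # YAML 1.1 parses a bare key `N` as boolean false; map it back
  names(raw)[names(raw) == "FALSE"] <- "N"
  unknown <- setdiff(names(raw), names(config_key_map))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (req in c("theta_D", "theta_P")) {
    if (is.null(raw[[req]])) stop(sprintf("config is missing required key '%s'", req))
  }
  names(raw) <- config_key_map[names(raw)]
  raw$validate <- validate
  do.call(calcitron_config, raw)
}

#' List the packaged example configurations
#'
#' One config per simulation-parameter row, named by regime.
#'
#' @return character vector of config names usable with [load_config()].
#' @export
list_example_configs <- function() {
  files <- list.files(system.file("configs", package = "calcitron"),
                      pattern = "\\.yaml$")
  sort(sub("\\.yaml$", "", files))
}

#' Write a configuration back to YAML
#'
#' Inverse of [load_config()]: load -> dump -> load is the identity.
#'
#' @param config a [calcitron_config()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "calcitron_config"))
  rev_map <- stats::setNames(names(config_key_map), config_key_map)
  out <- list()
  for (internal in names(config)) {
    v <- config[[internal]]
    if (is.null(v)) next
    out[[rev_map[[internal]]]] <- v
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
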