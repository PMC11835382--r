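# Seeded pattern generators and end-to-end experiment runners. The
# generators double as the synthetic-fixture factory for the test suite:
# every stream is a deterministic function of its arguments and seed.

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(expr)
}

#' Construct a pattern stream
#'
#' A time-indexed sequence of input vectors with optional per-step metadata:
#' pattern identity, binary target labels, a supervisory-signal schedule and
#' epoch indices. The generators below build these; construct one directly
#' for custom protocols.
#'
#' @param x numeric matrix, one row per timestep, one column per synapse.
#' @param pattern_id per-step pattern identifier (defaults to the step
#'   index).
#' @param label optional per-step binary target label.
#' @param z_schedule optional per-step supervisory-signal indicator/magnitude.
#' @param epoch optional per-step epoch index.
#' @param ... extra named fields kept on the stream (e.g. the signal pattern).
#' @return an object of class `pattern_stream`.
#' @export
pattern_stream <- function(x, pattern_id = NULL, label = NULL,
                           z_schedule = NULL, epoch = NULL, ...) {
  x <- as.matrix(x)
  if (any(!is.finite(x)) || any(x < 0)) stop("stream inputs must be finite and non-negative")
  n_steps <- nrow(x)
  for (v in list(pattern_id, label, z_schedule, epoch)) {
    if (!is.null(v) && length(v) != n_steps) {
      stop("stream metadata length must equal the number of timesteps")
    }
  }
  structure(
    c(
      list(
        x = unname(x), n_steps = n_steps, n_synapses = ncol(x),
        pattern_id = pattern_id %||% seq_len(n_steps),
        label = label, z_schedule = z_schedule, epoch = epoch
      ),
      list(...)
    ),
    class = "pattern_stream"
  )
}

#' @export
print.pattern_stream <- function(x, ...) {
  cat(sprintf("<pattern_stream> %d timesteps x %d synapses\n", x$n_steps, x$n_synapses))
  invisible(x)
}

#' Random binary pattern stream
#'
#' Independent Bernoulli activity per synapse per step: the unstructured
#' input ensemble used to demonstrate the Hebbian/anti-Hebbian regimes.
#'
#' @param n number of synapses.
#' @param t_steps number of timesteps.
#' @param p_active per-synapse activation probability.
#' @param seed integer seed.
#' @return a [pattern_stream()].
#' @export
gen_random_binary <- function(n = 10, t_steps = 100, p_active = 0.5, seed) {
  stopifnot(n >= 1, t_steps >= 1, p_active >= 0, p_active <= 1)
  x <- with_seed(seed, matrix(stats::rbinom(t_steps * n, 1, p_active),
                              nrow = t_steps, ncol = n))
  pattern_stream(x)
}

subset_key <- function(idx) paste(sort(idx), collapse = ",")

# a fresh k-of-n pattern distinct from everything in `used` (a set of keys)
draw_distinct_pattern <- function(n, k, used, max_tries = 5000L) {
  for (i in seq_len(max_tries)) {
    idx <- sort(sample.int(n, k))
    if (!(subset_key(idx) %in% used)) return(idx)
  }
  stop(sprintf("could not draw a new distinct %d-of-%d pattern; too few remain", k, n))
}

#' Signal-plus-noise stream for unsupervised pattern recognition
#'
#' One fixed "signal" pattern of `k` active synapses is presented with
#' probability `p_signal` per step; other steps present non-repeating random
#' "noise" patterns of the same sparsity, all pairwise distinct and distinct
#' from the signal. `label` is 1 on signal steps. The signal's active-synapse
#' indices are kept on the stream as `signal_synapses`.
#'
#' @param n number of synapses.
#' @param k active synapses per pattern (fixed sparsity).
#' @param t_steps number of timesteps.
#' @param p_signal probability that a step presents the signal pattern.
#' @param seed integer seed.
#' @return a [pattern_stream()] with `label`, `pattern_id` in
#'   \{"signal", "noise"\} and `signal_synapses`.
#' @export
gen_signal_noise <- function(n = 12, k = 4, t_steps = 300, p_signal = 0.5, seed) {
  stopifnot(k >= 1, k <= n, t_steps >= 1, p_signal >= 0, p_signal <= 1)
  with_seed(seed, {
    signal <- sort(sample.int(n, k))
    is_signal <- stats::runif(t_steps) < p_signal
    used <- subset_key(signal)
    x <- matrix(0, t_steps, n)
    for (t in seq_len(t_steps)) {
      if (is_signal[t]) {
        x[t, signal] <- 1
      } else {
        idx <- draw_distinct_pattern(n, k, used)
        used <- c(used, subset_key(idx))
        x[t, idx] <- 1
      }
    }
    pattern_stream(
      x,
      pattern_id = ifelse(is_signal, "signal", "noise"),
      label = as.numeric(is_signal),
      signal_synapses = signal
    )
  })
}

#' Circular-track stream for one-shot place-field learning
#'
#' A repeated sequence of `n_locations` distinct binary patterns (locations
#' on a circular track traversed once per timestep) over `n_laps` laps, plus
#' a sparse supervisory schedule: `n_supervised` plateau events at randomly
#' chosen steps separated by at least `min_gap` steps and leaving room for a
#' full lap afterwards. Patterns are pairwise distinct with overlap at most
#' `max_overlap` active synapses, so that a stored pattern's competitors stay
#' below the spike threshold.
#'
#' @param n number of synapses.
#' @param n_locations number of track locations (distinct patterns).
#' @param k active synapses per location pattern.
#' @param n_laps number of laps.
#' @param n_supervised number of supervisory plateau events.
#' @param min_gap minimum spacing between plateau events, in steps.
#' @param max_overlap maximum pairwise overlap between location patterns.
#' @param seed integer seed.
#' @return a [pattern_stream()] with `z_schedule` (0/1), `pattern_id` (the
#'   location), `n_locations` and the `patterns` matrix.
#' @export
gen_circular_track <- function(n = 14, n_locations = 4, k = 7, n_laps = 30,
                               n_supervised = 4, min_gap = 2 * n_locations,
                               max_overlap = k - 1, seed) {
  stopifnot(k >= 1, k <= n, n_locations >= 2, n_laps >= 2, n_supervised >= 1)
  with_seed(seed, {
    patterns <- matrix(0, n_locations, n)
    used <- character(0)
    for (l in seq_len(n_locations)) {
      for (tries in seq_len(5000L)) {
        idx <- sort(sample.int(n, k))
        ok <- !(subset_key(idx) %in% used)
        if (ok && l > 1L) {
          overlaps <- patterns[seq_len(l - 1L), , drop = FALSE] %*% replace(numeric(n), idx, 1)
          ok <- all(overlaps <= max_overlap)
        }
        if (ok) break
        if (tries == 5000L) stop("could not place distinct low-overlap track patterns")
      }
      used <- c(used, subset_key(idx))
      patterns[l, idx] <- 1
    }
    t_steps <- n_laps * n_locations
    location <- rep(seq_len(n_locations), n_laps)
    x <- patterns[location, , drop = FALSE]
    # supervised steps: spaced, and each followed by at least one clean lap
    latest <- t_steps - n_locations
    if (latest < n_supervised) stop("too few timesteps for the requested supervision events")
    sup <- NULL
    for (tries in seq_len(10000L)) {
      cand <- sort(sample.int(latest, n_supervised))
      if (n_supervised == 1L || all(diff(cand) >= min_gap)) {
        sup <- cand
        break
      }
    }
    if (is.null(sup)) stop("could not place supervision events with the requested spacing")
    z_schedule <- replace(numeric(t_steps), sup, 1)
    pattern_stream(
      x,
      pattern_id = location, z_schedule = z_schedule,
      n_locations = n_locations, patterns = patterns
    )
  })
}

#' Even/odd alternating-pattern stream for homeostasis
#'
#' Each step presents, in uniform random order, one of two fixed patterns:
#' all even-indexed synapses active, or all odd-indexed synapses active
#' (exactly `n/2` active synapses either way). Used with even synapses
#' initialized weak and odd synapses strong, so the two patterns initially
#' drive the output below and above the homeostatic target band.
#'
#' @param n number of synapses (even).
#' @param t_steps number of timesteps.
#' @param seed integer seed.
#' @return a [pattern_stream()] with `pattern_id` in \{"even", "odd"\}.
#' @export
gen_even_odd <- function(n = 20, t_steps = 400, seed) {
  stopifnot(n >= 2, n %% 2 == 0, t_steps >= 1)
  with_seed(seed, {
    which_pat <- sample(c("even", "odd"), t_steps, replace = TRUE)
    even_pat <- replace(numeric(n), seq(2L, n, by = 2L), 1)
    odd_pat <- replace(numeric(n), seq(1L, n, by = 2L), 1)
    x <- t(vapply(which_pat, function(p) if (p == "even") even_pat else odd_pat,
                  numeric(n)))
    pattern_stream(x, pattern_id = which_pat)
  })
}

#' Labelled classification stream for perceptron learning
#'
#' `n_patterns` pairwise-distinct binary patterns of `k` active synapses
#' each; a `positive_fraction` of them is assigned label 1, the rest 0. The
#' patterns are presented in fresh random order within each epoch.
#'
#' @param n number of synapses.
#' @param n_patterns number of distinct patterns.
#' @param k active synapses per pattern.
#' @param positive_fraction fraction of patterns labelled 1.
#' @param epochs number of presentation epochs.
#' @param seed integer seed.
#' @return a [pattern_stream()] with `label`, `epoch`, `pattern_id`,
#'   `patterns` and `pattern_labels`.
#' @export
gen_classification <- function(n = 24, n_patterns = 6, k = 8,
                               positive_fraction = 0.5, epochs = 100, seed) {
  stopifnot(k >= 1, k <= n, n_patterns >= 2, epochs >= 1)
  n_pos <- round(n_patterns * positive_fraction)
  with_seed(seed, {
    patterns <- matrix(0, n_patterns, n)
    used <- character(0)
    for (m in seq_len(n_patterns)) {
      idx <- draw_distinct_pattern(n, k, used)
      used <- c(used, subset_key(idx))
      patterns[m, idx] <- 1
    }
    pattern_labels <- sample(c(rep(1, n_pos), rep(0, n_patterns - n_pos)))
    order_all <- as.vector(vapply(seq_len(epochs),
                                  function(e) sample.int(n_patterns),
                                  integer(n_patterns)))
    pattern_stream(
      patterns[order_all, , drop = FALSE],
      pattern_id = order_all,
      label = pattern_labels[order_all],
      epoch = rep(seq_len(epochs), each = n_patterns),
      patterns = patterns, pattern_labels = pattern_labels
    )
  })
}

#' Build the stream described by a configuration
#'
#' Dispatches on `config$stream$kind` to the matching generator, filling in
#' the synapse count, timestep count and seed from the configuration.
#'
#' @param config a [calcitron_config()] whose `stream` field names a
#'   generator kind and its arguments.
#' @return a [pattern_stream()].
#' @export
build_stream <- function(config) {
  s <- config$stream
  if (is.null(s) || is.null(s$kind)) {
    stop("this configuration carries no stream specification")
  }
  n <- config$n %||% stop("config must set N to build a stream")
  switch(s$kind,
    random_binary = gen_random_binary(
      n = n, t_steps = s$t_steps %||% config$n_timesteps,
      p_active = s$p_active %||% 0.5, seed = config$seed
    ),
    signal_noise = gen_signal_noise(
      n = n, k = s$k %||% stop("signal_noise stream requires k"),
      t_steps = s$t_steps %||% config$n_timesteps,
      p_signal = s$p_signal %||% 0.5, seed = config$seed
    ),
    circular_track = gen_circular_track(
      n = n, n_locations = s$n_locations %||% 4,
      k = s$k %||% stop("circular_track stream requires k"),
      n_laps = s$n_laps %||% 30, n_supervised = s$n_supervised %||% 4,
      min_gap = s$min_gap %||% (2 * (s$n_locations %||% 4)),
      seed = config$seed
    ),
    even_odd = gen_even_odd(
      n = n, t_steps = s$t_steps %||% config$n_timesteps, seed = config$seed
    ),
    classification = gen_classification(
      n = n, n_patterns = s$n_patterns %||% 6,
      k = s$k %||% stop("classification stream requires k"),
      positive_fraction = s$positive_fraction %||% 0.5,
      epochs = s$epochs %||% 100, seed = config$seed
    ),
    stop(sprintf("unknown stream kind '%s'", s$kind))
  )
}

# one simulation step given prebuilt components; the evaluation order is
# output -> supervision -> calcium -> plasticity
step_core <- function(w, x, config, thresholds, rule, sup, y_target = NULL,
                      z_scheduled = NULL, t = NULL) {
  params <- calcitron_params(
    w, bias = config$b, activation = config$g,
    alpha = config$alpha, beta = config$beta,
    gamma = config$gamma, delta = config$delta
  )
  y_hat <- compute_output(params, x)
  z <- if (config$supervisor == "schedule") {
    (z_scheduled %||% 0) * config$z
  } else {
    emit_supervision(sup, y_hat = y_hat, y_target = y_target, t = t)
  }
  ca <- compute_calcium(params, x, y_hat, z)
  region <- classify_region(ca$total, thresholds)
  w_new <- apply_plasticity(w, ca, thresholds, rule, mode = config$mode)
  list(y_hat = y_hat, z = z, calcium = ca, region = region, weights = w_new)
}

#' Run a single calcitron timestep
#'
#' Executes one step in the canonical order: compute the output, emit the
#' supervisory signal, accumulate calcium, apply plasticity. The returned
#' weights take effect at the next timestep.
#'
#' @param weights current weight vector.
#' @param x input vector for this step.
#' @param config a [calcitron_config()].
#' @param y_target optional binary label (supervised regimes).
#' @param z_scheduled optional scheduled supervision indicator for this step
#'   (multiplied by the config's `Z` magnitude).
#' @return list with `y_hat`, `z`, `calcium` (a breakdown), `region`
#'   (per-synapse labels) and the updated `weights`.
#' @export
run_timestep <- function(weights, x, config, y_target = NULL, z_scheduled = NULL) {
  stopifnot(inherits(config, "calcitron_config"))
  thresholds <- config_thresholds(config)
  rule <- config_rule(config)
  sup <- config_supervisor(config)
  step_core(weights, x, config, thresholds, rule, sup,
            y_target = y_target, z_scheduled = z_scheduled, t = 1L)
}

initial_weights <- function(config, n) {
  w0 <- config$init_weights
  if (is.null(w0)) {
    rep((config$f_d + config$f_p) / 2, n)
  } else if (length(w0) == 1L) {
    rep(w0, n)
  } else if (length(w0) == n) {
    as.numeric(w0)
  } else {
    stop(sprintf("init_weights has length %d but N = %d", length(w0), n))
  }
}

#' Run a full experiment
#'
#' Presents every pattern of the stream to the calcitron, recording the
#' output, supervisory signal, per-synapse calcium, plasticity region and
#' post-update weights at every timestep. Deterministic given the
#' configuration and stream.
#'
#' @param config a [calcitron_config()].
#' @param stream a [pattern_stream()]; built from `config$stream` when
#'   omitted.
#' @return an object of class `calcitron_trace`: the config echo, a `steps`
#'   data.frame (`t`, `pattern_id`, `label`, `epoch`, `y_hat`, `spike`, `z`),
#'   matrices `x`, `calcium`, `region`, `weights` (all timesteps-by-synapses;
#'   weights are post-update), and the initial weights `w_init`.
#' @export
#' @examples
#' trace <- run_experiment(load_config("hebbian_nnp"))
#' head(trace$steps)
run_experiment <- function(config, stream = NULL) {
  stopifnot(inherits(config, "calcitron_config"))
  if (is.null(stream)) stream <- build_stream(config)
  stopifnot(inherits(stream, "pattern_stream"))
  n <- stream$n_synapses
  if (!is.null(config$n) && config$n != n) {
    stop(sprintf("stream width %d does not match config N = %d", n, config$n))
  }
  t_steps <- stream$n_steps
  thresholds <- config_thresholds(config)
  rule <- config_rule(config)
  sup <- config_supervisor(config, stream)
  w <- initial_weights(config, n)
  y_hat <- numeric(t_steps)
  z <- numeric(t_steps)
  calcium <- matrix(NA_real_, t_steps, n)
  region <- matrix(NA_character_, t_steps, n)
  weights <- matrix(NA_real_, t_steps, n)
  w_init <- w
  for (t in seq_len(t_steps)) {
    st <- step_core(
      w, stream$x[t, ], config, thresholds, rule, sup,
      y_target = if (is.null(stream$label)) NULL else stream$label[t],
      z_scheduled = if (is.null(stream$z_schedule)) NULL else stream$z_schedule[t],
      t = t
    )
    y_hat[t] <- st$y_hat
    z[t] <- st$z
    calcium[t, ] <- st$calcium$total
    region[t, ] <- st$region
    weights[t, ] <- st$weights
    w <- st$weights
  }
  steps <- data.frame(
    t = seq_len(t_steps),
    pattern_id = stream$pattern_id,
    label = stream$label %||% NA_real_,
    epoch = stream$epoch %||% NA_integer_,
    y_hat = y_hat,
    spike = as.integer(y_hat > 0),
    z = z,
    stringsAsFactors = FALSE
  )
  structure(
    list(config = config, steps = steps, x = stream$x, calcium = calcium,
         region = region, weights = weights, w_init = w_init,
         stream_info = stream[setdiff(names(stream), c("x", "pattern_id", "label",
                                                       "z_schedule", "epoch"))]),
    class = "calcitron_trace"
  )
}

#' @export
print.calcitron_trace <- function(x, ...) {
  cat(sprintf(
    "<calcitron_trace> regime = %s: %d timesteps x %d synapses, spike rate %.2f\n",
    x$config$regime, nrow(x$steps), ncol(x$weights), mean(x$steps$spike)
  ))
  invisible(x)
}

#' Phase plane of plasticity outcomes over pre/post firing rates
#'
#' In a rate model the calcium at an active synapse is
#' `alpha * x + gamma * y`; this classifies that calcium over a grid of
#' presynaptic rates `x` and postsynaptic rates `y`. With `gamma = 0` the
#' region boundaries are vertical lines at `x = theta / alpha`; with
#' `alpha = 0` they are horizontal.
#'
#' @param alpha,gamma non-negative rate coefficients, not both zero.
#' @param thresholds a [plasticity_thresholds()] object.
#' @param x_grid,y_grid non-negative rate grids.
#' @return character matrix of region labels, rows indexed by `x_grid`,
#'   columns by `y_grid`.
#' @export
phase_plane <- function(alpha, gamma, thresholds,
                        x_grid = seq(0, 10, length.out = 101),
                        y_grid = seq(0, 10, length.out = 101)) {
  if (alpha < 0 || gamma < 0) stop("alpha and gamma must be non-negative")
  if (alpha == 0 && gamma == 0) stop("degenerate phase plane: alpha and gamma are both 0")
  if (any(x_grid < 0) || any(y_grid < 0)) stop("rate grids must be non-negative")
  ca <- outer(alpha * x_grid, gamma * y_grid, "+")
  out <- matrix(classify_region(as.vector(ca), thresholds),
                nrow = length(x_grid), ncol = length(y_grid),
                dimnames = list(x = signif(x_grid, 8), y = signif(y_grid, 8)))
  out
}

#' Summarize a trace for a given protocol family
#'
#' Pure functions of a recorded trace:
#' * `"signal_noise"`: per-step spike/should-spike correctness, its mean over
#'   an early and a late window, and the final mean weight of signal vs noise
#'   synapses.
#' * `"classification"`: per-epoch error counts and the first epoch from
#'   which every later epoch is error-free.
#' * `"homeostatic"`: minimum, maximum and in-band fraction of the output
#'   over the final window, against the config's target band.
#' * `"place_field"`: for each supervisory plateau, whether the next lap
#'   spikes at the supervised location and nowhere else (events whose
#'   following lap contains another plateau are skipped).
#' * `"generic"`: spike rate, mean output and final weights.
#'
#' @param trace a [run_experiment()] trace.
#' @param regime summary family (see above).
#' @param window window length in steps for the windowed summaries
#'   (default: 20 for `"homeostatic"`, a quarter of the run capped at 50
#'   for `"signal_noise"`).
#' @return a named list of summary quantities.
#' @export
summarize_trace <- function(trace,
                            regime = c("generic", "signal_noise", "classification",
                                       "homeostatic", "place_field"),
                            window = NULL) {
  stopifnot(inherits(trace, "calcitron_trace"))
  regime <- match.arg(regime)
  st <- trace$steps
  t_steps <- nrow(st)
  switch(regime,
    generic = list(
      n_steps = t_steps,
      spike_rate = mean(st$spike),
      mean_output = mean(st$y_hat),
      final_weights = trace$weights[t_steps, ]
    ),
    signal_noise = {
      if (all(is.na(st$label))) stop("signal/noise summary requires step labels")
      window <- window %||% min(50L, floor(t_steps / 4))
      correct <- st$spike == st$label
      sig_row <- which(st$label == 1)[1]
      if (is.na(sig_row)) stop("trace contains no signal presentations")
      sig_syn <- which(trace$x[sig_row, ] > 0)
      wT <- trace$weights[t_steps, ]
      list(
        correct = correct,
        early_correct = mean(correct[seq_len(window)]),
        late_correct = mean(correct[seq(t_steps - window + 1L, t_steps)]),
        signal_synapses = sig_syn,
        mean_signal_weight = mean(wT[sig_syn]),
        mean_noise_weight = mean(wT[-sig_syn])
      )
    },
    classification = {
      if (all(is.na(st$label)) || all(is.na(st$epoch))) {
        stop("classification summary requires labels and epochs")
      }
      err <- tapply(st$spike != st$label, st$epoch, sum)
      errors <- data.frame(epoch = as.integer(names(err)), errors = as.integer(err))
      perfect <- errors$errors == 0
      first_clean <- if (any(perfect)) {
        # first epoch from which everything after is error-free
        idx <- which(rev(cumprod(rev(perfect))) == 1)
        errors$epoch[idx[1]]
      } else {
        NA_integer_
      }
      list(errors = errors, first_clean_epoch = first_clean,
           final_errors = errors$errors[nrow(errors)])
    },
    homeostatic = {
      window <- window %||% 20L
      outs <- st$y_hat[seq(t_steps - window + 1L, t_steps)]
      band <- c(trace$config$y_min_star, trace$config$y_max_star)
      list(
        window = window,
        min_output = min(outs), max_output = max(outs),
        in_range_fraction = mean(outs >= band[1] & outs <= band[2]),
        band = band
      )
    },
    place_field = {
      n_loc <- trace$stream_info$n_locations %||%
        stop("place-field summary requires a circular-track trace")
      sup_steps <- which(st$z > 0)
      events <- lapply(sup_steps, function(s) {
        if (s + n_loc > t_steps) return(NULL)
        lap <- seq(s + 1L, s + n_loc)
        if (any(st$z[lap] > 0)) return(NULL)  # overwritten mid-lap
        stored <- trace$x[s, ]
        at_loc <- vapply(lap, function(t) all(trace$x[t, ] == stored), logical(1))
        data.frame(
          supervised_step = s,
          spikes_at_location = all(st$spike[lap][at_loc] == 1),
          silent_elsewhere = all(st$spike[lap][!at_loc] == 0)
        )
      })
      events <- do.call(rbind, events)
      list(events = events,
           all_correct = !is.null(events) &&
             all(events$spikes_at_location & events$silent_elsewhere))
    }
  )
}
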