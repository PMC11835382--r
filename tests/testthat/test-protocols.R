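test_that("generators honour their sparsity and distinctness guarantees", {
  # even/odd: exactly half the synapses active, consistent parity
  s <- gen_even_odd(20, t_steps = 50, seed = 1)
  expect_true(all(rowSums(s$x) == 10))
  for (t in 1:50) {
    active <- which(s$x[t, ] > 0)
    expect_true(all(active %% 2 == (if (s$pattern_id[t] == "even") 0 else 1)))
  }

  # classification: distinct patterns, balanced labels, per-epoch permutations
  s <- gen_classification(24, n_patterns = 6, k = 8, positive_fraction = 0.5,
                          epochs = 4, seed = 2)
  expect_equal(nrow(s$patterns), 6)
  expect_equal(anyDuplicated(apply(s$patterns, 1, paste, collapse = "")), 0)
  expect_true(all(rowSums(s$patterns) == 8))
  expect_equal(sum(s$pattern_labels), 3)
  expect_equal(s$n_steps, 24)
  for (e in 1:4) {
    expect_setequal(s$pattern_id[s$epoch == e], 1:6)
  }

  # signal/noise: fixed sparsity; all-noise control repeats no pattern
  s <- gen_signal_noise(12, k = 4, t_steps = 100, p_signal = 0, seed = 3)
  expect_true(all(rowSums(s$x) == 4))
  expect_equal(anyDuplicated(apply(s$x, 1, paste, collapse = "")), 0)
  # infeasible pattern budgets error out
  expect_error(gen_signal_noise(6, k = 3, t_steps = 100, p_signal = 0, seed = 3),
               "distinct")

  # circular track: distinct location patterns, bounded overlap, spaced plateaus
  s <- gen_circular_track(14, n_locations = 4, k = 7, n_laps = 10,
                          n_supervised = 3, seed = 4)
  expect_equal(s$n_steps, 40)
  expect_true(all(rowSums(s$patterns) == 7))
  ov <- s$patterns %*% t(s$patterns)
  expect_true(all(ov[upper.tri(ov)] <= 6))
  sup <- which(s$z_schedule > 0)
  expect_length(sup, 3)
  expect_true(all(diff(sup) >= 8))
  expect_true(max(sup) <= s$n_steps - 4)  # a clean lap follows each plateau
})

test_that("streams are deterministic in their seed and leave the caller's RNG alone", {
  expect_identical(gen_random_binary(10, 30, 0.5, seed = 9),
                   gen_random_binary(10, 30, 0.5, seed = 9))
  expect_false(identical(gen_random_binary(10, 30, 0.5, seed = 9)$x,
                         gen_random_binary(10, 30, 0.5, seed = 10)$x))
  set.seed(123)
  before <- .Random.seed
  invisible(gen_classification(24, 6, 8, 0.5, 2, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("a timestep evaluates output, supervision, calcium, plasticity in order", {
  cfg <- load_row_config("one_shot_flip_flop")
  w <- rep(0.5, 14)
  x <- c(rep(1, 7), rep(0, 7))
  # the supervisory signal never reaches the output
  st0 <- run_timestep(w, x, cfg, z_scheduled = 0)
  st1 <- run_timestep(w, x, cfg, z_scheduled = 1)
  expect_identical(st0$y_hat, st1$y_hat)
  # a supervised step writes the binarized input into the binary weights
  expect_equal(st1$weights, cfg$f_d + (cfg$f_p - cfg$f_d) * x)
  # an unsupervised step leaves weights unchanged (alpha below theta_d)
  expect_equal(st0$weights, w)
})

test_that("one-shot writes hold for arbitrary binary inputs across seeds", {
  cfg <- load_row_config("one_shot_flip_flop")
  set.seed(31)
  for (i in 1:20) {
    x <- rbinom(14, 1, runif(1, 0.2, 0.8))
    w <- runif(14)  # any starting point inside [w_min, w_max]
    st <- run_timestep(w, x, cfg, z_scheduled = 1)
    expect_equal(st$weights, as.numeric(x))
  }
})

test_that("a recorded trace replays bit-for-bit", {
  cfg <- load_row_config("hebbian_ddp")
  stream <- build_stream(cfg)
  tr1 <- run_experiment(cfg, stream)
  tr2 <- run_experiment(cfg, stream)
  expect_identical(tr1$weights, tr2$weights)
  expect_identical(tr1$steps, tr2$steps)
  # internal consistency: y_hat at t is reproducible from the weights at t-1
  w_before <- rbind(tr1$w_init, tr1$weights[-nrow(tr1$weights), ])
  for (t in c(1, 7, 50, 100)) {
    p <- calcitron_params(w_before[t, ], bias = cfg$b, activation = cfg$g,
                          alpha = cfg$alpha, beta = cfg$beta,
                          gamma = cfg$gamma, delta = cfg$delta)
    expect_equal(compute_output(p, tr1$x[t, ]), tr1$steps$y_hat[t])
  }
  # and the weights at t follow from the calcium recorded at t
  th <- calcitron:::config_thresholds(cfg)
  rule <- calcitron:::config_rule(cfg)
  for (t in c(1, 25, 99)) {
    expect_equal(apply_plasticity(w_before[t, ], tr1$calcium[t, ], th, rule,
                                  mode = cfg$mode),
                 tr1$weights[t, ])
  }
})

test_that("mismatched stream width is rejected", {
  cfg <- load_row_config("hebbian_nnp")  # N = 10
  stream <- gen_random_binary(12, 20, 0.5, seed = 1)
  expect_error(run_experiment(cfg, stream), "does not match")
})

test_that("phase plane boundaries sit at threshold-over-coefficient rates", {
  th <- plasticity_thresholds(0.5, 0.8)
  xg <- seq(0, 4, by = 0.01)
  # presynaptic-only: vertical boundaries at theta_d/alpha and theta_p/alpha
  pp <- phase_plane(0.3, 0, th, x_grid = xg, y_grid = c(0, 5))
  xs <- as.numeric(rownames(pp))
  expect_equal(min(xs[pp[, 1] == "D"]), 5 / 3, tolerance = 0.011)
  expect_equal(min(xs[pp[, 1] == "P"]), 8 / 3, tolerance = 0.011)
  expect_identical(pp[, 1], pp[, 2])  # gamma = 0: no dependence on the output rate
  # postsynaptic-only: horizontal boundaries
  pp2 <- phase_plane(0, 0.3, th, x_grid = c(0, 5), y_grid = xg)
  ys <- as.numeric(colnames(pp2))
  expect_equal(min(ys[pp2[1, ] == "P"]), 8 / 3, tolerance = 0.011)
  # mixed coefficients: every cell classifies alpha*x + gamma*y directly
  pp3 <- phase_plane(0.3, 0.15, th, x_grid = seq(0, 4, 0.5), y_grid = seq(0, 4, 0.5))
  for (i in seq_along(rownames(pp3))) {
    for (j in seq_along(colnames(pp3))) {
      ca <- 0.3 * as.numeric(rownames(pp3))[i] + 0.15 * as.numeric(colnames(pp3))[j]
      expect_equal(pp3[i, j], classify_region(ca, th))
    }
  }
  expect_error(phase_plane(0, 0, th), "degenerate")
})

test_that("trace summaries compute their protocol statistics", {
  cfg <- load_row_config("perceptron_critic")
  cfg$stream$epochs <- 12
  sm <- summarize_trace(run_experiment(cfg), "classification")
  expect_equal(nrow(sm$errors), 12)
  expect_true(all(sm$errors$errors >= 0 & sm$errors$errors <= 6))
  expect_equal(sm$final_errors, sm$errors$errors[12])

  hcfg <- load_row_config("homeostatic_global_dual")
  hs <- summarize_trace(run_experiment(hcfg), "homeostatic")
  expect_equal(hs$band, c(1, 3))
  expect_lte(hs$min_output, hs$max_output)
  expect_gte(hs$in_range_fraction, 0)

  tr <- run_experiment(load_row_config("heterosynaptic_unsupervised"))
  ss <- summarize_trace(tr, "signal_noise")
  expect_length(ss$correct, 300)
  expect_length(ss$signal_synapses, 4)
  expect_error(summarize_trace(tr, "classification"), "epoch")
})
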