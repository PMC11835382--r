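test_that("region boundaries follow the closed depressive interval", {
  th <- plasticity_thresholds(0.5, 1)
  expect_equal(classify_region(0.5, th), "D")  # boundary calcium depresses
  expect_equal(classify_region(1, th), "D")
  expect_equal(classify_region(0, th), "N")
  expect_equal(classify_region(0.85, th_std), "P")  # strictly above theta_p

  # post-potentiative neutral zone: P up to and including theta_ppnz
  thz <- plasticity_thresholds(0.5, 0.6, theta_ppnz = 0.8)
  expect_equal(classify_region(c(0.45, 0.55, 0.7, 0.8, 0.81), thz),
               c("N", "D", "P", "P", "PPNZ"))

  # reversed (Purkinje-style) order: middle region potentiates, closed ends
  expect_equal(classify_region(c(0.3, 0.5, 0.65, 0.8, 0.81), th_rev),
               c("N", "P", "P", "P", "D"))

  expect_error(classify_region(-0.1, th), "non-negative")
  expect_error(plasticity_thresholds(0.5, 0.5), "degenerate")
  expect_error(plasticity_thresholds(0.8, 0.5, theta_ppnz = 1), "standard")
  expect_error(plasticity_thresholds(0.5, 0.8, theta_ppnz = 0.7), "exceed")
})

test_that("linear rule returns the signed step per region", {
  lin <- linear_rule(eta_d = 0.1, eta_p = 0.2)
  th <- plasticity_thresholds(0.5, 1)
  expect_equal(omega_linear(0.3, th, lin), 0)
  expect_equal(omega_linear(0.7, th, lin), -0.1)
  expect_equal(omega_linear(1.2, th, lin), 0.2)
  # signed depression rates are normalized: the rule carries the sign
  expect_equal(linear_rule(-0.1, 0.2)$eta_d, 0.1)
})

test_that("linear rule accumulates as an exact staircase", {
  lin <- linear_rule(0.1, 0.2)
  th <- plasticity_thresholds(0.5, 1)
  w <- 5
  for (t in 1:30) w <- w + omega_linear(0.7, th, lin)  # constant depressive step
  expect_equal(w, 5 - 30 * 0.1, tolerance = 1e-12)
  w <- 5
  for (t in 1:30) w <- w + omega_linear(1.5, th, lin)
  expect_equal(w, 5 + 30 * 0.2, tolerance = 1e-12)
  # the linear rule imposes no bounds: weights may cross zero
  w <- 0.2
  for (t in 1:5) w <- w + omega_linear(0.7, th, lin)
  expect_lt(w, 0)
})

test_that("FPLR steps move toward the region's fixed point", {
  th <- plasticity_thresholds(0.5, 1)
  f <- fplr_rule(f_d = 0, f_p = 1, eta_d = 0.1, eta_p = 0.1)
  expect_equal(fplr_step(0.4, 1.2, th, f), 0.46)
  # rate 1 jumps to the fixed point: switch-like one-shot writes
  f1 <- fplr_rule(f_d = 0, f_p = 1, eta_d = 1, eta_p = 1)
  expect_equal(fplr_step(0.73, 0.7, th, f1), 0)
  expect_equal(fplr_step(0.2, 1.5, th, f1), 1)
  # no pre-depressive drift by default
  expect_equal(fplr_step(0.2, 0.1, th, f), 0.2)
})

test_that("FPLR iteration matches its closed form to 1e-12", {
  # holding the region fixed, w_t = F + (1 - eta)^t (w_0 - F)
  th <- plasticity_thresholds(0.5, 1)
  cases <- list(
    list(eta = 0.1, c = 1.5, f_target = 1, w0 = 0.4),
    list(eta = 0.025, c = 0.7, f_target = 0, w0 = 0.73),
    list(eta = 0.5, c = 2.0, f_target = 1, w0 = 0.01)
  )
  for (cs in cases) {
    f <- fplr_rule(f_d = 0, f_p = 1, eta_d = cs$eta, eta_p = cs$eta)
    w <- cs$w0
    for (t in 1:60) {
      w <- fplr_step(w, cs$c, th, f)
      expect_equal(w, cs$f_target + (1 - cs$eta)^t * (cs$w0 - cs$f_target),
                   tolerance = 1e-12)
    }
  }
})

test_that("FPLR weights never leave the fixed-point envelope", {
  set.seed(7)
  th <- plasticity_thresholds(0.5, 1)
  for (i in 1:10) {
    f <- fplr_rule(f_d = 0, f_p = 1, eta_d = runif(1), eta_p = runif(1))
    w <- runif(8)  # start inside [w_min, w_max] = [0, 1]
    for (t in 1:200) {
      w <- fplr_step(w, runif(8, 0, 2), th, f)
      expect_true(all(w >= 0 & w <= 1))
    }
  }
})

test_that("region classification is monotone in calcium", {
  grid <- seq(0, 3, by = 0.001)
  for (th in list(th_std, th_wide)) {
    r <- region_rank(classify_region(grid, th), "standard")
    expect_true(all(diff(r) >= 0))
  }
  r <- region_rank(classify_region(grid, th_rev), "reversed")
  expect_true(all(diff(r) >= 0))
})

test_that("apply_plasticity equals element-wise rule application", {
  th <- plasticity_thresholds(0.5, 1)
  f <- fplr_rule(f_d = 0, f_p = 1, eta_d = 0.1, eta_p = 0.1)
  w <- c(0.2, 0.5, 0.9, 0.4)
  ca <- c(0.1, 0.7, 1.4, 0.45)
  expect_equal(apply_plasticity(w, ca, th, f, mode = "fplr"),
               vapply(seq_along(w), function(i) fplr_step(w[i], ca[i], th, f),
                      numeric(1)))
  # calcium everywhere below theta_d leaves the weights untouched
  expect_equal(apply_plasticity(w, rep(0.1, 4), th, f, mode = "fplr"), w)
  # rate-1 updates binarize the weight vector to the region fixed points
  f1 <- fplr_rule(eta_d = 1, eta_p = 1)
  expect_equal(apply_plasticity(w, c(0.7, 1.5, 0.7, 1.5), th, f1, mode = "fplr"),
               c(0, 1, 0, 1))
  # linear mode dispatches to the signed steps
  lin <- linear_rule(0.1, 0.2)
  expect_equal(apply_plasticity(w, ca, th, lin, mode = "linear"),
               w + omega_linear(ca, th, lin))
  expect_error(apply_plasticity(w, ca[1:3], th, f, mode = "fplr"), "length")
})

test_that("mixed regions depress inactive and potentiate active synapses in one call", {
  # the heterosynaptic configuration: shared depolarization calcium puts
  # inactive synapses in D while local calcium lifts active synapses into P
  th <- plasticity_thresholds(0.7, 2.6)
  f <- fplr_rule(f_d = 1, f_p = 3, eta_d = 0.025, eta_p = 0.025)
  p <- calcitron_params(rep(2, 12), bias = -8, alpha = 2, beta = 0.2)
  x <- c(rep(1, 4), rep(0, 8))
  ca <- compute_calcium(p, x, y_hat = 0)
  w2 <- apply_plasticity(p$weights, ca, th, f, mode = "fplr")
  expect_true(all(w2[1:4] > 2))   # active move toward w_max = 3
  expect_true(all(w2[5:12] < 2))  # inactive move toward w_min = 1
})
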