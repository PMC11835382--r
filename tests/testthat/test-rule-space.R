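test_that("the rule taxonomy has 27 three-slot and 81 four-slot codes", {
  counts <- combinatoric_counts()
  expect_identical(counts$three_slot, 27L)
  expect_identical(counts$four_slot, 81L)
  expect_length(all_rule_codes(), counts$three_slot)
  expect_false(anyDuplicated(all_rule_codes()) > 0)
})

test_that("coefficient pairs map to their rule codes", {
  expect_equal(rule_outcomes(0.4, 0.45, th_std), "NNP")  # fire together, wire together
  expect_equal(rule_outcomes(0.55, 0.7, th_std), "DDP")  # out of sync, lose your link
  expect_equal(rule_outcomes(0.4, 0.3, th_std), "NND")   # anti-Hebbian
  expect_equal(rule_outcomes(0.55, 0.6, th_rev), "PPD")  # reversed-threshold anti-Hebbian
  expect_error(rule_outcomes(-0.1, 0.3, th_std), "non-negative")
})

test_that("each threshold scenario admits exactly 13 rules with the expected exclusions", {
  narrow <- enumerate_feasible_rules(th_std)   # pre-depressive region larger
  wide <- enumerate_feasible_rules(th_wide)    # depressive region larger
  expect_length(narrow, 13)
  expect_length(wide, 13)
  expect_true("NNP" %in% narrow)
  expect_false("DDD" %in% narrow)
  expect_true("DDD" %in% wide)
  expect_false("NNP" %in% wide)
  # PPN cannot be realised under any thresholds: two potentiative components
  # always sum above the potentiation threshold
  expect_false("PPN" %in% narrow)
  expect_false("PPN" %in% wide)
  expect_false("PPN" %in% enumerate_feasible_rules(th_rev))
  expect_error(enumerate_feasible_rules(plasticity_thresholds(0.5, 0.5)), "degenerate")
})

test_that("the scenario unions hold 14 rules under either threshold order", {
  expect_length(feasible_rules_analytic("standard", "union"), 14)
  expect_length(feasible_rules_analytic("reversed", "union"), 14)
  # the boundary case (middle interval closed) behaves like the wide scenario
  expect_setequal(feasible_rules_analytic("standard", "boundary"),
                  feasible_rules_analytic("standard", "dep_region_larger"))
})

test_that("grid enumeration agrees with the analytic interval solution", {
  set.seed(11)
  for (i in 1:20) {
    lo <- runif(1, 0.1, 1)
    hi <- lo + runif(1, 0.05, 1.5)
    for (th in list(plasticity_thresholds(lo, hi), plasticity_thresholds(hi, lo))) {
      expect_identical(enumerate_feasible_rules(th),
                       calcitron:::feasible_rules_exact(th))
    }
  }
})

test_that("feasible codes obey the both >= max(pre, post) escalation law", {
  for (order in c("standard", "reversed")) {
    codes <- feasible_rules_analytic(order, "union")
    for (code in codes) {
      letters <- strsplit(code, "")[[1]]
      r <- region_rank(letters, order)
      expect_gte(r[3], max(r[1], r[2]))
    }
  }
  # and a code violating it is unreachable
  expect_false("PPD" %in% feasible_rules_analytic("standard", "union"))
})

test_that("NNP/DDD feasibility partitions on whether 2*theta_d exceeds theta_p", {
  set.seed(23)
  for (i in 1:20) {
    td <- runif(1, 0.1, 1)
    tp <- td + runif(1, 0.05, 1.5)
    feas <- enumerate_feasible_rules(plasticity_thresholds(td, tp))
    expect_equal("NNP" %in% feas, 2 * td > tp)
    expect_equal("DDD" %in% feas, 2 * td <= tp)
  }
  # exact boundary: the closed depressive interval admits DDD, not NNP
  feas <- enumerate_feasible_rules(plasticity_thresholds(0.5, 1.0))
  expect_true("DDD" %in% feas)
  expect_false("NNP" %in% feas)
})

test_that("synthesized witnesses round-trip and infeasible codes are marked", {
  for (th in list(th_std, th_wide, th_rev)) {
    feas <- enumerate_feasible_rules(th)
    for (code in all_rule_codes()) {
      wit <- synthesize_coefficients(code, th)
      expect_identical(wit$feasible, code %in% feas)
      if (wit$feasible) {
        expect_equal(rule_outcomes(wit$alpha, wit$gamma, th), code)
      } else {
        expect_true(is.na(wit$alpha) && is.na(wit$gamma))
      }
    }
  }
  # the documented witness style: NNP needs both coefficients sub-depressive
  # with a supra-potentiative sum
  wit <- synthesize_coefficients("NNP", th_std)
  expect_lt(wit$alpha, 0.5)
  expect_lt(wit$gamma, 0.5)
  expect_gt(wit$alpha + wit$gamma, 0.8)
  expect_error(synthesize_coefficients("QQQ", th_std), "rule codes")
})
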