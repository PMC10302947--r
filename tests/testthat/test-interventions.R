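test_that("blood-pressure lowering maps to hazard ratios by the 20-mm-Hg halving rule", {
  expect_equal(bp_reduction_to_hazard_ratio(0), 1)
  expect_equal(bp_reduction_to_hazard_ratio(20), 0.5)
  expect_equal(bp_reduction_to_hazard_ratio(7), 2^(-0.35))
  expect_equal(bp_reduction_to_hazard_ratio(7), 0.7846, tolerance = 1e-4)
  expect_error(bp_reduction_to_hazard_ratio(-1), "non-negative")
})

test_that("compliance mixes the effect all-or-nothing", {
  expect_equal(effective_hazard_ratio(0.3, 0), 1)
  expect_equal(effective_hazard_ratio(0.3, 1), 0.3)
  expect_equal(effective_hazard_ratio(2^(-0.35), 0.6),
               0.6 * 2^(-0.35) + 0.4)
  expect_equal(effective_hazard_ratio(0.7846, 0.6), 0.87076)
})

test_that("usual care leaves rates untouched and carries no intervention cost", {
  ps <- base_params()
  mod <- apply_strategy(ps, "usual_care")
  expect_equal(param_provenance(mod)$value, param_provenance(ps)$value)
  expect_equal(unname(mod$intervention_cost), rep(0, 4))
})

test_that("strategy efficacy scales hazards on the rate scale through compliance", {
  ps <- base_params()
  # a drug with a 20 mm Hg effect (HR 0.5) at 50% compliance on one state
  ps$efficacy$sbp_reduction$pre_hypertension$value <- 20
  ps$compliance$medication$value <- 0.5
  spec <- list(rules = list(list(
    states = "pre_hypertension", groups = c("low", "mid", "high"),
    bundle = "prophylactic_drug", compliance = "medication")))
  mod <- apply_strategy(ps, spec, group = "mid")
  p <- htncea:::p_value(ps$transition$p_pre_to_stage1)
  expect_equal(htncea:::p_value(mod$transition$p_pre_to_stage1),
               1 - (1 - p)^0.75)
  h <- htncea:::p_value(ps$hazards$mi$pre_hypertension)
  expect_equal(htncea:::p_value(mod$hazards$mi$pre_hypertension),
               1 - (1 - h)^0.75)
  # untargeted states and the regression rate are untouched
  expect_equal(htncea:::p_value(mod$transition$p_normal_to_pre),
               htncea:::p_value(ps$transition$p_normal_to_pre))
  expect_equal(htncea:::p_value(mod$transition$p_pre_to_normal),
               htncea:::p_value(ps$transition$p_pre_to_normal))
  expect_equal(unname(mod$intervention_cost),
               c(0, htncea:::p_value(ps$costs$prophylactic_drug), 0, 0))
  expect_error(apply_strategy(ps, list(rules = list(list(
    states = "pre_hypertension", groups = "mid", bundle = "no_such_item",
    compliance = "medication")))), "no_such_item")
})

test_that("rules apply only to their risk groups", {
  ps <- base_params()
  mod_low <- apply_strategy(ps, "personalized", group = "low")
  mod_high <- apply_strategy(ps, "personalized", group = "high")
  expect_gt(mod_high$intervention_cost[["stage2"]], 0)
  expect_equal(mod_low$intervention_cost[["stage2"]], 0)
})

test_that("zero-compliance prevention matches usual care except for program costs", {
  ps <- point_params()
  ps$compliance$lifestyle$value <- 0
  uc <- accumulate(run_cohort(ps, "usual_care", "mid"))
  pw <- accumulate(run_cohort(ps, "population_wide", "mid"))
  expect_equal(pw$qaly, uc$qaly)
  expect_gt(pw$cost, uc$cost)
})

test_that("with positive efficacy and zero program cost every strategy weakly dominates usual care in QALYs", {
  ps <- point_params()
  for (k in c("lifestyle_low", "lifestyle_mid", "lifestyle_full",
              "screening_low_awareness", "prophylactic_drug",
              "regular_checkup", "advanced_checkup"))
    ps$costs[[k]]$value <- 0
  uc <- htncea:::evaluate_strategies(ps, "usual_care")
  for (s in c("population_wide", "high_risk", "personalized")) {
    act <- htncea:::evaluate_strategies(ps, s)
    expect_gte(act$qaly, uc$qaly)
    expect_lte(act$cost, uc$cost)  # fewer complications, no program cost
  }
})
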