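test_that("a frozen cohort never moves and nobody dies", {
  ps <- generate_toy_model("frozen")
  tr <- run_cohort(ps, horizon = 15)
  expect_equal(tr$occupancy[16, ], tr$occupancy[1, ])
  expect_equal(unname(tr$occupancy[16, "dead"]), 0)
  expect_equal(rowSums(tr$occupancy), rep(1, 16), tolerance = 1e-12)
})

test_that("two-state chain occupancy matches the geometric closed form to 1e-12", {
  for (p in c(0.02, 0.1, 0.5)) {
    ps <- generate_toy_model("geometric", p = p)
    tr <- run_cohort(ps, horizon = 25)
    occ <- disease_occupancy(tr)
    expect_equal(unname(occ[, "stage1"]), 1 - (1 - p)^(0:25),
                 tolerance = 1e-12)
    expect_equal(unname(occ[, "pre_hypertension"]), (1 - p)^(0:25),
                 tolerance = 1e-12)
  }
})

test_that("a single complication produces h*m immediate deaths in cycle 1", {
  ps <- generate_toy_model("single_complication", h = 0.2, m = 0.15)
  tr <- run_cohort(ps, horizon = 3)
  expect_equal(unname(tr$occupancy[2, "dead"]), 0.2 * 0.15)
  # survivors carry the complication for life
  expect_equal(unname(tr$occupancy[2, "stage2.mi"]), 0.2 * 0.85)
  expect_equal(unname(tr$occupancy[2, "stage2.none"]), 0.8)
  # with zero yearly mortality the mi carriers persist
  expect_gte(tr$occupancy[4, "stage2.mi"], tr$occupancy[2, "stage2.mi"])
})

test_that("mass is conserved and dead mass is non-decreasing on the full model", {
  ps <- base_params()
  for (s in strategy_names(ps)) {
    tr <- run_cohort(ps, s, "high")
    expect_equal(rowSums(tr$occupancy), rep(1, ps$economics$horizon_years + 1),
                 tolerance = 1e-9)
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-15))
  }
})

test_that("discount factors follow (1+r)^-t with undiscounted cycle 0", {
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
  expect_equal(discount_factor(0.07, 0), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0.03, 5), 1.03^-5)
})

test_that("accumulated QALYs equal discount annuities for a full-utility cohort", {
  ps <- generate_toy_model("frozen")
  tr <- run_cohort(ps, horizon = 20)
  expect_equal(accumulate(tr, rate = 0)$qaly, 20)       # cycle 0 not counted
  expect_equal(accumulate(tr, rate = 0.03)$qaly, sum(1.03^-(1:20)))
  expect_equal(accumulate(tr, rate = 0.03)$qaly, 14.8775, tolerance = 1e-4)
  expect_equal(accumulate(tr, rate = 0)$cost, 0)
})

test_that("zero discount reproduces undiscounted sums exactly", {
  ps <- base_params()
  tr <- run_cohort(ps, "population_wide", "mid")
  ce <- accumulate(tr, rate = 0)
  expect_identical(ce$cost, sum(tr$cost_flow))
  expect_identical(ce$qaly, sum(tr$utility_flow))
  expect_true(ce$qaly >= 0 && ce$qaly <= tr$horizon)
})

test_that("raising a complication hazard raises cost and lowers QALYs", {
  ps <- point_params()
  base <- accumulate(run_cohort(ps, "usual_care", "mid"))
  ps2 <- ps
  for (s in disease_states()) ps2$hazards$esrd[[s]]$value <-
    min(1, 20 * htncea:::p_value(ps$hazards$esrd[[s]]))
  worse <- accumulate(run_cohort(ps2, "usual_care", "mid"))
  expect_gt(worse$cost, base$cost)
  expect_lt(worse$qaly, base$qaly)
})

test_that("the tidy trace export carries occupancy and flows per cycle", {
  ps <- generate_toy_model("geometric", p = 0.1)
  tr <- run_cohort(ps, horizon = 5)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 6 * 33)
  expect_setequal(unique(df$cycle), 0:5)
  expect_equal(sum(df$occupancy), 6)  # each cycle sums to 1
})
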