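test_that("the bundled base-case configuration loads with the published values", {
  ps <- base_params()
  expect_s3_class(ps, "htn_params")
  expect_equal(htncea:::p_value(ps$economics$discount_rate), 0.03)
  expect_equal(ps$economics$horizon_years, 20L)
  expect_equal(htncea:::p_value(ps$hazards$mi$normal), 0.003)
  expect_equal(htncea:::p_value(ps$compliance$lifestyle), 0.60)
  expect_equal(htncea:::p_value(ps$compliance$screening), 0.70)
  expect_equal(htncea:::p_value(ps$compliance$medication), 0.50)
  # cost base case defaults to the triangular mode
  expect_equal(htncea:::p_value(ps$costs$esrd_annual), 20000)
  expect_setequal(strategy_names(ps),
                  c("usual_care", "population_wide", "high_risk",
                    "personalized"))
})

test_that("the section24 hazard preset swaps only base-case hazard values", {
  ps <- load_parameters(htncea_example_config(), hazard_preset = "section24")
  expect_equal(htncea:::p_value(ps$hazards$mi$pre_hypertension), 0.0032)
  expect_equal(htncea:::p_value(ps$hazards$stroke$stage2), 0.0072)
  expect_equal(htncea:::p_value(ps$hazards$esrd$stage1), 0.0321)
  # distributions untouched
  expect_equal(ps$hazards$mi$pre_hypertension$dist,
               base_params()$hazards$mi$pre_hypertension$dist)
})

test_that("validation rejects out-of-range and missing inputs by name", {
  bad_prob <- write_modified_config(function(raw) {
    raw$transition$p_pre_to_normal <- 1.2
    raw
  })
  expect_error(load_parameters(bad_prob), "p_pre_to_normal")

  no_util <- write_modified_config(function(raw) {
    raw$utilities <- NULL
    raw
  })
  expect_error(load_parameters(no_util), "utilities")

  missing_cost <- write_modified_config(function(raw) {
    raw$costs$terminal_care <- NULL
    raw
  })
  expect_error(load_parameters(missing_cost), "terminal_care")

  bad_row <- write_modified_config(function(raw) {
    raw$transition$p_pre_to_stage1 <- 0.7
    raw$transition$p_pre_to_normal <- 0.6
    raw
  })
  expect_error(load_parameters(bad_row), "exit probabilities sum")

  bad_isd <- write_modified_config(function(raw) {
    raw$economics$initial_state_distribution$normal <- 0.9
    raw
  })
  expect_error(load_parameters(bad_isd), "initial_state_distribution")
})

test_that("sampling is deterministic under a fixed seed and a no-op on point masses", {
  ps <- base_params()
  expect_identical(sample_parameter_set(ps, 1L), sample_parameter_set(ps, 1L))
  expect_false(identical(sample_parameter_set(ps, 1L),
                         sample_parameter_set(ps, 2L)))
  pp <- point_params()
  expect_identical(sample_parameter_set(pp, 99L), pp)
})

test_that("sampled parameter sets satisfy the invariants and track their distributions", {
  ps <- base_params()
  sd_beta <- function(a, b) sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  n <- 2000L
  draws <- vapply(seq_len(n), function(r) {
    htncea:::p_value(sample_parameter_set(ps, r)$hazards$mi$normal)
  }, numeric(1))
  expect_true(all(draws >= 0 & draws <= 1))
  expect_lt(abs(mean(draws) - 0.003), 4 * sd_beta(30, 9970) / sqrt(n))
})

test_that("a sampled pre-hypertension row exceeding 1 is renormalized with a warning", {
  ps <- base_params()
  ps$transition$p_pre_to_stage1$dist <- dist_beta(990, 10)
  ps$transition$p_pre_to_normal$dist <- dist_beta(990, 10)
  expect_warning(out <- sample_parameter_set(ps, 5L), "renormalizing")
  expect_equal(htncea:::p_value(out$transition$p_pre_to_stage1) +
                 htncea:::p_value(out$transition$p_pre_to_normal), 1)
})

test_that("write_parameters round-trips point values bit-identically", {
  ps <- base_params()
  path <- tempfile(fileext = ".yaml")
  write_parameters(ps, path)
  ps2 <- load_parameters(path)
  expect_identical(param_provenance(ps)$value, param_provenance(ps2)$value)
  expect_identical(param_provenance(ps)$distribution,
                   param_provenance(ps2)$distribution)
})

test_that("provenance tags every parameter as published or assumption", {
  prov <- param_provenance(base_params())
  expect_true(all(prov$source %in% c("paper_table1", "assumption")))
  expect_gt(sum(prov$source == "assumption"), 0)  # unpublished inputs exist
  expect_true("transition.p_normal_to_pre" %in%
                prov$parameter[prov$source == "assumption"])
  expect_true("hazards.mi.normal" %in%
                prov$parameter[prov$source == "paper_table1"])
})
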