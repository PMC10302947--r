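test_that("transition matrix honours the zero pattern and row completion", {
  zero <- list(p_normal_to_pre = 0, p_pre_to_stage1 = 0,
               p_stage1_to_stage2 = 0, p_pre_to_normal = 0)
  expect_equal(unname(build_transition_matrix(zero)), diag(4))

  tr <- list(p_normal_to_pre = 0.08, p_pre_to_stage1 = 0.1,
             p_stage1_to_stage2 = 0.04, p_pre_to_normal = 0.05)
  m <- build_transition_matrix(tr)
  expect_equal(unname(m["pre_hypertension", ]), c(0.05, 0.85, 0.10, 0))
  expect_equal(rowSums(m), setNames(rep(1, 4), disease_states()))
  # no regression past stage I; stage II absorbing in disease space
  expect_identical(m["stage1", "normal"], 0)
  expect_identical(m["stage1", "pre_hypertension"], 0)
  expect_identical(unname(m["stage2", ]), c(0, 0, 0, 1))
  expect_error(build_transition_matrix(
    list(p_normal_to_pre = 0, p_pre_to_stage1 = 0.7,
         p_stage1_to_stage2 = 0, p_pre_to_normal = 0.6)),
    "pre_hypertension")
})

test_that("rows stay stochastic for random valid rates", {
  set.seed(4)
  for (i in 1:50) {
    e <- runif(2)
    tr <- list(p_normal_to_pre = runif(1), p_pre_to_stage1 = e[1] / sum(e),
               p_stage1_to_stage2 = runif(1), p_pre_to_normal = e[2] / sum(e))
    m <- build_transition_matrix(tr)
    expect_equal(rowSums(m), setNames(rep(1, 4), disease_states()),
                 tolerance = 1e-12)
    expect_true(all(m >= 0))
  }
})

test_that("risk scores are linear in the covariates and validate names", {
  w <- c(a = 0.5, b = -1)
  expect_equal(risk_score(c(a = 0, b = 0), w, intercept = 2), 2)
  expect_equal(risk_score(c(a = 10, b = 3), c(a = 0, b = 0), intercept = 2), 2)
  expect_equal(risk_score(c(x = 1), c(x = log(2))), log(2))
  expect_equal(exp(risk_score(c(x = 1), c(x = log(2)))), 2)
  expect_error(risk_score(c(a = 1, z = 2), w), "unmatched")
  df <- data.frame(a = c(0, 1), b = c(0, 1))
  expect_equal(risk_score(df, w, intercept = 1), c(1, 0.5))
})

test_that("stratification uses half-open cutoff intervals", {
  expect_equal(as.character(stratify(c(-1, 0, 1), c(0, 0.5))),
               c("low", "mid", "high"))
  expect_equal(as.character(stratify(c(-5, -4), c(0, 1))), c("low", "low"))
  expect_error(stratify(1:10, c(2, 2)), "strictly increasing")
  set.seed(8)
  s <- rnorm(1000)
  g <- table(stratify(s, quantile(s, c(1, 2) / 3)))
  expect_true(all(abs(g - c(333, 334, 333)) <= 1))
})

test_that("personalization scales progression on the rate scale only", {
  tr <- base_params()$transition
  p0 <- personalize_rates(tr, 0)
  expect_equal(p0$p_pre_to_stage1, htncea:::p_value(tr$p_pre_to_stage1))
  expect_equal(p0$p_pre_to_normal, htncea:::p_value(tr$p_pre_to_normal))

  tr2 <- list(p_normal_to_pre = 0.1, p_pre_to_stage1 = 0.1,
              p_stage1_to_stage2 = 0.1, p_pre_to_normal = 0.2)
  pl <- personalize_rates(tr2, log(2))
  expect_equal(pl$p_pre_to_stage1, 1 - 0.9^2)  # 0.19
  expect_equal(pl$p_pre_to_normal, 0.2)        # regression untouched
  ph <- personalize_rates(tr2, 50)
  expect_true(all(unlist(ph[c("p_normal_to_pre", "p_pre_to_stage1",
                              "p_stage1_to_stage2")]) > 1 - 1e-12))
  # monotone in the score
  scores <- seq(-2, 2, by = 0.5)
  p_seq <- vapply(scores, function(s)
    personalize_rates(tr2, s)$p_pre_to_stage1, numeric(1))
  expect_true(all(diff(p_seq) > 0))
  # regression scaled down when enabled
  pr <- personalize_rates(tr2, 1, modify_regression = TRUE)
  expect_lt(pr$p_pre_to_normal, 0.2)
})
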