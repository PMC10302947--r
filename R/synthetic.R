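# Synthetic inputs: covariate profiles with known risk-score structure and
# closed-form toy parameter sets for oracle verification.  These stand in
# for non-public cohort data; none of the covariate distributions or weights
# below are empirical estimates.

default_covariates <- function() {
  list(age    = list(kind = "normal", mean = 50, sd = 10),
       bmi    = list(kind = "normal", mean = 24, sd = 3.5),
       male   = list(kind = "bernoulli", p = 0.5),
       smoker = list(kind = "bernoulli", p = 0.3))
}

default_weights <- function() {
  c(age = 0.02, bmi = 0.05, male = 0.30, smoker = 0.40)
}

#' Generate synthetic covariate profiles with known risk scores
#'
#' Draws `n` individuals from the covariate specification, computes each
#' individual's linear risk score with the (known, synthetic) weights, and
#' stratifies into low/mid/high groups. Reproducible by seed; a pure
#' function of its arguments.
#'
#' @param n Number of individuals (`>= 1`).
#' @param covariates Named list; each element is
#'   `list(kind = "normal", mean, sd)` (`sd >= 0`) or
#'   `list(kind = "bernoulli", p)` (`p` in \[0, 1\]). Default: age and BMI
#'   normal, male and smoker Bernoulli.
#' @param weights Named weights matching the covariates.
#' @param intercept Score intercept.
#' @param seed Integer seed.
#' @param cutoffs Score cutoffs for [stratify()]; default empirical
#'   tertiles.
#' @return data.frame: `id`, one column per covariate, `score`, `group`.
#' @export
generate_profiles <- function(n, covariates = default_covariates(),
                              weights = default_weights(), intercept = 0,
                              seed = 1L, cutoffs = NULL) {
  stopifnot(n >= 1L)
  if (!setequal(names(covariates), names(weights)))
    stop("covariate and weight names must match")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  cols <- lapply(covariates, function(cv) {
    switch(cv$kind,
      normal = {
        if (cv$sd < 0) stop("normal covariate needs sd >= 0")
        stats::rnorm(n, cv$mean, cv$sd)
      },
      bernoulli = {
        if (cv$p < 0 || cv$p > 1) stop("bernoulli covariate needs p in [0, 1]")
        stats::rbinom(n, 1L, cv$p)
      },
      stop("unknown covariate kind: ", cv$kind))
  })
  df <- as.data.frame(cols)
  df$score <- risk_score(df, weights, intercept)
  df$group <- if (is.null(cutoffs)) {
    if (n >= 3L && stats::sd(df$score) > 0) stratify(df$score)
    else factor(rep("mid", n), levels = risk_groups())
  } else stratify(df$score, cutoffs)
  cbind(id = seq_len(n), df)
}

point_mass_params <- function(ps) {
  walk_params(ps, function(p, path) {
    p$dist <- dist_point(p$value)
    p
  })
}

#' Toy parameter sets with closed-form behaviour
#'
#' Built for oracle tests of the cohort engine; every parameter is a point
#' mass (so a degenerate PSA reproduces the base case), all costs are zero,
#' all utility weights are one, and the cohort is a single average-risk
#' group.
#'
#' * `"frozen"`: all transition and hazard probabilities zero; occupancy is
#'   constant and the QALY total is the plain discount annuity.
#' * `"geometric"`: everyone starts pre-hypertensive and the only flow is
#'   pre to stage I with probability `p`; stage-I occupancy after `t`
#'   cycles is `1 - (1 - p)^t`.
#' * `"single_complication"`: everyone starts in stage II with an AMI
#'   hazard `h` and immediate case fatality `m`; first-cycle deaths equal
#'   `h * m`.
#'
#' @param name One of `"frozen"`, `"geometric"`, `"single_complication"`.
#' @param p,h,m Toy probabilities (see above).
#' @param horizon_years Cycles (default 20).
#' @return An `htn_params` object.
#' @export
generate_toy_model <- function(name = c("frozen", "geometric",
                                        "single_complication"),
                               p = 0.1, h = 0.2, m = 0.15,
                               horizon_years = 20L) {
  name <- match.arg(name)
  ps <- load_parameters(htncea_example_config())
  ps <- walk_params(ps, function(pp, path) {
    root <- path[1L]
    pp$value <- if (root %in% c("transition", "hazards", "costs")) 0
      else if (root == "utilities") 1
      else pp$value
    pp$dist <- dist_point(pp$value)
    pp$source <- "synthetic"
    pp
  })
  ps$economics$horizon_years <- as.integer(horizon_years)
  ps$risk_model$group_scores <- c(low = 0, mid = 0, high = 0)
  ps$risk_model$group_weights <- c(low = 0, mid = 1, high = 0)
  ps$state_costs <- lapply(ps$state_costs, function(x) character())
  ps$strategies <- list(usual_care = list(rules = list()))
  isd <- c(normal = 0, pre_hypertension = 0, stage1 = 0, stage2 = 0)
  if (name == "geometric") {
    ps$transition$p_pre_to_stage1$value <- p
    ps$transition$p_pre_to_stage1$dist <- dist_point(p)
    isd["pre_hypertension"] <- 1
  } else if (name == "single_complication") {
    ps$hazards$mi$stage2$value <- h
    ps$hazards$mi$stage2$dist <- dist_point(h)
    ps$hazards$mi$mortality_immediate$value <- m
    ps$hazards$mi$mortality_immediate$dist <- dist_point(m)
    isd["stage2"] <- 1
  } else {
    isd["normal"] <- 1
  }
  ps$economics$initial_state_distribution <- isd
  ps
}

#' Reference comparison table on the bundled configuration
#'
#' Runs all four strategies deterministically on the bundled assumption
#' configuration and returns (optionally writes) the comparison table:
#' strategy, discounted cost, QALYs, increments, ICUR and quadrant versus
#' usual care. This is a regression fixture for the pipeline, not a
#' reproduction of any published totals (the published transition
#' probabilities, prevalence and utility weights are not public).
#'
#' @param seed Integer seed (the deterministic base case consumes no random
#'   numbers; the seed is recorded for manifest purposes).
#' @param path Optional CSV output path.
#' @param config Configuration file (default the bundled one).
#' @return The comparison table (data.frame), invisibly if `path` is given.
#' @export
make_reference_run <- function(seed = 1L, path = NULL,
                               config = htncea_example_config()) {
  ps <- load_parameters(config)
  tab <- cea_table(htn_cea(ps))
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE, na = "")
    return(invisible(tab))
  }
  tab
}
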