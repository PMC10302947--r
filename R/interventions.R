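# Prevention strategies: mapping (disease state, risk group) to intervention
# bundles and converting blood-pressure lowering into hazard ratios.

#' Convert a systolic blood-pressure reduction into a hazard ratio
#'
#' Uses the log-linear epidemiological relation in which vascular risk
#' halves for every 20 mm Hg reduction in usual systolic pressure:
#' `HR = 2^(-delta_sbp / 20)`.
#'
#' @param delta_sbp Non-negative reduction in systolic pressure (mm Hg).
#' @return Hazard ratio in (0, 1].
#' @export
bp_reduction_to_hazard_ratio <- function(delta_sbp) {
  if (any(delta_sbp < 0)) stop("delta_sbp must be non-negative")
  2^(-delta_sbp / 20)
}

#' Population-level hazard ratio under partial compliance
#'
#' Compliance acts as an all-or-nothing mixture: a fraction `compliance`
#' of the cohort receives the full effect `hr`, the rest none, so the
#' population-level ratio is `compliance * hr + (1 - compliance)`.
#'
#' @param hr Hazard ratio in (0, 1] for full compliance.
#' @param compliance Probability of compliance in \[0, 1\].
#' @return Effective hazard ratio.
#' @export
effective_hazard_ratio <- function(hr, compliance) {
  stopifnot(all(hr > 0), all(hr <= 1), all(compliance >= 0),
            all(compliance <= 1))
  compliance * hr + (1 - compliance)
}

# Effective hazard ratio per disease state under one strategy for one risk
# group: the product over all applicable rules of the compliance-mixed,
# BP-derived ratio.  Also returns the per-state annual intervention cost
# (charged to everyone offered the bundle, compliant or not).
strategy_modifiers <- function(ps, strategy, group) {
  if (is.character(strategy)) {
    if (!strategy %in% names(ps$strategies))
      stop("unknown strategy: ", strategy)
    strategy <- ps$strategies[[strategy]]
  }
  states <- disease_states()
  hr <- stats::setNames(rep(1, 4), states)
  cost <- stats::setNames(rep(0, 4), states)
  for (r in strategy$rules) {
    if (!is.null(group) && !group %in% r$groups) next
    bad <- setdiff(r$bundle, cost_items())
    if (length(bad)) stop("unknown bundle cost item(s): ",
                          paste(bad, collapse = ", "))
    comp <- p_value(ps$compliance[[r$compliance]])
    bundle_cost <- sum(vapply(r$bundle, function(k) p_value(ps$costs[[k]]),
                              numeric(1)))
    for (s in r$states) {
      ds <- p_value(ps$efficacy$sbp_reduction[[s]])
      hr[s] <- hr[s] *
        effective_hazard_ratio(bp_reduction_to_hazard_ratio(ds), comp)
      cost[s] <- cost[s] + bundle_cost
    }
  }
  list(hr = hr, cost = cost)
}

#' Apply a prevention strategy to a parameter set
#'
#' Scales the progression probabilities and the complication hazards of
#' every disease state covered by the strategy's rules (for the given risk
#' group) by the effective hazard ratio, on the rate scale
#' (`p' = 1 - (1 - p)^HR`), and attaches the per-state annual intervention
#' cost. Blood-pressure lowering through screening and awareness does not
#' act on progression out of stage II (stage II is absorbing in the disease
#' space), but treatment efficacy still lowers stage II complication
#' hazards. The regression probability (pre to normal) is not modified.
#'
#' @param ps An `htn_params` object.
#' @param strategy A strategy name from [strategy_names()] or a strategy
#'   spec (list with a `rules` element).
#' @param group Risk group label (`"low"`, `"mid"`, `"high"`) or `NULL` for
#'   a homogeneous cohort.
#' @return An `htn_params` object with modified transition probabilities and
#'   hazards, plus an `intervention_cost` element (USD/person-year by state).
#' @export
apply_strategy <- function(ps, strategy, group = NULL) {
  stopifnot(inherits(ps, "htn_params"))
  mod <- strategy_modifiers(ps, strategy, group)
  out <- ps
  prog <- c(normal = "p_normal_to_pre", pre_hypertension = "p_pre_to_stage1",
            stage1 = "p_stage1_to_stage2")
  for (s in names(prog)) {
    k <- prog[[s]]
    out$transition[[k]]$value <-
      scale_probability(p_value(ps$transition[[k]]), mod$hr[[s]])
  }
  for (cc in complications()) for (s in disease_states()) {
    out$hazards[[cc]][[s]]$value <-
      scale_probability(p_value(ps$hazards[[cc]][[s]]), mod$hr[[s]])
  }
  out$intervention_cost <- mod$cost
  out
}
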