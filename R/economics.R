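# Deterministic cost-utility comparisons: increments, ICUR, net monetary
# benefit, cost-effectiveness-plane classification.

#' Incremental cost and QALYs of a strategy against a comparator
#'
#' @param comparator,strategy `ce_result` objects (see [accumulate()]) or
#'   lists with `cost` and `qaly` elements. When both carry horizon/discount
#'   metadata the settings must match.
#' @return Named numeric vector `c(d_cost, d_qaly)`.
#' @export
incremental <- function(comparator, strategy) {
  if (!is.null(comparator$horizon) && !is.null(strategy$horizon)) {
    if (comparator$horizon != strategy$horizon ||
        !isTRUE(all.equal(comparator$discount, strategy$discount)))
      stop("comparator and strategy were run with different horizon or ",
           "discount settings")
  }
  c(d_cost = strategy$cost - comparator$cost,
    d_qaly = strategy$qaly - comparator$qaly)
}

#' Incremental cost-utility ratio
#'
#' `d_cost / d_qaly` (USD per QALY gained). Undefined at `d_qaly = 0`;
#' negative ratios are reported verbatim but flag dominance (cheaper and
#' more effective, or costlier and less effective) and are not
#' interpretable as prices. Reports conventionally round to the nearest
#' integer USD.
#'
#' @param d_cost,d_qaly Incremental cost (USD) and QALYs.
#' @return The ratio, unrounded.
#' @export
icur <- function(d_cost, d_qaly) {
  if (any(d_qaly == 0))
    stop("ICUR undefined at d_qaly = 0; report dominance or net monetary ",
         "benefit instead")
  d_cost / d_qaly
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`.
#'
#' @param r A `ce_result` (or list with `cost`, `qaly`).
#' @param wtp Willingness to pay (USD per QALY), `>= 0`; vectorized.
#' @return Numeric NMB(s) in USD.
#' @export
nmb <- function(r, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * r$qaly - r$cost
}

#' Classify a point on the cost-effectiveness plane
#'
#' `dominant` if cheaper and more effective (southeast quadrant),
#' `dominated` if costlier and less effective (northwest), otherwise a
#' trade-off: `trade_off_ne` (costlier, more effective; includes the
#' origin and the non-negative boundary by convention) or `trade_off_sw`
#' (cheaper, less effective).
#'
#' @param d_cost,d_qaly Incremental cost and QALYs (vectorized).
#' @return Character vector of quadrant labels.
#' @export
classify_quadrant <- function(d_cost, d_qaly) {
  ifelse(d_cost < 0 & d_qaly > 0, "dominant",
  ifelse(d_cost > 0 & d_qaly < 0, "dominated",
  ifelse(d_cost >= 0 & d_qaly >= 0, "trade_off_ne", "trade_off_sw")))
}

# Evaluate a set of strategies on one parameter set: each strategy is run
# for every risk group with positive weight and aggregated by group weight,
# so all strategies face the same heterogeneous cohort.
evaluate_strategies <- function(ps, strategies = strategy_names(ps),
                                horizon = ps$economics$horizon_years,
                                rate = p_value(ps$economics$discount_rate)) {
  gw <- ps$risk_model$group_weights
  groups <- names(gw)[gw > 0]
  res <- lapply(strategies, function(s) {
    cost <- 0; qaly <- 0
    for (g in groups) {
      ce <- accumulate(run_cohort(ps, s, g, horizon), rate)
      cost <- cost + gw[[g]] * ce$cost
      qaly <- qaly + gw[[g]] * ce$qaly
    }
    data.frame(strategy = s, cost = cost, qaly = qaly,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Deterministic cost-utility analysis of the prevention strategies
#'
#' Runs the cohort model for every strategy over the risk-group mixture
#' defined in the configuration (so all strategies face the same
#' heterogeneous cohort), accumulates discounted costs and QALYs, and
#' compares each strategy with the comparator.
#'
#' @param ps An `htn_params` object.
#' @param strategies Strategy names; defaults to all configured strategies.
#' @param comparator Reference strategy (default `"usual_care"`).
#' @param horizon,rate Override the configured horizon (years) or annual
#'   discount rate.
#' @return Object of class `htn_cea` with elements `results` (strategy,
#'   cost, qaly) and `comparisons` (d_cost, d_qaly, icur, quadrant).
#' @export
htn_cea <- function(ps, strategies = strategy_names(ps),
                    comparator = "usual_care",
                    horizon = ps$economics$horizon_years,
                    rate = p_value(ps$economics$discount_rate)) {
  stopifnot(inherits(ps, "htn_params"))
  if (!comparator %in% strategies)
    stop("comparator '", comparator, "' is not among the strategies")
  results <- evaluate_strategies(ps, strategies, horizon, rate)
  comp <- results[results$strategy == comparator, ]
  others <- results[results$strategy != comparator, , drop = FALSE]
  comparisons <- data.frame(
    strategy = others$strategy,
    d_cost = others$cost - comp$cost,
    d_qaly = others$qaly - comp$qaly,
    stringsAsFactors = FALSE)
  comparisons$icur <- ifelse(comparisons$d_qaly == 0, NA_real_,
                             comparisons$d_cost / comparisons$d_qaly)
  comparisons$quadrant <- classify_quadrant(comparisons$d_cost,
                                            comparisons$d_qaly)
  structure(list(results = results, comparisons = comparisons,
                 comparator = comparator, horizon = horizon, discount = rate),
            class = "htn_cea")
}

#' Comparison table of a cost-utility analysis
#'
#' One row per strategy: discounted cost (nearest USD), QALYs (4 decimals),
#' increments and ICUR versus the comparator (blank for the comparator row),
#' and the cost-effectiveness-plane quadrant.
#'
#' @param x An `htn_cea` object.
#' @return A data.frame.
#' @export
cea_table <- function(x) {
  stopifnot(inherits(x, "htn_cea"))
  res <- x$results
  cmp <- x$comparisons[match(res$strategy, x$comparisons$strategy), ]
  data.frame(
    strategy = res$strategy,
    cost = round(res$cost),
    qaly = round(res$qaly, 4),
    increment_cost = round(cmp$d_cost),
    increment_qaly = round(cmp$d_qaly, 4),
    icur = round(cmp$icur),
    quadrant = cmp$quadrant,
    stringsAsFactors = FALSE)
}

#' @export
print.htn_cea <- function(x, ...) {
  cat(sprintf(
    "Cost-utility analysis (%d-year horizon, %.1f%%/yr discount, vs %s)\n",
    x$horizon, 100 * x$discount, x$comparator))
  print(cea_table(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.htn_cea <- function(object, wtp = 100000, ...) {
  tab <- cea_table(object)
  res <- object$results
  tab$nmb <- round(wtp * res$qaly - res$cost)
  cat(sprintf("Net monetary benefit at WTP %s USD/QALY:\n",
              format(wtp, big.mark = ",")))
  print(tab[, c("strategy", "cost", "qaly", "nmb", "quadrant")],
        row.names = FALSE)
  invisible(tab)
}
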