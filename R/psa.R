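# Probabilistic sensitivity analysis: Monte-Carlo over the parameter
# distributions, cost-effectiveness plane, acceptability curves.

#' Run a probabilistic sensitivity analysis
#'
#' Replicate `r` evaluates every strategy on the parameter set drawn with
#' [sample_parameter_set()] and seed `xor(seed, r)`: the same sampled
#' parameters are shared across strategies within a replicate (common
#' random numbers), so incremental quantities are differenced within
#' replicate. Results are reproducible given `seed`.
#'
#' @param ps An `htn_params` object (base-case values plus distributions).
#' @param strategies Strategy names; defaults to all configured.
#' @param n Number of Monte-Carlo replicates (`>= 1`); default 10,000.
#' @param seed Master integer seed.
#' @param comparator Reference strategy for increments.
#' @param horizon Cycles per run; defaults to the configured horizon.
#' @return Object of class `htn_psa`: replicate-by-strategy matrices
#'   `cost`, `qaly`, `d_cost`, `d_qaly`, plus `n`, `seed`, `comparator`.
#' @export
run_psa <- function(ps, strategies = strategy_names(ps), n = 10000L,
                    seed = 1L, comparator = "usual_care",
                    horizon = ps$economics$horizon_years) {
  stopifnot(inherits(ps, "htn_params"), n >= 1L)
  if (!comparator %in% strategies)
    stop("comparator '", comparator, "' is not among the strategies")
  seed <- as.integer(seed)
  cost <- matrix(NA_real_, n, length(strategies),
                 dimnames = list(NULL, strategies))
  qaly <- cost
  for (r in seq_len(n)) {
    psr <- sample_parameter_set(ps, bitwXor(seed, r))
    # the sampled discount rate is applied to that replicate's totals
    res <- evaluate_strategies(psr, strategies, horizon,
                               rate = p_value(psr$economics$discount_rate))
    cost[r, ] <- res$cost[match(strategies, res$strategy)]
    qaly[r, ] <- res$qaly[match(strategies, res$strategy)]
  }
  structure(list(
    n = n, seed = seed, strategies = strategies, comparator = comparator,
    horizon = horizon, cost = cost, qaly = qaly,
    d_cost = cost - cost[, comparator],
    d_qaly = qaly - qaly[, comparator]),
    class = "htn_psa")
}

#' @export
print.htn_psa <- function(x, ...) {
  cat(sprintf("PSA: %d replicates (seed %d), comparator %s\n",
              x$n, x$seed, x$comparator))
  for (s in setdiff(x$strategies, x$comparator)) {
    cat(sprintf(
      "  %s: mean d_cost %.0f USD, mean d_qaly %.4f, P(dominant) %.2f\n",
      s, mean(x$d_cost[, s]), mean(x$d_qaly[, s]),
      mean(x$d_cost[, s] < 0 & x$d_qaly[, s] > 0)))
  }
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that a strategy is
#' cost-effective is the fraction of replicates in which its net monetary
#' benefit exceeds the comparator's; ties count 0.5, so in a two-way
#' comparison the two curves sum to 1.
#'
#' @param psa An `htn_psa` object.
#' @param wtp_grid Strictly increasing WTP grid (USD/QALY); default 0 to
#'   300,000 in steps of 10,000.
#' @return Object of class `htn_ceac`: a data.frame with column `wtp` and
#'   one probability column per non-comparator strategy.
#' @export
compute_ceac <- function(psa, wtp_grid = seq(0, 300000, by = 10000)) {
  stopifnot(inherits(psa, "htn_psa"), psa$n >= 1L)
  if (any(diff(wtp_grid) <= 0)) stop("wtp_grid must be strictly increasing")
  others <- setdiff(psa$strategies, psa$comparator)
  out <- data.frame(wtp = wtp_grid)
  for (s in others) {
    out[[s]] <- vapply(wtp_grid, function(w) {
      d_nmb <- w * psa$d_qaly[, s] - psa$d_cost[, s]
      mean((d_nmb > 0) + 0.5 * (d_nmb == 0))
    }, numeric(1))
  }
  structure(out, class = c("htn_ceac", "data.frame"))
}

#' Cost-effectiveness plane scatter table
#'
#' @param psa An `htn_psa` object.
#' @return Tidy data.frame: `replicate`, `strategy`, `d_cost`, `d_qaly`,
#'   `quadrant`.
#' @export
export_ce_plane <- function(psa) {
  stopifnot(inherits(psa, "htn_psa"))
  others <- setdiff(psa$strategies, psa$comparator)
  if (!length(others))
    stop("no strategies to plot: the PSA contains only the comparator")
  rows <- lapply(others, function(s) {
    data.frame(replicate = seq_len(psa$n), strategy = s,
               d_cost = psa$d_cost[, s], d_qaly = psa$d_qaly[, s],
               quadrant = classify_quadrant(psa$d_cost[, s],
                                            psa$d_qaly[, s]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot the PSA scatter on the cost-effectiveness plane
#'
#' @param x An `htn_psa` object.
#' @param strategies Strategies to show (default all non-comparator).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.htn_psa <- function(x, strategies = setdiff(x$strategies, x$comparator),
                         ...) {
  pl <- export_ce_plane(x)
  pl <- pl[pl$strategy %in% strategies, ]
  cols <- stats::setNames(seq_along(strategies) + 1L, strategies)
  graphics::plot(pl$d_qaly, pl$d_cost, col = cols[pl$strategy], pch = 16,
                 cex = 0.5, xlab = "Incremental QALYs",
                 ylab = "Incremental cost (USD)",
                 main = paste("CE plane vs", x$comparator), ...)
  graphics::abline(h = 0, v = 0, lty = 2)
  graphics::legend("topleft", legend = strategies, col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param x An `htn_ceac` object.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.htn_ceac <- function(x, ...) {
  strategies <- setdiff(names(x), "wtp")
  graphics::matplot(x$wtp, as.matrix(x[, strategies, drop = FALSE]),
                    type = "l", lty = 1, lwd = 2,
                    col = seq_along(strategies) + 1L,
                    xlab = "Willingness to pay (USD/QALY)",
                    ylab = "Probability cost-effective", ylim = c(0, 1), ...)
  graphics::legend("bottomright", legend = strategies, lwd = 2,
                   col = seq_along(strategies) + 1L, bty = "n")
  invisible(x)
}
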