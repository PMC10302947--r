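# Annual-cycle deterministic cohort engine over the full state space:
# 4 disease states x 8 complication combinations (alive) + dead.
#
# Within-cycle update order:
#   1. disease-state transition,
#   2. complication events drawn per current disease state (independent
#      hazards; joint events generate the combined complication nodes),
#   3. immediate complication mortality applied to incident events,
#   4. yearly mortality applied to prevalent complication carriers.
# Acquired complications persist for life.

comp_mask_matrix <- function() {
  m <- t(vapply(0:7, function(b) {
    c(bitwAnd(b, 1L) > 0L, bitwAnd(b, 2L) > 0L, bitwAnd(b, 4L) > 0L)
  }, logical(3)))
  colnames(m) <- complications()
  m
}

comp_mask_labels <- function() {
  has <- comp_mask_matrix()
  vapply(seq_len(8), function(k) {
    cc <- complications()[has[k, ]]
    if (!length(cc)) "none" else paste(cc, collapse = "+")
  }, character(1))
}

# Per disease state: 8x8 alive-to-alive kernel over complication sets,
# per-set death probability, and per-set expected event cost.
build_complication_kernel <- function(h, m_imm, m_yr, event_cost) {
  has <- comp_mask_matrix()
  A <- matrix(0, 8, 8)
  evcost <- numeric(8)
  for (k in seq_len(8)) {
    carried <- which(has[k, ])
    free <- which(!has[k, ])
    surv_prev <- prod(1 - m_yr[carried])
    evcost[k] <- sum(h[free] * event_cost[free])
    nf <- length(free)
    for (jbits in 0:(2^nf - 1L)) {
      J <- free[bitwAnd(jbits, 2^(seq_len(nf) - 1L)) > 0L]
      p_j <- prod(h[J]) * prod(1 - h[setdiff(free, J)])
      kk <- k + sum(2^(J - 1L))
      A[k, kk] <- A[k, kk] + p_j * prod(1 - m_imm[J]) * surv_prev
    }
  }
  list(A = A, death = 1 - rowSums(A), evcost = evcost)
}

#' Discount factor for an annual cycle
#'
#' `(1 + rate)^(-t)`; cycle-0 flows are undiscounted.
#'
#' @param rate Annual discount rate (fraction), `>= 0`.
#' @param t Cycle index (vectorized), `>= 0`.
#' @return Numeric discount factor(s).
#' @export
discount_factor <- function(rate, t) {
  stopifnot(rate >= 0, all(t >= 0))
  (1 + rate)^(-t)
}

#' Run the deterministic cohort simulation
#'
#' Propagates a closed cohort through the four-state natural history with
#' complication and mortality sub-models for `horizon` one-year cycles,
#' under a prevention strategy, accumulating per-cycle cost and utility
#' flows. Costs and utilities are counted at cycle end (cycles `1..T`);
#' cycle 0 holds the initial distribution only and carries zero flows (no
#' half-cycle correction). Terminal care is charged once, in the cycle of a
#' complication death. Complication event costs (admissions) are charged to
#' every incident event; maintenance costs are charged annually to alive
#' carriers from the event cycle onward.
#'
#' @param ps An `htn_params` object.
#' @param strategy Strategy name or spec (default `"usual_care"`).
#' @param group Risk group (`"low"`, `"mid"`, `"high"`) whose score
#'   personalizes the progression rates, or `NULL` for the average-risk
#'   cohort.
#' @param horizon Number of one-year cycles; defaults to the configured
#'   horizon.
#' @return An object of class `cohort_trace`: occupancy matrix
#'   (`horizon + 1` cycles by 33 states, the 33rd being dead), `cost_flow`
#'   and `utility_flow` vectors, and run metadata.
#' @export
run_cohort <- function(ps, strategy = "usual_care", group = NULL,
                       horizon = ps$economics$horizon_years) {
  stopifnot(inherits(ps, "htn_params"), horizon >= 1L)
  strategy_name <- if (is.character(strategy)) strategy else "custom"

  mod <- ps
  if (!is.null(group)) {
    score <- ps$risk_model$group_scores[[group]]
    if (is.null(score)) stop("unknown risk group: ", group)
    pr <- personalize_rates(ps$transition, score,
                            ps$risk_model$modify_regression)
    for (k in names(pr)) mod$transition[[k]]$value <- pr[[k]]
  }
  mod <- apply_strategy(mod, strategy, group)

  M <- build_transition_matrix(mod$transition)
  states <- disease_states()
  comps <- complications()
  kernels <- lapply(states, function(s) {
    build_complication_kernel(
      h     = vapply(comps, function(cc) p_value(mod$hazards[[cc]][[s]]),
                     numeric(1)),
      m_imm = vapply(comps, function(cc)
        p_value(mod$hazards[[cc]]$mortality_immediate), numeric(1)),
      m_yr  = vapply(comps, function(cc)
        p_value(mod$hazards[[cc]]$mortality_yearly), numeric(1)),
      event_cost = c(mi = p_value(mod$costs$mi_admission),
                     stroke = p_value(mod$costs$stroke_admission),
                     esrd = 0))
  })
  names(kernels) <- states

  maint <- {
    has <- comp_mask_matrix()
    mc <- c(mi = p_value(mod$costs$mi_visit),
            stroke = p_value(mod$costs$stroke_visit),
            esrd = p_value(mod$costs$esrd_annual))
    as.numeric(has %*% mc)
  }
  state_cost <- vapply(states, function(s) {
    sum(vapply(mod$state_costs[[s]], function(k) p_value(mod$costs[[k]]),
               numeric(1)))
  }, numeric(1))
  iv_cost <- mod$intervention_cost
  terminal <- p_value(mod$costs$terminal_care)

  uw <- vapply(states, function(s) p_value(mod$utilities$state[[s]]),
               numeric(1))
  cw <- vapply(comps, function(cc) p_value(mod$utilities$complication[[cc]]),
               numeric(1))
  has <- comp_mask_matrix()
  combo <- vapply(seq_len(8), function(k) {
    w <- cw[has[k, ]]
    if (!length(w)) 1
    else if (mod$utilities$combination_rule == "minimum") min(w)
    else prod(w)
  }, numeric(1))
  util <- outer(uw, combo)  # 4 x 8

  U <- matrix(0, 4, 8, dimnames = list(states, comp_mask_labels()))
  U[, 1] <- ps$economics$initial_state_distribution[states]
  dead <- 0

  n_cycles <- horizon + 1L
  occ <- matrix(0, n_cycles, 33)
  colnames(occ) <- c(as.vector(outer(states, comp_mask_labels(), paste,
                                     sep = ".")), "dead")
  cost_flow <- numeric(n_cycles)
  utility_flow <- numeric(n_cycles)
  occ[1L, ] <- c(as.vector(U), dead)

  for (t in seq_len(horizon)) {
    U1 <- crossprod(M, U)                       # disease transition
    ev_cost <- 0
    U2 <- U1
    for (d in seq_len(4)) {
      kr <- kernels[[d]]
      ev_cost <- ev_cost + sum(U1[d, ] * kr$evcost)
      U2[d, ] <- as.numeric(U1[d, ] %*% kr$A)
    }
    deaths <- sum(U1) - sum(U2)
    dead <- dead + deaths
    total <- sum(U2) + dead
    if (abs(total - 1) > 1e-9)
      stop(sprintf("mass conservation violated at cycle %d (total = %.12f)",
                   t, total))
    cost_flow[t + 1L] <- ev_cost + deaths * terminal +
      sum(U2 * matrix(state_cost + iv_cost, 4, 8)) +
      sum(U2 %*% maint)
    utility_flow[t + 1L] <- sum(U2 * util)
    U <- U2
    occ[t + 1L, ] <- c(as.vector(U), dead)
  }

  structure(list(occupancy = occ, cost_flow = cost_flow,
                 utility_flow = utility_flow, horizon = horizon,
                 strategy = strategy_name, group = group,
                 discount_rate = p_value(ps$economics$discount_rate)),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace: strategy %s%s, %d cycles\n", x$strategy,
              if (is.null(x$group)) "" else paste0(" (", x$group, " risk)"),
              x$horizon))
  cat(sprintf("  dead mass at horizon: %.4f\n",
              x$occupancy[nrow(x$occupancy), "dead"]))
  cat(sprintf("  undiscounted totals: cost %.0f, QALY %.4f\n",
              sum(x$cost_flow), sum(x$utility_flow)))
  invisible(x)
}

#' Tidy per-cycle trace
#'
#' @param x A `cohort_trace`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return Long data.frame with columns `cycle`, `state`, `occupancy`,
#'   `cost_flow`, `utility_flow` (flows repeated within a cycle).
#' @export
as.data.frame.cohort_trace <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  n <- nrow(x$occupancy)
  states <- colnames(x$occupancy)
  data.frame(
    cycle = rep(0:(n - 1L), times = length(states)),
    state = rep(states, each = n),
    occupancy = as.vector(x$occupancy),
    cost_flow = rep(x$cost_flow, times = length(states)),
    utility_flow = rep(x$utility_flow, times = length(states)),
    stringsAsFactors = FALSE)
}

#' Total disease-state occupancy (summed over complication sets)
#'
#' @param trace A `cohort_trace`.
#' @return Matrix of cycles by the four disease states plus dead.
#' @export
disease_occupancy <- function(trace) {
  occ <- trace$occupancy
  states <- disease_states()
  out <- sapply(states, function(s) {
    rowSums(occ[, grep(paste0("^", s, "\\."), colnames(occ)), drop = FALSE])
  })
  cbind(out, dead = occ[, "dead"])
}

#' Discounted totals of a cohort trace
#'
#' `cost = sum_t cost_flow(t) / (1 + rate)^t`, and likewise for QALYs.
#'
#' @param trace A `cohort_trace`.
#' @param rate Annual discount rate; defaults to the rate the trace was run
#'   with.
#' @return Object of class `ce_result`: `strategy`, `cost`, `qaly`,
#'   `horizon`, `discount`.
#' @export
accumulate <- function(trace, rate = trace$discount_rate) {
  stopifnot(inherits(trace, "cohort_trace"), rate >= 0)
  t <- 0:trace$horizon
  df <- discount_factor(rate, t)
  structure(list(strategy = trace$strategy,
                 cost = sum(trace$cost_flow * df),
                 qaly = sum(trace$utility_flow * df),
                 horizon = trace$horizon, discount = rate),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("%s: discounted cost %.0f USD, %.4f QALYs (%d y, %.1f%%/y)\n",
              x$strategy, x$cost, x$qaly, x$horizon, 100 * x$discount))
  invisible(x)
}
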