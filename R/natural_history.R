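# Four-state natural history: normal -> pre-hypertension -> stage I -> stage II,
# with regression pre -> normal only (no regression past stage I).

#' Build the annual disease-state transition matrix
#'
#' Rows and columns follow [disease_states()]. Only four off-diagonal cells
#' may be nonzero: normal to pre-hypertension, pre-hypertension to normal,
#' pre-hypertension to stage I, and stage I to stage II; stage II is
#' absorbing within the disease space. Diagonals complete each row to 1.
#'
#' @param tr Either the `transition` block of an `htn_params` object or a
#'   named list/vector with elements `p_normal_to_pre`, `p_pre_to_stage1`,
#'   `p_stage1_to_stage2`, `p_pre_to_normal`.
#' @return A 4 x 4 row-stochastic matrix.
#' @export
build_transition_matrix <- function(tr) {
  g <- function(k) {
    v <- p_value(tr[[k]])
    if (is.null(v) || !is.finite(v) || v < 0 || v > 1)
      stop("transition probability ", k, " must be in [0, 1]")
    v
  }
  p_np <- g("p_normal_to_pre")
  p_ps <- g("p_pre_to_stage1")
  p_ss <- g("p_stage1_to_stage2")
  p_pn <- g("p_pre_to_normal")
  if (p_ps + p_pn > 1 + 1e-12)
    stop("pre_hypertension row exit probabilities sum to ", p_ps + p_pn,
         " > 1")
  s <- disease_states()
  m <- matrix(0, 4, 4, dimnames = list(s, s))
  m["normal", "pre_hypertension"] <- p_np
  m["pre_hypertension", "normal"] <- p_pn
  m["pre_hypertension", "stage1"] <- p_ps
  m["stage1", "stage2"] <- p_ss
  diag(m) <- 1 - rowSums(m)
  m
}

#' Linear state-specific risk score
#'
#' The score is `intercept + sum(weights * covariates)`, matched by name;
#' `exp(score)` acts as a multiplier on the progression rates (see
#' [personalize_rates()]), the proportional-hazards convention of multistate
#' regression models.
#'
#' @param profile Named numeric vector (or a data.frame of such rows) of
#'   covariate values.
#' @param weights Named numeric vector of log-rate-ratio weights.
#' @param intercept Scalar intercept (default 0).
#' @return Numeric score(s).
#' @export
risk_score <- function(profile, weights, intercept = 0) {
  if (is.data.frame(profile)) {
    miss <- setdiff(names(weights), names(profile))
    if (length(miss))
      stop("covariates missing from profile: ", paste(miss, collapse = ", "))
    return(intercept +
             as.numeric(as.matrix(profile[, names(weights), drop = FALSE]) %*%
                          weights))
  }
  miss <- setdiff(names(weights), names(profile))
  extra <- setdiff(names(profile), names(weights))
  if (length(miss) || length(extra))
    stop("profile/weight name mismatch; unmatched: ",
         paste(c(miss, extra), collapse = ", "))
  as.numeric(intercept + sum(weights * profile[names(weights)]))
}

#' Assign risk groups by score cutoffs
#'
#' `low` if `score < cutoffs[1]`, `mid` if `cutoffs[1] <= score <
#' cutoffs[2]`, `high` otherwise.
#'
#' @param scores Numeric vector of risk scores.
#' @param cutoffs Strictly increasing numeric pair. The default splits at
#'   the empirical tertiles of `scores`.
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
stratify <- function(scores, cutoffs = stats::quantile(scores, c(1, 2) / 3)) {
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) != 2L || !(cutoffs[1] < cutoffs[2]))
    stop("cutoffs must be a strictly increasing pair")
  lab <- ifelse(scores < cutoffs[1], "low",
                ifelse(scores < cutoffs[2], "mid", "high"))
  factor(lab, levels = risk_groups())
}

# Rate-scale scaling of an annual probability: multiply the underlying
# constant rate by m, i.e. p' = 1 - (1 - p)^m.  Keeps p' in [0, 1] for any
# m >= 0, unlike naive multiplication.
scale_probability <- function(p, m) {
  pmin(pmax(1 - (1 - p)^m, 0), 1)
}

#' Personalize transition rates by a risk score
#'
#' Each progression probability is scaled on the rate scale by the
#' multiplier `exp(score)`: `p' = 1 - (1 - p)^exp(score)`. The regression
#' probability (pre-hypertension to normal) is left unchanged unless
#' `modify_regression` is `TRUE`, in which case it is scaled by
#' `exp(-score)` (higher-risk individuals regress less).
#'
#' @param tr Transition block as in [build_transition_matrix()].
#' @param score Finite risk score.
#' @param modify_regression Logical; default `FALSE`.
#' @return A list with the four transition probabilities (plain numerics).
#' @export
personalize_rates <- function(tr, score, modify_regression = FALSE) {
  stopifnot(is.finite(score))
  m <- exp(score)
  out <- list(
    p_normal_to_pre   = scale_probability(p_value(tr[["p_normal_to_pre"]]), m),
    p_pre_to_stage1   = scale_probability(p_value(tr[["p_pre_to_stage1"]]), m),
    p_stage1_to_stage2 = scale_probability(p_value(tr[["p_stage1_to_stage2"]]), m),
    p_pre_to_normal   = p_value(tr[["p_pre_to_normal"]]))
  if (modify_regression)
    out$p_pre_to_normal <- scale_probability(out$p_pre_to_normal, exp(-score))
  out
}
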