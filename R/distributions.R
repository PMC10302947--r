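#' Uncertainty distributions for model parameters
#'
#' Every model input carries a base-case value and, optionally, an
#' uncertainty distribution used by the probabilistic sensitivity analysis.
#' Three kinds are supported: `beta` (for probabilities), `triangular`
#' (for costs and the discount rate) and `point` (a degenerate mass; the
#' value is never resampled).
#'
#' @param alpha,beta Positive shape parameters of the Beta distribution.
#' @param low,mode,high Triangular distribution support and mode, with
#'   `low <= mode <= high`.
#' @param value The fixed value of a point mass.
#' @return An object of class `htn_dist`.
#' @examples
#' distribution_mean(dist_beta(30, 9970))   # 0.003
#' distribution_mean(dist_triangular(0, 0.03, 0.05))
#' @name distributions
NULL

new_dist <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "htn_dist")
}

#' @rdname distributions
#' @export
dist_beta <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha <= 0 || beta <= 0)
    stop("beta distribution requires alpha > 0 and beta > 0, got (",
         alpha, ", ", beta, ")")
  new_dist("beta", alpha = alpha, beta = beta)
}

#' @rdname distributions
#' @export
dist_triangular <- function(low, mode, high) {
  if (!(low <= mode && mode <= high))
    stop("triangular distribution requires low <= mode <= high, got (",
         low, ", ", mode, ", ", high, ")")
  new_dist("triangular", low = low, mode = mode, high = high)
}

#' @rdname distributions
#' @export
dist_point <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  new_dist("point", value = value)
}

#' @export
print.htn_dist <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.htn_dist <- function(x, ...) {
  switch(x$kind,
    beta       = sprintf("Beta(%g, %g)", x$alpha, x$beta),
    triangular = sprintf("Triangular(%g, %g, %g)", x$low, x$mode, x$high),
    point      = sprintf("Point(%g)", x$value))
}

#' Closed-form mean of an uncertainty distribution
#'
#' Beta: `alpha / (alpha + beta)`. Triangular: `(low + mode + high) / 3`.
#' Point: the value itself.
#'
#' @param d An [`htn_dist`][distributions] object.
#' @return A single number.
#' @export
distribution_mean <- function(d) {
  stopifnot(inherits(d, "htn_dist"))
  switch(d$kind,
    beta       = d$alpha / (d$alpha + d$beta),
    triangular = (d$low + d$mode + d$high) / 3,
    point      = d$value)
}

#' Draw random variates from an uncertainty distribution
#'
#' Beta draws use [stats::rbeta()]. Triangular draws use the inverse-CDF
#' transform of a uniform variate. Point masses return the value, consuming
#' no random numbers.
#'
#' @param d An [`htn_dist`][distributions] object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(d, n = 1L) {
  stopifnot(inherits(d, "htn_dist"), n >= 1L)
  switch(d$kind,
    point = rep(d$value, n),
    beta  = stats::rbeta(n, d$alpha, d$beta),
    triangular = {
      u <- stats::runif(n)
      fc <- if (d$high == d$low) 0.5 else (d$mode - d$low) / (d$high - d$low)
      lower <- u < fc
      out <- numeric(n)
      out[lower]  <- d$low + sqrt(u[lower] * (d$high - d$low) * (d$mode - d$low))
      out[!lower] <- d$high -
        sqrt((1 - u[!lower]) * (d$high - d$low) * (d$high - d$mode))
      # degenerate supports collapse to the mode
      if (d$high == d$low) out[] <- d$mode
      out
    })
}
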