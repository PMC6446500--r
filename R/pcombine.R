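#' Clamp p-values away from 0 and 1
#'
#' The inverse-normal transform diverges at 0 and 1, so every p-value entering
#' the combiner is first clamped into `[eps, 1 - eps]`. Clamping preserves the
#' ordering of p-values and keeps normal scores finite.
#'
#' @param p Numeric vector of probabilities.
#' @param eps Clamping margin; default `1e-15`.
#' @return Numeric vector with all values in `[eps, 1 - eps]`.
#' @export
#' @examples
#' clamp_pvalues(c(0, 0.5, 1))
clamp_pvalues <- function(p, eps = 1e-15) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  pmin(pmax(p, eps), 1 - eps)
}

#' Normal score of a p-value
#'
#' Transforms an (upper-tail) p-value to its standard-normal quantile
#' \eqn{t = \Phi^{-1}(1 - p)}. Small p-values map to large positive scores;
#' the transform is strictly decreasing in `p`.
#'
#' @param p Numeric vector of p-values, already clamped to `[1e-15, 1 - 1e-15]`
#'   (see [clamp_pvalues()]). Non-finite values are a contract violation.
#' @return Numeric vector of normal scores.
#' @seealso [combine_pvalues()]
#' @export
#' @examples
#' normal_score(0.5)    # 0
#' normal_score(0.025)  # 1.959964
normal_score <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p))) {
    stop("normal_score() requires finite numeric p-values")
  }
  stats::qnorm(p, lower.tail = FALSE)
}

#' Estimate the common correlation of normal scores
#'
#' Hartung's moment estimator of the common pairwise correlation \eqn{\rho}
#' among a set of dependent normal scores:
#' \deqn{\hat\rho = 1 - \frac{1}{n-1}\sum_i (t_i - \bar t)^2,}
#' clamped to the admissible range `[-1/(n-1), 1]` (a common correlation of
#' `n` variables cannot fall below `-1/(n-1)`). Identical scores give
#' \eqn{\hat\rho = 1}.
#'
#' @param scores Numeric vector of normal scores, length at least 2.
#' @return Estimated correlation in `[-1/(n-1), 1]`.
#' @export
#' @examples
#' estimate_rho(c(1.3, 1.3, 1.3))  # 1
#' estimate_rho(c(0, 1, 2))        # 0
estimate_rho <- function(scores) {
  n <- length(scores)
  if (n < 2) stop("estimate_rho() requires at least 2 scores")
  if (any(!is.finite(scores))) stop("scores must be finite")
  rho <- 1 - stats::var(scores)
  min(max(rho, -1 / (n - 1)), 1)
}

#' Weighted inverse-normal combined statistic
#'
#' Evaluates Hartung's combined statistic for dependent normal scores
#' \eqn{t_i} with positive weights \eqn{\lambda_i} and common correlation
#' \eqn{\rho}:
#' \deqn{t(\rho) = \frac{\sum_i \lambda_i t_i}
#'   {\sqrt{(1-\rho)\sum_i \lambda_i^2 + \rho\,(\sum_i \lambda_i)^2}}.}
#' At \eqn{\rho = 0} with unit weights this is Stouffer's statistic
#' \eqn{\sum t_i / \sqrt n}; at \eqn{\rho = 1} it is the mean score.
#'
#' @param scores Numeric vector of normal scores.
#' @param weights Positive weights, same length as `scores`. Default all 1.
#' @param rho Common correlation. Must leave the denominator positive.
#' @return The value of the statistic (a scalar).
#' @export
combined_statistic <- function(scores, weights = rep(1, length(scores)), rho) {
  n <- length(scores)
  if (n < 1) stop("combined_statistic() requires at least one score")
  if (length(weights) != n) stop("scores and weights must have equal length")
  if (any(weights <= 0)) stop("weights must be positive")
  if (!is.finite(rho)) stop("rho must be finite")
  denom2 <- (1 - rho) * sum(weights^2) + rho * sum(weights)^2
  if (denom2 <= 0) {
    stop("denominator is not positive: rho = ", rho, " is out of range for n = ", n)
  }
  sum(weights * scores) / sqrt(denom2)
}

#' Combine dependent p-values with Hartung's method
#'
#' Transforms p-values to normal scores, estimates their common correlation,
#' and combines them with the weighted inverse-normal statistic. The combined
#' p-value is the upper-tail probability `1 - pnorm(statistic)`.
#'
#' A single p-value is returned unchanged (after clamping); correlation
#' estimation is bypassed and `rho_hat` is recorded as 0. For two or more
#' p-values the correlation is estimated with [estimate_rho()]; because the
#' estimator's lower clamp `-1/(n-1)` makes the denominator of the statistic
#' exactly zero under equal weights, the value actually plugged into the
#' statistic (`rho_used`) is floored at 0. Vicinal genes are modelled as
#' non-negatively correlated replicate measurements of one sub-graph level
#' signal; a negative common correlation would reward discordant score sets.
#' Both the raw clamped estimate and the value used are reported.
#'
#' @param p Numeric vector of p-values (clamped internally).
#' @param weights Positive weights, default all 1. The combined p-value is
#'   invariant under uniform rescaling of the weights.
#' @param rho Optional: force the correlation to this value instead of
#'   estimating it (used e.g. for null calibration at `rho = 0`). Supplied
#'   values are used exactly, with no flooring.
#' @return An object of class `msf_combined`: a list with elements
#'   `statistic`, `rho_hat`, `rho_used`, `combined_p`, `log_p` (the natural
#'   log of `combined_p`, kept to avoid underflow), `n` and `weights`.
#' @export
#' @examples
#' combine_pvalues(0.01)                   # single p passes through
#' combine_pvalues(c(0.5, 0.5))$combined_p # 0.5
#' combine_pvalues(c(0.05, 0.05, 0.05))$combined_p # identical scores: rho = 1
combine_pvalues <- function(p, weights = NULL, rho = NULL) {
  n <- length(p)
  if (n == 0) stop("combine_pvalues() requires at least one p-value")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("p and weights must have equal length")
  if (any(weights <= 0)) stop("weights must be positive")
  pc <- clamp_pvalues(p)
  scores <- normal_score(pc)

  if (n == 1) {
    out <- list(
      statistic = scores, rho_hat = 0, rho_used = 0,
      combined_p = pc, log_p = log(pc), n = 1L, weights = weights
    )
    class(out) <- "msf_combined"
    return(out)
  }

  rho_hat <- estimate_rho(scores)
  rho_used <- if (is.null(rho)) max(rho_hat, 0) else rho
  statistic <- combined_statistic(scores, weights, rho_used)
  log_p <- stats::pnorm(statistic, lower.tail = FALSE, log.p = TRUE)
  out <- list(
    statistic = statistic, rho_hat = rho_hat, rho_used = rho_used,
    combined_p = exp(log_p), log_p = log_p, n = as.integer(n),
    weights = weights
  )
  class(out) <- "msf_combined"
  out
}

#' @export
print.msf_combined <- function(x, ...) {
  cat(sprintf(
    "Hartung combined score: t = %.4f, rho_hat = %.3f (used %.3f), n = %d, p = %.4g\n",
    x$statistic, x$rho_hat, x$rho_used, x$n, x$combined_p
  ))
  invisible(x)
}

# Fast internal scorer used by the search: works on precomputed normal scores
# and returns log(combined p). Unit weights. Comparisons in the search are on
# the log scale so that deeply significant sub-graphs (p underflows to 0)
# still order strictly.
.logp_scores <- function(scores) {
  n <- length(scores)
  if (n == 1L) return(stats::pnorm(scores, lower.tail = FALSE, log.p = TRUE))
  rho <- 1 - stats::var(scores)
  rho <- min(max(rho, 0), 1)
  stat <- sum(scores) / sqrt((1 - rho) * n + rho * n * n)
  stats::pnorm(stat, lower.tail = FALSE, log.p = TRUE)
}
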