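# Trend testing, angle summaries and the two-group sample-size formula,
# implemented from the defining formulas (normal equations, t distribution,
# standard-normal quantiles).

#' Ordinary least-squares trend with a t-test on the slope
#'
#' Slope and intercept from the normal equations; two-sided p-value for
#' the slope from the t distribution with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3; `x` must vary.
#' @return object of class `trend_result`: `slope`, `intercept`,
#'   `t_statistic`, `p_value`, `n`.
#' @export
linear_trend <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need n >= 3 observations", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) stop("x is constant; trend undefined", call. = FALSE)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  rss <- sum((y - intercept - slope * x)^2)
  se <- sqrt(rss / (n - 2L) / sxx)
  tval <- if (se == 0) sign(slope) * Inf else slope / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2L)
  structure(list(slope = slope, intercept = intercept, t_statistic = tval,
                 p_value = p, n = n), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("linear trend: slope %.4g (t = %.3g, p = %.3g, n = %d)\n",
              x$slope, x$t_statistic, x$p_value, x$n))
  invisible(x)
}

#' Sample size for comparing two means
#'
#' Normal-approximation formula for two independent groups with common
#' standard deviation:
#' `n = ceil( 2 (z_{1-alpha/2} + z_{power})^2 sd^2 / (mu_a - mu_b)^2 )`
#' per group.
#'
#' @param alpha two-sided significance level.
#' @param power target power (1 - beta).
#' @param mu_a,mu_b group means.
#' @param sd common standard deviation (> 0).
#' @return integer sample size per group.
#' @export
sample_size_two_means <- function(alpha = 0.05, power = 0.8, mu_a, mu_b, sd) {
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1 || sd <= 0) {
    stop("require 0 < alpha < 1, 0 < power < 1, sd > 0", call. = FALSE)
  }
  delta <- mu_a - mu_b
  if (delta == 0) {
    stop("group means are equal: required sample size is unbounded",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling(2 * z^2 * sd^2 / delta^2))
}

#' Linear summary of angle data
#'
#' Arithmetic mean, sample standard deviation and range. Angles are
#' treated linearly (valid for the sub-90-degree axis angles handled here;
#' no wraparound).
#'
#' @param values numeric vector (deg), n >= 2.
#' @return named vector `mean`, `sd`, `min`, `max`.
#' @export
angle_summary <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  m <- sum(values) / n
  s <- sqrt(sum((values - m)^2) / (n - 1L))
  c(mean = m, sd = s, min = min(values), max = max(values))
}
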