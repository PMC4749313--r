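#' @title Hypothesis-test result container
#' @description Internal constructor for the common test-result structure
#'   shared by all tests in the package: the method label, the standardized
#'   statistic, optional degrees of freedom, a two-sided p-value, per-group
#'   sample sizes and a degeneracy flag (set whenever a denominator is zero).
#' @noRd
new_test_result <- function(method, statistic, df = NA_real_, p_value,
                            n_groups, degenerate = FALSE,
                            degenerate_reason = NA_character_) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(
    list(method = method,
         statistic = statistic,
         df = df,
         p_value = p_value,
         n_groups = as.integer(n_groups),
         degenerate = isTRUE(degenerate),
         degenerate_reason = degenerate_reason),
    class = "cnv_test")
}

#' @export
print.cnv_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g", x$method, x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %.4g", x$df))
  cat(sprintf(", p = %.4g, n = (%s)\n", x$p_value,
              paste(x$n_groups, collapse = ", ")))
  if (x$degenerate) cat("  degenerate:", x$degenerate_reason, "\n")
  invisible(x)
}

# Placements of each element of x among y: number of y strictly below,
# with ties counted one half.
fp_placements <- function(x, y) {
  colSums(outer(y, x, "<")) + 0.5 * colSums(outer(y, x, "=="))
}

# Core Fligner-Policello standardized statistic. Returns a list with the
# z value (+/-Inf under complete separation, 0 for the 0/0 case) and the
# degeneracy bookkeeping, shared by the asymptotic and exact routines.
fp_statistic <- function(x, y) {
  px <- fp_placements(x, y)
  py <- fp_placements(y, x)
  n <- length(x); m <- length(y)
  # placements conservation: each (x_i, y_j) pair is counted exactly once
  stopifnot(abs(sum(px) + sum(py) - n * m) < 1e-8)
  pbx <- mean(px); pby <- mean(py)
  vx <- sum((px - pbx)^2); vy <- sum((py - pby)^2)
  num <- sum(py) - sum(px)
  den <- 2 * sqrt(vx + vy + pbx * pby)
  if (den == 0) {
    if (num == 0) {
      list(z = 0, degenerate = TRUE, reason = "zero numerator and denominator")
    } else {
      list(z = sign(num) * Inf, degenerate = TRUE,
           reason = "complete separation (zero variability indices)")
    }
  } else {
    list(z = num / den, degenerate = FALSE, reason = NA_character_)
  }
}

#' Fligner-Policello robust rank order test
#'
#' Tests equality of medians of two samples without assuming equal shapes
#' or variances. Each observation's placement is the count of observations
#' in the other sample lying strictly below it, with ties counted one half;
#' the standardized statistic is
#' \deqn{z = (\sum P(y_j) - \sum P(x_i)) / (2 \sqrt{V_x + V_y + \bar P_x \bar P_y})}
#' where \eqn{V_x, V_y} are the sums of squared deviations of the placements
#' around their group means. The two-sided p-value comes from the standard
#' normal distribution; z is positive when \code{y} tends to be larger.
#'
#' Complete separation drives both variability indices to zero; the result is
#' then flagged degenerate with an infinite statistic and p = 0 so pipelines
#' can continue rather than abort.
#'
#' @param x,y numeric vectors, each with at least one observation.
#' @return a \code{cnv_test} result (method \code{"fligner_policello"}).
#' @references Fligner, M.A. and Policello, G.E. (1981) Robust rank
#'   procedures for the Behrens-Fisher problem. JASA 76, 162-168.
#' @seealso [fligner_policello_exact()] for the exact permutation version.
#' @export
fligner_policello_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L || anyNA(x) || anyNA(y))
    stop("both samples must be non-empty and free of missing values")
  s <- fp_statistic(x, y)
  p <- if (s$degenerate) {
    if (is.infinite(s$z)) 0 else 1
  } else {
    2 * pnorm(-abs(s$z))
  }
  new_test_result("fligner_policello", s$z, NA_real_, p,
                  c(length(x), length(y)), s$degenerate, s$reason)
}

#' Exact permutation Fligner-Policello test
#'
#' Enumerates every reassignment of the pooled observations into groups of
#' the observed sizes and reports the proportion whose absolute
#' Fligner-Policello statistic is at least the observed one. Serves as the
#' exact small-sample oracle for the asymptotic test; limited to
#' \code{length(x) + length(y) <= 14} (at most 3432 relabelings).
#'
#' @inheritParams fligner_policello_test
#' @return a \code{cnv_test} result (method \code{"permutation"}).
#' @export
fligner_policello_exact <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x); m <- length(y); N <- n + m
  if (n < 1L || m < 1L) stop("both samples must be non-empty")
  if (N > 14L)
    stop("exact enumeration limited to n + m <= 14; ",
         "use a Monte Carlo approximation for larger samples")
  pooled <- c(x, y)
  obs <- fp_statistic(x, y)
  combos <- utils::combn(N, n)
  zs <- apply(combos, 2L, function(idx) fp_statistic(pooled[idx], pooled[-idx])$z)
  # Inf >= Inf is TRUE, so complete separation is handled transparently.
  p <- mean(abs(zs) >= abs(obs$z) - 1e-12)
  new_test_result("permutation", obs$z, NA_real_, p, c(n, m),
                  obs$degenerate, obs$reason)
}

#' Fligner-Killeen test of homogeneity of variances
#'
#' Normal-scores form: each observation is centered at its group median,
#' the pooled absolute deviations are ranked (average ranks for ties), and
#' scored \eqn{a_i = \Phi^{-1}(1/2 + r_i / (2(N+1)))}. The statistic
#' \deqn{X^2 = \sum_j n_j (\bar A_j - \bar a)^2 / s^2}
#' (with \eqn{s^2} the sample variance of all scores) is compared to a
#' chi-square distribution on k - 1 degrees of freedom.
#'
#' @param groups list of numeric vectors, at least two groups with at least
#'   two observations each.
#' @return a \code{cnv_test} result (method \code{"fligner_killeen"}).
#' @references Conover, W.J., Johnson, M.E. and Johnson, M.M. (1981) A
#'   comparative study of tests for homogeneity of variances.
#'   Technometrics 23, 351-361.
#' @export
fligner_killeen_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  groups <- lapply(groups, as.numeric)
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop("every group needs at least two observations")
  if (anyNA(unlist(groups))) stop("missing values are not supported")
  k <- length(groups)
  N <- sum(sizes)
  devs <- unlist(lapply(groups, function(g) abs(g - median(g))))
  g <- rep.int(seq_len(k), sizes)
  if (all(devs == 0)) {
    return(new_test_result("fligner_killeen", 0, k - 1, 1, sizes,
                           degenerate = TRUE,
                           degenerate_reason = "all absolute deviations zero"))
  }
  a <- qnorm(0.5 + rank(devs) / (2 * (N + 1)))
  abar <- mean(a)
  s2 <- var(a)
  if (s2 == 0) {
    return(new_test_result("fligner_killeen", 0, k - 1, 1, sizes,
                           degenerate = TRUE,
                           degenerate_reason = "zero score variance"))
  }
  group_means <- tapply(a, g, mean)
  stat <- sum(sizes * (group_means - abar)^2) / s2
  p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  new_test_result("fligner_killeen", stat, k - 1, p, sizes)
}

#' Welch two-sample t test
#'
#' Standard unequal-variance t statistic with Satterthwaite degrees of
#' freedom and a two-sided p-value. Constant samples on both sides give a
#' degenerate result (p = 1 when the means agree, p = 0 otherwise) rather
#' than an error.
#'
#' @param x,y numeric vectors with at least two observations each.
#' @return a \code{cnv_test} result (method \code{"welch_t"}).
#' @export
welch_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x); m <- length(y)
  if (n < 2L || m < 2L) stop("each sample needs at least two observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  vx <- var(x); vy <- var(y)
  se2 <- vx / n + vy / m
  diff <- mean(x) - mean(y)
  if (se2 == 0) {
    if (diff == 0) {
      return(new_test_result("welch_t", 0, NA_real_, 1, c(n, m),
                             TRUE, "both samples constant and equal"))
    }
    return(new_test_result("welch_t", sign(diff) * Inf, NA_real_, 0, c(n, m),
                           TRUE, "both samples constant, unequal means"))
  }
  t <- diff / sqrt(se2)
  df <- se2^2 / ((vx / n)^2 / (n - 1) + (vy / m)^2 / (m - 1))
  p <- 2 * pt(-abs(t), df)
  new_test_result("welch_t", t, df, p, c(n, m))
}

#' Ordinary least-squares fit of y on x
#'
#' Closed-form simple linear regression with vertical residuals and their
#' summary moments, which downstream analyses use to standardize focal
#' deviations. The residual standard deviation uses the n - 1 denominator.
#'
#' @param x,y numeric vectors of equal length, at least three points;
#'   \code{x} must not be constant.
#' @return object of class \code{cnv_ols}: slope, intercept, r_squared,
#'   p_slope, fitted, residuals, residual_mean, residual_sd, n.
#' @export
ols_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3L) stop("need at least three points")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) stop("x is constant; the regression is undefined")
  sxy <- sum((x - xbar) * (y - ybar))
  syy <- sum((y - ybar)^2)
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  fitted <- intercept + slope * x
  resid <- y - fitted
  rss <- sum(resid^2)
  r2 <- if (syy > 0) 1 - rss / syy else 1
  se_slope <- sqrt(rss / (n - 2) / sxx)
  p_slope <- if (se_slope == 0) {
    if (slope == 0) 1 else 0
  } else {
    2 * pt(-abs(slope / se_slope), df = n - 2)
  }
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = max(0, min(1, r2)), p_slope = p_slope,
         fitted = fitted, residuals = resid,
         residual_mean = mean(resid), residual_sd = sd(resid),
         n = n),
    class = "cnv_ols")
}

#' @export
print.cnv_ols <- function(x, ...) {
  cat(sprintf("OLS fit: y = %.4g + %.4g x  (n = %d, R^2 = %.3g, p_slope = %.3g)\n",
              x$intercept, x$slope, x$n, x$r_squared, x$p_slope))
  cat(sprintf("residuals: mean %.3g, sd %.3g\n", x$residual_mean, x$residual_sd))
  invisible(x)
}

#' Serialize a test result to a plain list for JSON reports
#' @param x a \code{cnv_test} object.
#' @return a named list with finite-safe values.
#' @export
as_report <- function(x) {
  UseMethod("as_report")
}

#' @export
as_report.cnv_test <- function(x) {
  list(method = x$method,
       statistic = if (is.finite(x$statistic)) x$statistic else
         as.character(x$statistic),
       df = x$df, p_value = x$p_value, n = x$n_groups,
       degenerate = x$degenerate, degenerate_reason = x$degenerate_reason)
}
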