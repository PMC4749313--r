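# From-scratch test statistics, checked against independent oracles:
# hand-computed closed forms, exact permutation enumeration, and the
# base-R implementations of the classical procedures.

test_that("Fligner-Policello is symmetric on identical samples", {
  r <- fligner_policello_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$degenerate)
})

test_that("Fligner-Policello matches the hand-worked placement example", {
  # placements for {1,2,3} vs {2,3,4}: sums 2 and 7 (conserved: 2+7 = 3*3);
  # z = 5 / (2*sqrt(7/6 + 7/6 + (2/3)(7/3))) = 15 / (2*sqrt(35))
  r <- fligner_policello_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, 15 / (2 * sqrt(35)))
  expect_equal(r$p_value, 2 * pnorm(-15 / (2 * sqrt(35))))
  # exact enumeration over all C(6,3) = 20 relabelings gives p = 1/2
  # (verified by an independent enumeration outside this package)
  e <- fligner_policello_exact(c(1, 2, 3), c(2, 3, 4))
  expect_equal(e$p_value, 0.5)
  expect_equal(e$statistic, r$statistic)
})

test_that("complete separation is flagged degenerate with p = 0", {
  r <- fligner_policello_test(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_true(r$degenerate)
  expect_equal(r$p_value, 0)
  expect_true(is.infinite(r$statistic) && r$statistic > 0)
  # reversed orientation flips the sign
  r2 <- fligner_policello_test(c(10, 11, 12, 13), c(1, 2, 3, 4))
  expect_true(r2$statistic < 0)
})

test_that("Fligner-Policello rejects empty or oversized inputs", {
  expect_error(fligner_policello_test(numeric(0), 1:3), "non-empty")
  expect_error(fligner_policello_exact(1:10, 1:10), "n \\+ m")
})

test_that("asymptotic and exact Fligner-Policello agree on small samples", {
  set.seed(101)
  dps <- replicate(60, {
    n <- sample(4:7, 1); m <- sample(4:7, 1)
    x <- rnorm(n)
    y <- rnorm(m, 0.5)
    a <- fligner_policello_test(x, y)
    e <- fligner_policello_exact(x, y)
    c(dp = abs(a$p_value - e$p_value),
      same_sign = sign(a$statistic) == sign(e$statistic))
  })
  expect_lt(median(dps["dp", ]), 0.05)
  expect_true(all(as.logical(dps["same_sign", ])))
})

test_that("identical constant samples give permutation p = 1", {
  # tied placements keep the denominator positive, so this is a clean
  # (non-degenerate) z = 0
  e <- fligner_policello_exact(c(2, 2, 2), c(2, 2, 2))
  expect_equal(e$p_value, 1)
  expect_equal(e$statistic, 0)
  expect_false(e$degenerate)
})

test_that("Fligner-Killeen matches the base-R implementation", {
  set.seed(33)
  for (i in 1:10) {
    gs <- lapply(sample(2:4, 1) + seq_len(sample(2:3, 1)) * 0,
                 function(k) rnorm(sample(5:40, 1), sd = runif(1, 0.5, 4)))
    mine <- fligner_killeen_test(gs)
    ref <- fligner.test(unlist(gs), factor(rep(seq_along(gs), lengths(gs))))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter))
  }
})

test_that("Fligner-Killeen null and degenerate behaviour", {
  same <- fligner_killeen_test(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  const <- fligner_killeen_test(list(c(5, 5, 5), c(5, 5)))
  expect_true(const$degenerate)
  expect_equal(const$p_value, 1)
  expect_error(fligner_killeen_test(list(1, c(1, 2))), "at least two")
})

test_that("Fligner-Killeen detects a variance difference at fixed seed", {
  set.seed(2024)
  r <- fligner_killeen_test(list(rnorm(50, sd = 1), rnorm(50, sd = 3)))
  expect_lt(r$p_value, 0.05)
})

test_that("FK and Welch are location invariant; FK is scale invariant", {
  set.seed(5)
  x <- rnorm(20, sd = 1); y <- rnorm(25, sd = 2.5)
  fk0 <- fligner_killeen_test(list(x, y))
  fk_shift <- fligner_killeen_test(list(x + 100, y + 100))
  fk_scale <- fligner_killeen_test(list(3 * x, 3 * y))
  expect_equal(fk0$statistic, fk_shift$statistic, tolerance = 1e-10)
  expect_equal(fk0$statistic, fk_scale$statistic, tolerance = 1e-10)
  w0 <- welch_t_test(x, y)
  w_shift <- welch_t_test(x + 100, y + 100)
  expect_equal(w0$statistic, w_shift$statistic, tolerance = 1e-10)
})

test_that("Welch matches the closed form and base t.test", {
  # hand computation: means 2.5 / 3.5, both variances 5/3,
  # se^2 = 5/6, t = -1/sqrt(5/6), df = 6
  w <- welch_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(w$statistic, -1 / sqrt(5 / 6))
  expect_equal(w$df, 6)
  expect_equal(w$p_value, 2 * pt(-1 / sqrt(5 / 6), 6))
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), 0.3, 2)
    mine <- welch_t_test(x, y)
    ref <- t.test(x, y)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_equal(welch_t_test(1:5, 1:5)$statistic, 0)
  expect_error(welch_t_test(1, 1:4), "two observations")
  expect_true(welch_t_test(c(2, 2), c(2, 2))$degenerate)
})

test_that("OLS matches the normal equations and base lm", {
  exact <- ols_fit(0:4, 2 * (0:4) + 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$residuals, rep(0, 5))

  # hand-solved: x = (0,1,2), y = (0,1,0) -> slope 0, intercept 1/3
  tri <- ols_fit(c(0, 1, 2), c(0, 1, 0))
  expect_equal(tri$slope, 0)
  expect_equal(tri$intercept, 1 / 3)
  expect_equal(tri$r_squared, 0)

  set.seed(14)
  x <- runif(40); y <- 1.7 * x - 0.4 + rnorm(40, 0, 0.2)
  mine <- ols_fit(x, y)
  ref <- lm(y ~ x)
  sref <- summary(ref)
  expect_equal(mine$slope, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(mine$intercept, unname(coef(ref)[1]), tolerance = 1e-12)
  expect_equal(mine$r_squared, sref$r.squared, tolerance = 1e-12)
  expect_equal(mine$p_slope, sref$coefficients[2, 4], tolerance = 1e-12)
  expect_equal(mine$residual_mean, 0, tolerance = 1e-10)

  expect_error(ols_fit(rep(1, 5), 1:5), "constant")
  expect_error(ols_fit(1:2, 1:2), "three points")
})
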