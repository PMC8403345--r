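test_that("identical columns give an ICC of exactly one", {
  m <- cbind(c(3, 7, 1, 9, 4), c(3, 7, 1, 9, 4))
  icc <- icc_agreement_single(m)
  expect_equal(icc$estimate, 1.0)
  expect_equal(icc$conf_low, 1.0)
})

test_that("the estimate matches an aov-based computation on random matrices", {
  withr::with_seed(21, {
    for (i in 1:10) {
      n <- sample(4:12, 1)
      M <- matrix(rnorm(2 * n, mean = 10, sd = 5), ncol = 2)
      M[, 2] <- M[, 2] + rnorm(n, sd = 2)
      icc <- icc_agreement_single(M)
      expect_equal(icc$estimate, icc_aov(M), tolerance = 1e-10)
    }
  })
})

test_that("model tag changes only the label, not the estimate or interval", {
  withr::with_seed(4, M <- matrix(rnorm(20, 10, 4), ncol = 2))
  r <- icc_agreement_single(M, model = "random")
  x <- icc_agreement_single(M, model = "mixed")
  expect_equal(r$estimate, x$estimate)
  expect_equal(r$conf_low, x$conf_low)
  expect_equal(r$conf_high, x$conf_high)
  expect_equal(tidy(r)$model, "random")
  expect_equal(tidy(x)$model, "mixed")
})

test_that("confidence intervals bracket the estimate and tighten with n", {
  withr::with_seed(8, {
    s <- rnorm(200, 0, 9)
    M <- cbind(10 + s + rnorm(200, 0, 2), 10 + s + rnorm(200, 0, 2))
  })
  small <- icc_agreement_single(M[1:12, ])
  large <- icc_agreement_single(M)
  for (icc in list(small, large)) {
    expect_lte(icc$conf_low, icc$estimate)
    expect_gte(icc$conf_high, icc$estimate)
    expect_lte(icc$estimate, 1)
  }
  expect_lt(large$conf_high - large$conf_low,
            small$conf_high - small$conf_low)
})

test_that("permuting one rater's values across units destroys agreement", {
  withr::with_seed(13, {
    s <- rnorm(60, 0, 9)
    M <- cbind(10 + s + rnorm(60, 0, 1), 10 + s + rnorm(60, 0, 1))
    icc0 <- icc_agreement_single(M)$estimate
    Mp <- M
    Mp[, 2] <- sample(Mp[, 2])
    icc_perm <- icc_agreement_single(Mp)$estimate
  })
  expect_gt(icc0, 0.95)
  expect_lt(abs(icc_perm), 0.35)
})

test_that("degenerate and insufficient inputs raise typed errors", {
  expect_error(icc_agreement_single(matrix(5, 4, 2)),
               class = "femtor_error_undefined_icc")
  expect_error(icc_agreement_single(matrix(rnorm(2), 1, 2)),
               class = "femtor_error_insufficient")
  expect_error(icc_agreement_single(matrix(rnorm(4), 4, 1)),
               class = "femtor_error_insufficient")
  expect_error(icc_agreement_single(cbind(c(1, NA, 3), c(1, 2, 3))),
               class = "femtor_error_missing")
})

test_that("SEM follows its defining identity", {
  vals <- c(10, 12, 9, 14, 11, 13)
  icc1 <- structure(list(estimate = 1), class = "fem_icc")
  expect_equal(sem_from_icc(vals, icc1), 0)
  icc0 <- structure(list(estimate = 0), class = "fem_icc")
  expect_equal(sem_from_icc(vals, icc0), sd(vals))
  withr::with_seed(2, v <- rnorm(40, 10, 8.81))
  expect_equal(sem_from_icc(v, 0.950), sd(v) * sqrt(0.05))
  expect_error(sem_from_icc(c(1), 0.5), class = "femtor_error_insufficient")
})

test_that("paired differences handle identity, constant shift and real pairs", {
  eq <- paired_difference(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$mean_diff, 0)
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)

  shift <- paired_difference(c(1, 2, 3), c(2, 3, 4))
  expect_equal(shift$mean_diff, 1)
  expect_equal(shift$sd_diff, 0)
  expect_true(shift$degenerate_sd)
  expect_true(is.na(shift$p_value))

  withr::with_seed(3, {
    x <- rnorm(30)
    y <- x + rnorm(30, 0.5, 1)
  })
  pd <- paired_difference(x, y)
  tt <- t.test(y - x)
  expect_equal(pd$t, unname(tt$statistic))
  expect_equal(pd$p_value, tt$p.value)
  expect_equal(pd$df, 29)
  expect_error(paired_difference(c(1, NA), c(2, 3)),
               class = "femtor_error_insufficient")
})
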