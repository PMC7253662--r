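test_that("the log-log improvement fit recovers exact power laws", {
  z <- 10^seq(0, 5, length.out = 40)
  d <- tibble::tibble(prize_size = z, improvement = 0.03 * z^1.0)
  fit <- fit_improvement(d)
  expect_equal(fit$beta0, log10(0.03), tolerance = 1e-6)
  expect_equal(fit$beta1, 1, tolerance = 1e-6)
  d2 <- tibble::tibble(prize_size = z, improvement = 2 * z^0.7)
  fit2 <- fit_improvement(d2)
  expect_equal(fit2$beta1, 0.7, tolerance = 1e-6)
  # constant improvement: zero slope
  flat <- fit_improvement(tibble::tibble(prize_size = z, improvement = 5))
  expect_equal(flat$beta1, 0, tolerance = 1e-8)
  expect_error(fit_improvement(d[1:2, ]), "at least 3")
  expect_error(
    fit_improvement(tibble::tibble(prize_size = 1:3,
                                   improvement = c(1, -1, 1))),
    "positive"
  )
})

test_that("the logistic fit recovers known coefficients within 3 SE", {
  withr::with_seed(123, {
    n <- 5000
    beta <- c(-20, 2.5)
    x <- runif(n, 5, 11)                       # log10 prize in USD
    pgo <- plogis(beta[1] + beta[2] * x)
    d <- tibble::tibble(prize_size = 10^x, go_with = runif(n) < pgo)
    fit <- fit_pgo(d)
    expect_false(fit$separated)
    # prize_size is in the same unit as x here, so coefficients map directly
    expect_lt(abs(fit$beta0 - beta[1]), 3 * fit$se_beta0)
    expect_lt(abs(fit$beta1 - beta[2]), 3 * fit$se_beta1)
    expect_gt(fit$beta1, 0)
  })
})

test_that("degenerate and separated response data are not silently fitted", {
  d <- tibble::tibble(prize_size = 10^(1:10), go_with = rep(TRUE, 10))
  expect_error(fit_pgo(d), "both go and no")
  sep <- tibble::tibble(prize_size = 10^seq(1, 5, length.out = 60))
  sep$go_with <- sep$prize_size > 10^3
  fit <- fit_pgo(sep)
  expect_true(fit$separated)
  expect_true(is.finite(fit$beta0) && is.finite(fit$beta1))
  expect_gt(fit$beta1, 0)
  # the flagged ridge curve still crosses 0.5 near the separation point
  expect_equal(log10(solve_prize(fit, 0.5)), 3, tolerance = 0.5)
})

test_that("prediction and prize solving are exact inverses", {
  fit <- abxfund:::new_abx_fit("pgo_logistic", "ABOM", "P1",
                               beta0 = -6, beta1 = 2.8, n_obs = 100,
                               p_value = 1e-9, separated = FALSE)
  expect_equal(predict_pgo(fit, solve_prize(fit, 0.9)), 0.9,
               tolerance = 1e-9)
  expect_equal(solve_prize(fit, 0.5), 10^(6 / 2.8), tolerance = 1e-12)
  z <- c(1, 10, 100)
  expect_true(all(diff(predict_pgo(fit, z)) > 0))
  expect_true(all(predict_pgo(fit, z) > 0 & predict_pgo(fit, z) < 1))
  expect_error(predict_pgo(fit, -1), "positive")
  expect_error(solve_prize(fit, 1), "strictly between")
  flat <- abxfund:::new_abx_fit("pgo_logistic", "ABOM", "P1", 0, 0, 10,
                                NA, FALSE)
  expect_error(solve_prize(flat, 0.5), "slope is zero")
})

test_that("analytic inversion agrees with brute-force bisection", {
  fit <- abxfund:::new_abx_fit("pgo_logistic", "CUTI", "M1",
                               beta0 = -11.2, beta1 = 3.4, n_obs = 100,
                               p_value = 1e-9, separated = FALSE)
  for (target in c(0.1, 0.5, 0.9, 0.99)) {
    root <- stats::uniroot(
      function(lz) predict_pgo(fit, 10^lz) - target,
      interval = c(-6, 12), tol = 1e-12
    )$root
    expect_equal(solve_prize(fit, target), 10^root, tolerance = 1e-6)
  }
})

test_that("rescaling prize units only shifts the intercept", {
  withr::with_seed(7, {
    n <- 3000
    x <- runif(n, 0, 6)
    y <- runif(n) < plogis(-7 + 2 * x)
    d1 <- tibble::tibble(prize_size = 10^x, go_with = y)
    d2 <- tibble::tibble(prize_size = 1000 * 10^x, go_with = y)
    f1 <- fit_pgo(d1)
    f2 <- fit_pgo(d2)
    expect_equal(f2$beta1, f1$beta1, tolerance = 1e-6)
    expect_equal(f2$beta0, f1$beta0 - f1$beta1 * 3, tolerance = 1e-6)
    # solved prizes scale by the same unit factor
    expect_equal(solve_prize(f2, 0.8) / solve_prize(f1, 0.8), 1000,
                 tolerance = 1e-6)
  })
})

test_that("tidy and glance expose the fitted coefficients", {
  z <- 10^seq(0, 4, length.out = 20)
  fit <- fit_improvement(tibble::tibble(prize_size = z,
                                        improvement = 0.5 * z),
                         indication = "CABP", prize_phase = "P2")
  td <- tidy(fit)
  expect_equal(td$term, c("beta0", "beta1"))
  expect_equal(td$estimate[2], 1, tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(gl$indication, "CABP")
  expect_equal(gl$model, "improvement_loglog")
})
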