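toy_two_step <- tibble::tibble(
  t = c(0, 1), phase = c("P1", "M1"), cost = c(10, 0),
  revenue = c(0, 22), prize = c(0, 0), survival = c(1, 0.5)
)

test_that("perspective ENPVs match hand-computed toys", {
  expect_equal(enpv_private(toy_two_step, r = 0.1), 0)
  with_prize <- toy_two_step
  with_prize$prize[1] <- 10
  expect_equal(enpv_intervened(with_prize, r = 0.1), 10)
  expect_equal(enpv_intervened(toy_two_step, 0.1),
               enpv_private(toy_two_step, 0.1))
  # prize of 100 at t = 2 reaching with probability 0.5, social rate 4%
  s <- tibble::tibble(t = 2, phase = "P2", cost = 0, revenue = 0,
                      prize = 100, survival = 0.5)
  expect_equal(enpv_indirect(s, 0.04), -100 * 0.5 / 1.04^2)
  expect_equal(enpv_indirect(toy_two_step, 0.04), 0)
  # single cost of 10 at t = 1, survival 0.8, 50% inefficiency
  d <- tibble::tibble(t = 1, phase = "P1", cost = 10, revenue = 0,
                      prize = 0, survival = 0.8)
  expect_equal(enpv_direct(d, 0.04, i = 0.5), -15 * 0.8 / 1.04)
  # r = 0 with full survival reduces to the plain cashflow sum
  flat <- toy_two_step
  flat$survival <- 1
  expect_equal(enpv_private(flat, 0), 22 - 10)
  expect_error(enpv_private(toy_two_step, -1), "discount rate")
  expect_error(enpv_direct(d, 0.04, i = -0.1), "inefficiency")
})

test_that("all four perspectives agree with a brute-force oracle", {
  withr::with_seed(42, {
    for (case in 1:50) {
      s <- random_toy_schedule(5)
      r <- runif(1, 0, 0.3)
      i <- runif(1, 0, 1)
      expect_equal(enpv_private(s, r), oracle_enpv(s, r, "private"),
                   tolerance = 1e-9)
      expect_equal(enpv_intervened(s, r), oracle_enpv(s, r, "intervened"),
                   tolerance = 1e-9)
      expect_equal(enpv_indirect(s, r), oracle_enpv(s, r, "indirect"),
                   tolerance = 1e-9)
      expect_equal(enpv_direct(s, r, i),
                   oracle_enpv(s, r, "direct", inefficiency = i),
                   tolerance = 1e-9)
    }
  })
})

test_that("direct ENPV is affine-linear in the inefficiency factor", {
  p <- abx_test_params()
  s <- build_schedule(toy_project(), p)
  v0 <- enpv_direct(s, 0.04, i = 0)
  expect_equal(enpv_direct(s, 0.04, i = 1), 2 * v0)
  expect_equal(enpv_direct(s, 0.04, i = 0.25), 1.25 * v0)
})

test_that("raising the social rate moves a cost-only ENPV toward zero", {
  p <- abx_test_params()
  s <- build_schedule(toy_project(), p)
  rates <- seq(0.01, 0.2, by = 0.01)
  vals <- vapply(rates, function(r) enpv_direct(s, r), numeric(1))
  expect_true(all(vals < 0))
  expect_true(all(diff(vals) > 0))
})

test_that("the intervened-private gap is strictly increasing in prize size", {
  p <- abx_test_params()
  pr <- toy_project()
  gaps <- vapply(c(1, 10, 100, 1000), function(z) {
    s <- build_schedule(pr, p, prize_phase = "P2", prize_size = z)
    enpv_intervened(s, 0.11) - enpv_private(s, 0.11)
  }, numeric(1))
  expect_true(all(gaps > 0))
  expect_true(all(diff(gaps) > 0))
})

test_that("per-market-approval scaling divides by the technical P0", {
  expect_equal(per_market_approval(-50, 0.5), -100)
  expect_equal(per_market_approval(-50, 1), -50)
  p <- abx_test_params()
  s <- build_schedule(toy_project(prob_pc = 0.5, prob_p1 = 0.4, prob_p2 = 1,
                                  prob_p3 = 1, prob_p4 = 1), p)
  expect_equal(attr(s, "p_reach_market"), prod(c(0.5, 0.4)))
  expect_equal(per_market_approval(-10, s), -10 / 0.2)
  expect_error(per_market_approval(-10, 0), "positive")
})

test_that("cost savings carry the direct-minus-indirect sign convention", {
  p <- abx_test_params()
  pr <- toy_project()
  # a huge market-entry prize stimulates and dwarfs the at-cost bill
  s <- build_schedule(pr, p, prize_phase = "M1", prize_size = 1e5)
  expect_gt(enpv_intervened(s, pr$r_private), 0)
  expect_gt(cost_savings(s, pr$r_private, pr$r_social, i = 0), 0)
  # a tiny prize cannot stimulate this toy: filtering bug must error
  tiny <- build_schedule(pr, p, prize_phase = "M1", prize_size = 0.001)
  if (enpv_intervened(tiny, pr$r_private) < 0) {
    expect_error(cost_savings(tiny, pr$r_private, pr$r_social),
                 "not stimulate")
  }
})

test_that("vectorized valuation matches the per-schedule route", {
  p <- abx_test_params()
  for (ind in c("ABOM", "HABP/VABP")) {
    pr <- sample_projects(p, ind, 10, seed = 31)
    v <- value_projects(pr, p)
    for (j in seq_len(nrow(pr))) {
      s <- build_schedule(pr[j, ], p)
      expect_equal(v$enpv_private[j], enpv_private(s, pr$r_private[j]),
                   tolerance = 1e-9)
      expect_equal(-v$cost_pv_social[j], enpv_direct(s, pr$r_social[j]),
                   tolerance = 1e-9)
      expect_equal(v$p0[j], attr(s, "p_reach_market"), tolerance = 1e-12)
      sz <- build_schedule(pr[j, ], p, prize_phase = "P3", prize_size = 250)
      gap <- enpv_intervened(sz, pr$r_private[j]) -
        enpv_private(sz, pr$r_private[j])
      expect_equal(250 * v$s_P3[j] / (1 + pr$r_private[j])^v$t_P3[j], gap,
                   tolerance = 1e-9)
      expect_equal(enpv_indirect(sz, pr$r_social[j]),
                   -250 * v$s_P3[j] / (1 + pr$r_social[j])^v$t_P3[j],
                   tolerance = 1e-9)
    }
  }
})

test_that("benefactor perspectives are never positive on sampled projects", {
  p <- abx_test_params()
  pr <- sample_projects(p, "CIAI", 300, seed = 8)
  v <- value_projects(pr, p)
  prizes <- withr::with_seed(9, 10^runif(300, -1, 5))
  for (ph in c("P1", "M1")) {
    res <- apply_prize(v, ph, prize_size = prizes, inefficiency = 0.5)
    expect_true(all(res$enpv_indirect <= 0))
    expect_true(all(res$enpv_direct <= 0))
    expect_true(all(res$enpv_intervened >= res$enpv_private))
    expect_true(all(is.na(res$savings) == !res$go_with))
  }
  none <- apply_prize(v, "none", 0)
  expect_true(all(none$enpv_indirect == 0))
  expect_equal(none$enpv_intervened, none$enpv_private)
})
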