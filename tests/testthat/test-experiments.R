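params <- abx_test_params()

test_that("the baseline run is complete, coherent and reproducible", {
  bl <- run_baseline(params, n_samples = 300, seed = 4)
  expect_s3_class(bl, "abx_baseline")
  expect_setequal(bl$decisions$indication,
                  c("ABOM", "ABSSSI", "CABP", "CIAI", "CUTI", "HABP/VABP"))
  expect_equal(bl$decisions$go + bl$decisions$no, rep(1, 6))
  expect_true(all(bl$decisions$go >= 0 & bl$decisions$go <= 1))
  # two models per indication x prize phase
  expect_equal(nrow(bl$fits), 6 * 5 * 2)
  expect_setequal(unique(bl$fits$model),
                  c("improvement_loglog", "pgo_logistic"))
  expect_true(all(bl$prizes$prize_size > 0))
  expect_equal(nrow(bl$prizes), 30)
  # deterministic under the seed contract
  bl2 <- run_baseline(params, n_samples = 300, seed = 4)
  expect_identical(bl$decisions, bl2$decisions)
  expect_identical(bl$prizes, bl2$prizes)
  bl3 <- run_baseline(params, n_samples = 300, seed = 5)
  expect_false(identical(bl$prizes, bl3$prizes))
  # broom-style accessors
  expect_equal(nrow(tidy(bl)), 60)
  expect_equal(glance(bl)$n_samples, 300)
})

test_that("improvement fits are near-perfectly log-linear in prize size", {
  bl <- run_baseline(params, n_samples = 500, seed = 2,
                     indications = "ABOM")
  imp <- bl$fits[bl$fits$model == "improvement_loglog", ]
  # the lump-sum mechanics make the slope one and the fit extremely tight
  expect_true(all(abs(imp$beta1 - 1) < 0.05))
  expect_true(all(imp$p_value < 1e-10))
})

test_that("the grid covers its cells and flags empties as missing", {
  bl <- run_baseline(params, n_samples = 400, seed = 6,
                     indications = "CUTI")
  g <- run_grid(bl, params, pgo_grid = seq(0.5, 0.9875, length.out = 5),
                ineff_grid = seq(0, 1, length.out = 4), n_per_cell = 8,
                seed = 6, indications = "CUTI", prize_phases = c("P1", "M1"))
  expect_equal(nrow(g), 5 * 4 * 2)
  expect_true(all(g$n_effective <= 8))
  expect_true(all(is.na(g$mean_cost_savings) == (g$n_effective == 0)))
  g2 <- run_grid(bl, params, pgo_grid = seq(0.5, 0.9875, length.out = 5),
                 ineff_grid = seq(0, 1, length.out = 4), n_per_cell = 8,
                 seed = 6, indications = "CUTI", prize_phases = c("P1", "M1"))
  expect_identical(as.data.frame(g), as.data.frame(g2))
})

test_that("savings move with the target and the inefficiency as expected", {
  bl <- run_baseline(params, n_samples = 1500, seed = 3,
                     indications = "ABOM")
  g <- run_grid(bl, params, pgo_grid = c(0.55, 0.95),
                ineff_grid = c(0, 1), n_per_cell = 600, seed = 3,
                indications = "ABOM", prize_phases = "M1")
  val <- function(pg, ie) {
    g$mean_cost_savings[abs(g$target_pgo - pg) < 1e-9 &
                          g$inefficiency == ie]
  }
  # larger targets demand larger prizes: direct funding gains ground
  expect_gt(val(0.95, 0), val(0.55, 0))
  expect_gt(val(0.95, 1), val(0.55, 1))
  # higher inefficiency makes direct funding dearer: savings fall
  expect_gt(val(0.95, 0), val(0.95, 1))
  expect_gt(val(0.55, 0), val(0.55, 1))
  # at a high target and no inefficiency a market-entry reward costs more
  expect_gt(val(0.95, 0), 0)
})

test_that("the frontier fit recovers an exactly quadratic zero contour", {
  quad <- function(e) 0.62 + 0.18 * e + 0.09 * e^2
  ineffs <- seq(0, 1, by = 0.25)
  pgos <- sort(c(quad(ineffs), 0.52, 0.57, 0.99))
  cells <- tidyr::expand_grid(target_pgo = pgos, inefficiency = ineffs)
  cells$indication <- "SYN"
  cells$prize_phase <- "M1"
  cells$prize_size <- 1
  # savings vanish exactly on the quadratic and change sign across it
  cells$mean_cost_savings <- 1000 * (cells$target_pgo -
                                       quad(cells$inefficiency))
  cells$n_effective <- 5L
  class(cells) <- c("abx_grid", class(cells))
  fr <- fit_frontier(cells)
  expect_false(fr$flagged)
  expect_equal(fr$a, 0.62, tolerance = 1e-9)
  expect_equal(fr$b, 0.18, tolerance = 1e-9)
  expect_equal(fr$c, 0.09, tolerance = 1e-9)
  # a surface with no sign change is flagged, not fitted
  mono <- cells
  mono$mean_cost_savings <- abs(mono$mean_cost_savings) + 1
  fr2 <- fit_frontier(mono)
  expect_true(fr2$flagged)
  expect_true(is.na(fr2$a))
})

test_that("the scenario filters non-stimulated projects and summarises", {
  bl <- run_baseline(params, n_samples = 500, seed = 12,
                     indications = c("ABOM", "CUTI"))
  sc <- run_scenario(bl, params, n_samples = 200, inefficiency = 0.5,
                     target_pgo = 0.9, seed = 12,
                     indications = c("ABOM", "CUTI"))
  expect_s3_class(sc, "abx_scenario")
  expect_equal(nrow(sc$savings), 2 * 5)
  expect_true(all(sc$savings$n_effective <= 200))
  # every retained sample was stimulated: its prize cost is a real cost
  expect_true(all(sc$samples$indirect_per_approval > 0))
  expect_true(all(sc$samples$direct_per_approval > 0))
  expect_equal(
    sc$samples$savings,
    sc$samples$indirect_per_approval - sc$samples$direct_per_approval
  )
  td <- tidy(sc)
  expect_equal(names(td), c("indication", "P1", "P2", "P3", "P4", "M1"))
  sc2 <- run_scenario(bl, params, n_samples = 200, inefficiency = 0.5,
                      target_pgo = 0.9, seed = 12,
                      indications = c("ABOM", "CUTI"))
  expect_identical(sc$savings, sc2$savings)
})

test_that("plot builders return ggplot objects", {
  bl <- run_baseline(params, n_samples = 300, seed = 21,
                     indications = "ABOM")
  expect_s3_class(plot_pgo_curves(bl), "ggplot")
  g <- run_grid(bl, params, pgo_grid = seq(0.5, 0.95, length.out = 4),
                ineff_grid = seq(0, 1, length.out = 3), n_per_cell = 5,
                seed = 1, indications = "ABOM", prize_phases = "M1")
  expect_s3_class(plot_savings_heatmap(g), "ggplot")
  sc <- run_scenario(bl, params, n_samples = 100, seed = 1,
                     indications = "ABOM")
  expect_s3_class(plot_cost_distributions(sc), "ggplot")
  expect_s3_class(autoplot(bl), "ggplot")
})
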