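# Shared fixtures for the test suite. Everything is built in code: the
# packaged parameter tables are loaded once, and toy projects/schedules are
# constructed with fully controlled values.

abx_test_params <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- abx_parameters()
    cached
  }
})

# One project row with every draw pinned to a known value; fields can be
# overridden. Durations in years, costs in million USD, probabilities as
# fractions.
toy_project <- function(...) {
  base <- tibble::tibble(
    indication = "ABOM", project = 1L,
    dur_pc = 2, dur_p1 = 1, dur_p2 = 1, dur_p3 = 2, dur_p4 = 1,
    cost_pc = 20, cost_p1 = 10, cost_p2 = 9, cost_p3 = 40, cost_p4 = 2,
    prob_pc = 0.4, prob_p1 = 0.5, prob_p2 = 0.5, prob_p3 = 0.6,
    prob_p4 = 0.9,
    market_size = 2720, launch_frac = 0.5, generic_entry = 12,
    generic_reduction = 0.5, r_private = 0.11, r_social = 0.04,
    ac_sample_prep = 2.7, ac_process_dev = 26.8, ac_plant_design = 13.4,
    ac_plant_build = 83, ac_non_clinical = 3.7, ac_pas = 10
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# Independent ENPV oracle: plain accumulation loop over rows, written
# without reusing any package internals.
oracle_enpv <- function(schedule, rate, perspective = "private",
                        inefficiency = 0) {
  total <- 0
  for (row in seq_len(nrow(schedule))) {
    cash <- switch(perspective,
      private = schedule$revenue[row] - schedule$cost[row],
      intervened = schedule$revenue[row] - schedule$cost[row] +
        schedule$prize[row],
      indirect = -schedule$prize[row],
      direct = -(1 + inefficiency) * schedule$cost[row]
    )
    total <- total + cash * schedule$survival[row] /
      (1 + rate)^schedule$t[row]
  }
  total
}

# Random small schedule for property tests (up to `max_steps` steps).
random_toy_schedule <- function(max_steps = 5) {
  n <- sample(1:max_steps, 1)
  tibble::tibble(
    t = sort(runif(n, 0, 10)),
    phase = paste0("S", seq_len(n)),
    cost = runif(n, 0, 50),
    revenue = runif(n, 0, 50),
    prize = sample(c(0, 100), n, replace = TRUE),
    survival = sort(runif(n, 0.05, 1), decreasing = TRUE)
  )
}
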