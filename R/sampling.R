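#' Sample project realizations for one indication
#'
#' Draws `n` hypothetical development projects: per-phase durations, costs and
#' success probabilities from their triangulars, market size (uniform over the
#' printed range where one is given, fixed otherwise), the launch-success
#' draw, generic-entry timing and revenue reduction, per-project private and
#' social discount rates, and one draw of every additional cost item.
#'
#' The launch-success draw is used only to position the market-share
#' trajectory between its printed lower and upper envelope: the draw is
#' rescaled linearly onto `[0, 1]` as
#' `f = (draw - min) / (max - min)`, and every year's share is
#' `lower + f * (upper - lower)`, so the position between the bounds is the
#' same in every year and the share curve never decreases before its plateau.
#'
#' @param params An [abx_parameters()] object.
#' @param indication One of the six packaged indication codes.
#' @param n Number of projects.
#' @param seed Optional integer; when supplied the draw is made under a local
#'   RNG state so the caller's stream is untouched.
#' @return A tibble with one row per project and one column per draw:
#'   durations (years), costs (million USD), probabilities (fractions),
#'   `market_size`, `launch_frac`, `generic_entry` (years after launch),
#'   `generic_reduction`, `r_private`, `r_social`, and one `ac_*` column per
#'   additional cost item.
#' @examples
#' params <- abx_parameters()
#' sample_projects(params, "ABOM", 3, seed = 1)
#' @export
sample_projects <- function(params, indication, n, seed = NULL) {
  stopifnot(inherits(params, "abx_parameters"))
  if (!indication %in% params$market$indication) {
    stop("unknown indication: ", indication, call. = FALSE)
  }
  if (!is.null(seed)) {
    return(withr::with_seed(seed, sample_projects(params, indication, n)))
  }
  ph <- params$phases[params$phases$indication == indication, ]
  ph <- ph[match(.dev_phases, ph$phase), ]
  draws <- list()
  for (i in seq_along(.dev_phases)) {
    key <- tolower(.dev_phases[i])
    draws[[paste0("dur_", key)]] <-
      rtriangular(n, ph$time_min[i], ph$time_mode[i], ph$time_max[i])
    draws[[paste0("cost_", key)]] <-
      rtriangular(n, ph$cost_min[i], ph$cost_mode[i], ph$cost_max[i])
    draws[[paste0("prob_", key)]] <-
      rtriangular(n, ph$prob_min[i], ph$prob_mode[i], ph$prob_max[i])
  }
  mk <- params$market[params$market$indication == indication, ]
  market_size <- if (is.na(mk$size_max)) {
    rep(mk$size_min, n)
  } else {
    runif(n, mk$size_min, mk$size_max)
  }
  ec <- params$econ
  launch <- rtriangular(n, ec$launch_success[1], ec$launch_success[2],
                        ec$launch_success[3])
  launch_frac <- (launch - ec$launch_success[1]) /
    (ec$launch_success[3] - ec$launch_success[1])
  extra <- params$extra_costs
  ac <- lapply(seq_len(nrow(extra)), function(i) {
    rtriangular(n, extra$cost_min[i], extra$cost_mode[i], extra$cost_max[i])
  })
  names(ac) <- paste0("ac_", extra_cost_key(extra$item))
  tibble(
    indication = indication,
    project = seq_len(n),
    !!!draws,
    market_size = market_size,
    launch_frac = launch_frac,
    generic_entry = rtriangular(n, ec$generic_entry[1], ec$generic_entry[2],
                                ec$generic_entry[3]),
    generic_reduction = rtriangular(n, ec$generic_reduction[1],
                                    ec$generic_reduction[2],
                                    ec$generic_reduction[3]),
    r_private = rtriangular(n, ec$private_rate[1], ec$private_rate[2],
                            ec$private_rate[3]),
    r_social = runif(n, ec$social_rate["min"], ec$social_rate["max"]),
    !!!ac
  )
}

# "Sample prep." -> "sample_prep": stable machine keys for cost columns
extra_cost_key <- function(item) {
  gsub("^_|_$", "", gsub("[^a-z0-9]+", "_", tolower(item)))
}

#' Sample prize draws
#'
#' Prize sizes are sampled logarithmically: `10^X` USD with
#' `X ~ Uniform(5, 11)`, i.e. from 100,000 USD to 100 billion USD, expressed
#' in million USD. The prize phase is drawn uniformly from phase-1 to phase-4
#' entry and market entry unless fixed; a project never carries more than one
#' prize, and pre-clinical entry prizes are never generated (they would be
#' undiscounted from the pre-clinical valuation point).
#'
#' @param n Number of draws.
#' @param prize_phase Optional fixed phase, one of `"P1"`..`"P4"`, `"M1"`.
#' @param seed Optional integer for a local RNG state.
#' @return A tibble with columns `prize_phase` and `prize_size` (million USD).
#' @examples
#' sample_prizes(5, prize_phase = "M1", seed = 1)
#' @export
sample_prizes <- function(n, prize_phase = NULL, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, sample_prizes(n, prize_phase)))
  }
  if (!is.null(prize_phase) && !prize_phase %in% .prize_phases) {
    stop("prize_phase must be one of ", paste(.prize_phases, collapse = ", "),
         call. = FALSE)
  }
  phases <- if (is.null(prize_phase)) {
    sample(.prize_phases, n, replace = TRUE)
  } else {
    rep(prize_phase, n)
  }
  tibble(
    prize_phase = phases,
    prize_size = 10^(runif(n, 5, 11) - 6)
  )
}

# Deterministic substream seed for (experiment purpose, indication index).
# Keeps every derived seed a valid 32-bit integer and well separated so
# adding indications or experiments does not perturb other streams.
derive_seed <- function(seed, purpose, index = 0L) {
  base <- as.integer(seed) %% 1000000L
  (base + 101393L * as.integer(purpose) + 7919L * as.integer(index)) %%
    2147483629L
}
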