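#' Expand one project into a discrete cashflow schedule
#'
#' Converts a sampled project (one row of [sample_projects()]) into the
#' sequence of yearly timesteps that the ENPV sums run over. A development
#' phase of duration `d` years starting at time `s` contributes
#' `n = ceiling(d)` steps at `t = s, s + 1, ..., s + n - 1`; the next phase
#' starts at `s + d`, so steps are equidistant within a phase but not
#' necessarily across phases. The phase's cost draw is split equally across
#' its steps. Its success probability is split geometrically: each step's
#' conditional survival is `p^(1/n)` so the per-step hazard is constant and
#' the product over the phase recovers the phase draw exactly. The 20 market
#' years follow as unit steps starting at the total development time, with
#' revenues from [build_revenues()]. `survival` is the probability of
#' reaching each step from `t = 0`; it equals 1 at the first step, and the
#' probability of reaching the market (`P0`, the product of the five phase
#' probability draws) is stored in the `p_reach_market` attribute.
#'
#' @param project One-row tibble from [sample_projects()].
#' @param params The [abx_parameters()] the project was sampled from.
#' @return A tibble of class `abx_schedule` with columns `t` (years from
#'   pre-clinical start), `phase` (`PC`, `P1`..`P4`, `M1`..`M20`), `cost`,
#'   `revenue`, `prize` (million USD) and `survival`.
#' @examples
#' params <- abx_parameters()
#' project <- sample_projects(params, "ABOM", 1, seed = 1)
#' periodize(project, params)
#' @export
periodize <- function(project, params) {
  stopifnot(nrow(project) == 1)
  dur <- as.numeric(project[paste0("dur_", tolower(.dev_phases))])
  cst <- as.numeric(project[paste0("cost_", tolower(.dev_phases))])
  prb <- as.numeric(project[paste0("prob_", tolower(.dev_phases))])
  if (any(dur <= 0)) stop("phase durations must be positive", call. = FALSE)
  starts <- cumsum(c(0, dur))[seq_along(dur)]
  reach <- cumprod(c(1, prb))[seq_along(prb)]
  steps <- vector("list", length(.dev_phases))
  for (p in seq_along(.dev_phases)) {
    nsteps <- ceiling(dur[p])
    k <- seq_len(nsteps) - 1
    steps[[p]] <- tibble(
      t = starts[p] + k,
      phase = .dev_phases[p],
      cost = cst[p] / nsteps,
      revenue = 0,
      prize = 0,
      survival = reach[p] * prb[p]^(k / nsteps)
    )
  }
  p0 <- prod(prb)
  dev_time <- sum(dur)
  life <- params$econ$market_life
  market <- tibble(
    t = dev_time + seq_len(life) - 1,
    phase = paste0("M", seq_len(life)),
    cost = 0,
    revenue = build_revenues(project, params),
    prize = 0,
    survival = p0
  )
  out <- bind_rows(c(steps, list(market)))
  attr(out, "p_reach_market") <- p0
  class(out) <- c("abx_schedule", class(out))
  out
}

#' Yearly market revenues for one project
#'
#' Revenue in market year `y` is the market-size draw times the year's
#' market share, interpolated between the printed share envelope by the
#' project's launch fraction. From the first market year strictly after the
#' sampled generic-entry year, revenue is reduced by the sampled
#' generic-entry fraction and held at that reduced constant to the end of
#' market life.
#'
#' @inheritParams periodize
#' @return Numeric vector of 20 yearly revenues (million USD).
#' @export
build_revenues <- function(project, params) {
  stopifnot(nrow(project) == 1)
  sh <- params$shares
  share <- sh$lower + project$launch_frac * (sh$upper - sh$lower)
  rev <- project$market_size * share
  post_generic <- sh$year > project$generic_entry
  rev[post_generic] <- rev[post_generic] * (1 - project$generic_reduction)
  rev
}

#' Spread additional cost items over a schedule
#'
#' Adds each additional cost draw (the `ac_*` columns of the project) to the
#' schedule: the item's cost is split across its target phases by the
#' allocation weights from the parameter table (equal weights where none are
#' printed), then equally across that phase's steps. Items allocated to
#' market years (post-approval studies over `M1`..`M3`) land on those market
#' steps.
#'
#' @param schedule A schedule from [periodize()].
#' @param project The project row the schedule was built from.
#' @param params The [abx_parameters()] object (holds the allocations).
#' @return The schedule with augmented `cost` column.
#' @export
allocate_additional_costs <- function(schedule, project, params) {
  extra <- params$extra_costs
  keys <- paste0("ac_", extra_cost_key(extra$item))
  cost <- schedule$cost
  for (i in seq_len(nrow(extra))) {
    draw <- project[[keys[i]]]
    alloc <- extra$allocation[[i]]
    for (j in seq_along(alloc)) {
      target <- names(alloc)[j]
      rows <- which(schedule$phase == target)
      if (length(rows) == 0) {
        stop("cost item '", extra$item[i], "' allocated to phase ", target,
             " which is absent from the schedule", call. = FALSE)
      }
      cost[rows] <- cost[rows] + draw * alloc[j] / length(rows)
    }
  }
  schedule$cost <- cost
  schedule
}

#' Attach a lump-sum prize to a schedule
#'
#' Places the prize on the first step of the named phase (for `"M1"`, the
#' first market year), modelling a one-time payment upon phase entry.
#'
#' @param schedule A schedule from [periodize()].
#' @param prize_phase `"none"` or one of `"P1"`..`"P4"`, `"M1"`.
#' @param prize_size Prize in million USD.
#' @return The schedule with its `prize` column set.
#' @export
attach_prize <- function(schedule, prize_phase, prize_size) {
  schedule$prize <- 0
  if (identical(prize_phase, "none")) {
    return(schedule)
  }
  if (!prize_phase %in% .prize_phases) {
    stop("prize_phase must be 'none' or one of ",
         paste(.prize_phases, collapse = ", "), call. = FALSE)
  }
  row <- which(schedule$phase == prize_phase)[1]
  if (is.na(row)) {
    stop("prize phase ", prize_phase, " absent from schedule", call. = FALSE)
  }
  schedule$prize[row] <- prize_size
  schedule
}

#' Full schedule for one project
#'
#' Convenience wrapper: [periodize()], then [allocate_additional_costs()],
#' then [attach_prize()].
#'
#' @inheritParams periodize
#' @inheritParams attach_prize
#' @return An `abx_schedule` tibble.
#' @examples
#' params <- abx_parameters()
#' project <- sample_projects(params, "CUTI", 1, seed = 7)
#' build_schedule(project, params, prize_phase = "M1", prize_size = 500)
#' @export
build_schedule <- function(project, params, prize_phase = "none",
                           prize_size = 0) {
  schedule <- periodize(project, params)
  schedule <- allocate_additional_costs(schedule, project, params)
  attach_prize(schedule, prize_phase, prize_size)
}
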