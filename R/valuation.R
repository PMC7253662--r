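#' Expected net present value of a schedule, private perspective
#'
#' Sums `(revenue - cost) * survival / (1 + r)^t` over all steps of the
#' schedule, with real-valued exponents `t` (fractional years are not
#' rounded). `survival` is the probability of reaching the step from the
#' valuation point, so the sum is the risk-adjusted discounted expectation a
#' private developer uses for the go-/no-decision.
#'
#' @param schedule A schedule tibble from [build_schedule()] (columns `t`,
#'   `cost`, `revenue`, `prize`, `survival`).
#' @param r Annual discount rate (fraction), must be greater than -1.
#' @return ENPV in million USD.
#' @examples
#' toy <- tibble::tibble(t = c(0, 1), phase = c("P1", "M1"),
#'                       cost = c(10, 0), revenue = c(0, 22),
#'                       prize = 0, survival = c(1, 0.5))
#' enpv_private(toy, r = 0.1) # -10 + 22 * 0.5 / 1.1 = 0
#' @export
enpv_private <- function(schedule, r) {
  check_rate(r)
  sum((schedule$revenue - schedule$cost) * schedule$survival / (1 + r)^schedule$t)
}

#' ENPV under a prize intervention, private perspective
#'
#' As [enpv_private()] but with the prize added to the cashflow:
#' `(revenue - cost + prize) * survival / (1 + r)^t`.
#'
#' @inheritParams enpv_private
#' @return ENPV in million USD; equals [enpv_private()] when no prize is
#'   attached and exceeds it whenever one is.
#' @export
enpv_intervened <- function(schedule, r) {
  check_rate(r)
  sum((schedule$revenue - schedule$cost + schedule$prize) * schedule$survival /
        (1 + r)^schedule$t)
}

#' Benefactor's cost of a prize, indirect-funding perspective
#'
#' The only cashflow is the prize itself, risk-adjusted by the probability
#' that it is ever paid and discounted at the benefactor's (social) rate:
#' `sum(-prize * survival / (1 + r_social)^t)`. Always `<= 0`; equals 0 when
#' no prize is attached.
#'
#' @inheritParams enpv_private
#' @param r_social Annual social discount rate (fraction).
#' @return ENPV in million USD (non-positive).
#' @export
enpv_indirect <- function(schedule, r_social) {
  check_rate(r_social)
  sum(-schedule$prize * schedule$survival / (1 + r_social)^schedule$t)
}

#' Benefactor's cost of funding at-cost, direct-funding perspective
#'
#' Only costs are considered, inflated by the operational inefficiency `i`:
#' `sum(-(1 + i) * cost * survival / (1 + r_social)^t)`. Revenues and prizes
#' are ignored, so the value is non-positive and affine-linear in `(1 + i)`.
#'
#' @inheritParams enpv_indirect
#' @param i Inefficiency fraction, `>= 0`.
#' @return ENPV in million USD (non-positive).
#' @export
enpv_direct <- function(schedule, r_social, i = 0) {
  check_rate(r_social)
  if (i < 0) stop("inefficiency must be >= 0", call. = FALSE)
  sum(-(1 + i) * schedule$cost * schedule$survival /
        (1 + r_social)^schedule$t)
}

check_rate <- function(r) {
  if (any(r <= -1)) stop("discount rate must be greater than -1", call. = FALSE)
  invisible(r)
}

#' Rescale a per-project value to a per-market-approval value
#'
#' Divides by the technical probability that the project reaches market
#' (`P0`, the product of the development-phase success draws), turning an
#' expected cost per funded project into an expected cost per observed
#' market approval.
#'
#' @param value Value in million USD.
#' @param schedule A schedule carrying a `p_reach_market` attribute, or a
#'   bare numeric probability.
#' @return Value in million USD per market approval.
#' @export
per_market_approval <- function(value, schedule) {
  p0 <- if (is.numeric(schedule)) schedule else attr(schedule, "p_reach_market")
  if (is.null(p0)) stop("schedule carries no p_reach_market", call. = FALSE)
  if (any(p0 <= 0)) {
    stop("probability of reaching market must be positive", call. = FALSE)
  }
  value / p0
}

#' Cost savings of direct over indirect funding for one stimulated project
#'
#' `per_market_approval(direct) - per_market_approval(indirect)`: both terms
#' are non-positive costs, so a positive difference means the direct
#' alternative is cheaper. Only defined for projects the prize actually
#' stimulates (intervened private ENPV `>= 0`); calling it on a
#' non-stimulated project signals a filtering bug upstream and errors.
#'
#' @param schedule A schedule with a prize attached.
#' @param r Private discount rate used for the stimulation check.
#' @param r_social Social discount rate.
#' @param i Direct-funding inefficiency fraction.
#' @return Savings in million USD per market approval.
#' @export
cost_savings <- function(schedule, r, r_social, i = 0) {
  if (enpv_intervened(schedule, r) < 0) {
    stop("cost_savings called on a project the prize does not stimulate",
         call. = FALSE)
  }
  per_market_approval(enpv_direct(schedule, r_social, i), schedule) -
    per_market_approval(enpv_indirect(schedule, r_social), schedule)
}

#' Value many projects at once
#'
#' Vectorized valuation engine. For every project row it computes the
#' private ENPV, the social-rate present value of the full cost stream (the
#' direct-funding cost at zero inefficiency, stored as the non-negative
#' `cost_pv_social`), the probability of reaching market `p0`, and the entry
#' time and survival of every prize anchor (phase-1 to phase-4 entry and
#' market entry). Identical, to numerical tolerance, to building each
#' project's schedule with [build_schedule()] and applying the `enpv_*`
#' functions, but orders of magnitude faster for Monte Carlo runs.
#'
#' @param projects Tibble from [sample_projects()].
#' @param params The [abx_parameters()] object.
#' @return A tibble with one row per project: `indication`, `project`, `p0`,
#'   `enpv_private`, `cost_pv_social`, `r_private`, `r_social`, and prize
#'   anchor columns `t_P1`..`t_M1`, `s_P1`..`s_M1`.
#' @examples
#' params <- abx_parameters()
#' projects <- sample_projects(params, "CUTI", 100, seed = 1)
#' value_projects(projects, params)
#' @export
value_projects <- function(projects, params) {
  n <- nrow(projects)
  dur <- as.matrix(projects[paste0("dur_", tolower(.dev_phases))])
  cst <- as.matrix(projects[paste0("cost_", tolower(.dev_phases))])
  prb <- as.matrix(projects[paste0("prob_", tolower(.dev_phases))])
  if (any(dur <= 0)) stop("phase durations must be positive", call. = FALSE)
  starts <- cbind(0, t(apply(dur, 1, cumsum)))[, seq_along(.dev_phases),
                                               drop = FALSE]
  dev_time <- rowSums(dur)
  reach <- cbind(1, t(apply(prb, 1, cumprod)))[, seq_along(.dev_phases),
                                               drop = FALSE]
  p0 <- reach[, 5] * prb[, 5]

  # additional costs: per-phase totals from the allocation table
  extra <- params$extra_costs
  keys <- paste0("ac_", extra_cost_key(extra$item))
  extra_phase <- matrix(0, n, 5,
                        dimnames = list(NULL, .dev_phases))
  pas_years <- integer(0)        # market years carrying allocated costs
  for (i in seq_len(nrow(extra))) {
    alloc <- extra$allocation[[i]]
    for (j in seq_along(alloc)) {
      target <- names(alloc)[j]
      if (target %in% .dev_phases) {
        extra_phase[, target] <- extra_phase[, target] +
          projects[[keys[i]]] * alloc[j]
      } else {
        pas_years <- union(pas_years, as.integer(sub("^M", "", target)))
      }
    }
  }

  cost_total <- cst + extra_phase
  r <- projects$r_private
  rs <- projects$r_social
  cost_pv_priv <- numeric(n)
  cost_pv_soc <- numeric(n)
  nsteps <- ceiling(dur)
  for (p in seq_along(.dev_phases)) {
    nv <- nsteps[, p]
    cond <- prb[, p]^(1 / nv)
    per_step <- cost_total[, p] / nv
    for (k in 0:(max(nv) - 1)) {
      live <- k < nv
      tk <- starts[live, p] + k
      sv <- reach[live, p] * cond[live]^k
      cost_pv_priv[live] <- cost_pv_priv[live] +
        per_step[live] * sv / (1 + r[live])^tk
      cost_pv_soc[live] <- cost_pv_soc[live] +
        per_step[live] * sv / (1 + rs[live])^tk
    }
  }

  sh <- params$shares
  rev_pv <- numeric(n)
  for (y in seq_len(params$econ$market_life)) {
    share_y <- sh$lower[y] + projects$launch_frac * (sh$upper[y] - sh$lower[y])
    rev_y <- projects$market_size * share_y *
      ifelse(y > projects$generic_entry, 1 - projects$generic_reduction, 1)
    ty <- dev_time + y - 1
    rev_pv <- rev_pv + rev_y * p0 / (1 + r)^ty
    if (y %in% pas_years) {
      per_item <- numeric(n)
      for (i in seq_len(nrow(extra))) {
        alloc <- extra$allocation[[i]]
        target <- paste0("M", y)
        if (target %in% names(alloc)) {
          per_item <- per_item + projects[[keys[i]]] * alloc[[target]]
        }
      }
      cost_pv_priv <- cost_pv_priv + per_item * p0 / (1 + r)^ty
      cost_pv_soc <- cost_pv_soc + per_item * p0 / (1 + rs)^ty
    }
  }

  anchors_t <- cbind(starts[, 2:5, drop = FALSE], dev_time)
  anchors_s <- cbind(reach[, 2:5, drop = FALSE], p0)
  colnames(anchors_t) <- paste0("t_", .prize_phases)
  colnames(anchors_s) <- paste0("s_", .prize_phases)

  tibble(
    indication = projects$indication,
    project = projects$project,
    p0 = p0,
    enpv_private = rev_pv - cost_pv_priv,
    cost_pv_social = cost_pv_soc,
    r_private = r,
    r_social = rs,
    as_tibble(anchors_t),
    as_tibble(anchors_s)
  )
}

#' Apply a prize and an inefficiency to valued projects
#'
#' Derives, from [value_projects()] output, all four perspective values and
#' both decisions under a given prize placement and direct-funding
#' inefficiency. The prize improvement is the closed-form lump-sum term
#' `prize * survival_at_entry / (1 + r)^t_entry`, so no schedule needs to be
#' rebuilt per intervention.
#'
#' @param valued Tibble from [value_projects()].
#' @param prize_phase `"none"` or one of `"P1"`..`"P4"`, `"M1"`.
#' @param prize_size Prize in million USD; scalar or one value per project.
#' @param inefficiency Direct-funding inefficiency fraction.
#' @return `valued` with columns `prize_phase`, `prize_size`, `improvement`,
#'   `enpv_intervened`, `enpv_indirect`, `enpv_direct`, `go_without`,
#'   `go_with` and `savings` (million USD per market approval, `NA` for
#'   projects the prize does not stimulate).
#' @export
apply_prize <- function(valued, prize_phase, prize_size,
                        inefficiency = 0) {
  if (identical(prize_phase, "none")) {
    improvement <- rep(0, nrow(valued))
    indirect <- rep(0, nrow(valued))
  } else {
    if (!prize_phase %in% .prize_phases) {
      stop("prize_phase must be 'none' or one of ",
           paste(.prize_phases, collapse = ", "), call. = FALSE)
    }
    tz <- valued[[paste0("t_", prize_phase)]]
    sz <- valued[[paste0("s_", prize_phase)]]
    improvement <- prize_size * sz / (1 + valued$r_private)^tz
    indirect <- -prize_size * sz / (1 + valued$r_social)^tz
  }
  direct <- -(1 + inefficiency) * valued$cost_pv_social
  out <- valued
  out$prize_phase <- prize_phase
  out$prize_size <- if (identical(prize_phase, "none")) 0 else prize_size
  out$improvement <- improvement
  out$enpv_intervened <- valued$enpv_private + improvement
  out$enpv_indirect <- indirect
  out$enpv_direct <- direct
  out$go_without <- valued$enpv_private >= 0
  out$go_with <- out$enpv_intervened >= 0
  out$savings <- ifelse(out$go_with, (direct - indirect) / valued$p0, NA_real_)
  out
}
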