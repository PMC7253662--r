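#' Baseline experiment: go-ratios, response fits and solved prizes
#'
#' Samples `n_samples` projects per indication, computes each project's
#' private ENPV and go-/no-decision, draws one logarithmically sampled prize
#' per project, and for every prize phase fits (a) the log-log
#' prize-to-improvement model on all projects and (b) the logistic
#' go-response model on the no-decision subset. Each logistic fit is
#' inverted at `target_pgo` to give the prize expected to convert that share
#' of no-decisions.
#'
#' @param params An [abx_parameters()] object.
#' @param n_samples Projects per indication (default 2000).
#' @param seed Integer seed; every indication draws from a deterministically
#'   derived substream so runs are reproducible and adding indications does
#'   not perturb the others.
#' @param target_pgo Target conditional go-probability for prize solving.
#' @param indications Indications to run (default: all six).
#' @param prize_phases Prize placements to evaluate (default: `P1`..`P4`,
#'   `M1`).
#' @return An object of class `abx_baseline`: list with tibbles `decisions`
#'   (per-indication go/no ratios), `fits` (both models per indication x
#'   phase), `prizes` (solved prize per indication x phase) and `meta`.
#' @examples
#' \donttest{
#' params <- abx_parameters()
#' bl <- run_baseline(params, n_samples = 500, seed = 1)
#' bl$decisions
#' }
#' @export
run_baseline <- function(params, n_samples = 2000, seed = 1,
                         target_pgo = 0.9, indications = .indications,
                         prize_phases = .prize_phases) {
  decisions <- list(); fits <- list(); prizes <- list()
  for (ii in seq_along(indications)) {
    ind <- indications[ii]
    sub_seed <- derive_seed(seed, purpose = 1L, index = ii)
    drawn <- withr::with_seed(sub_seed, {
      projects <- sample_projects(params, ind, n_samples)
      prize_draws <- sample_prizes(n_samples)
      list(projects = projects, prize = prize_draws)
    })
    valued <- value_projects(drawn$projects, params)
    go <- valued$enpv_private >= 0
    go_ratio <- mean(go)
    decisions[[ii]] <- tibble(
      indication = ind, n = n_samples,
      go = go_ratio, no = 1 - go_ratio
    )
    for (ph in prize_phases) {
      with_prize <- apply_prize(valued, ph, drawn$prize$prize_size)
      imp_fit <- fit_improvement(
        tibble(prize_size = with_prize$prize_size,
               improvement = with_prize$improvement),
        indication = ind, prize_phase = ph
      )
      no_pool <- with_prize[!with_prize$go_without, ]
      pgo_fit <- fit_pgo(
        tibble(prize_size = no_pool$prize_size, go_with = no_pool$go_with),
        indication = ind, prize_phase = ph
      )
      fits[[length(fits) + 1]] <- bind_rows(glance(imp_fit), glance(pgo_fit))
      prizes[[length(prizes) + 1]] <- tibble(
        indication = ind, prize_phase = ph, target_pgo = target_pgo,
        prize_size = solve_prize(pgo_fit, target_pgo)
      )
    }
  }
  structure(
    list(
      decisions = bind_rows(decisions),
      fits = bind_rows(fits),
      prizes = bind_rows(prizes),
      meta = list(n_samples = n_samples, seed = seed,
                  target_pgo = target_pgo, indications = indications,
                  prize_phases = prize_phases)
    ),
    class = "abx_baseline"
  )
}

#' @export
print.abx_baseline <- function(x, ...) {
  cat("<abx_baseline> n =", x$meta$n_samples, "per indication, seed",
      x$meta$seed, "\n")
  print(x$decisions)
  invisible(x)
}

#' @export
tidy.abx_baseline <- function(x, ...) x$fits

#' @export
glance.abx_baseline <- function(x, ...) {
  tibble(n_samples = x$meta$n_samples, seed = x$meta$seed,
         target_pgo = x$meta$target_pgo,
         n_indications = length(x$meta$indications),
         max_p_value = max(x$fits$p_value, na.rm = TRUE),
         any_separated = any(x$fits$separated))
}

# beta coefficients of the logistic fit for one indication x phase
pgo_fit_for <- function(baseline, ind, ph) {
  f <- baseline$fits
  row <- f[f$model == "pgo_logistic" & f$indication == ind &
             f$prize_phase == ph, ]
  if (nrow(row) != 1) {
    stop("no logistic fit for ", ind, " / ", ph, call. = FALSE)
  }
  new_abx_fit("pgo_logistic", ind, ph, row$beta0, row$beta1, row$n_obs,
              row$p_value, row$separated,
              se_beta0 = row$se_beta0, se_beta1 = row$se_beta1)
}

#' Grid experiment: mean cost savings over targets and inefficiencies
#'
#' For every combination of target go-probability and direct-funding
#' inefficiency, draws `n_per_cell` fresh projects, sizes the prize from the
#' baseline logistic fit at the cell's target, removes projects the prize
#' does not stimulate (intervened private ENPV below zero), and averages the
#' per-market-approval cost savings of direct over indirect funding. Cells
#' where no sampled project is stimulated are recorded as missing rather
#' than zero.
#'
#' @param baseline An [run_baseline()] result providing the response fits.
#' @param params The [abx_parameters()] object.
#' @param pgo_grid Target go-probabilities (default 40 values on
#'   `[0.5, 0.9875]`).
#' @param ineff_grid Inefficiencies (default 41 values on `[0, 1]`).
#' @param n_per_cell Projects per cell (default 10).
#' @param seed Integer seed.
#' @param indications,prize_phases Subsets to run (defaults: all).
#' @return A tibble of class `abx_grid`: one row per indication x phase x
#'   cell with `mean_cost_savings` (million USD per market approval) and
#'   `n_effective`.
#' @export
run_grid <- function(baseline, params,
                     pgo_grid = seq(0.5, 0.9875, length.out = 40),
                     ineff_grid = seq(0, 1, length.out = 41),
                     n_per_cell = 10, seed = 1,
                     indications = baseline$meta$indications,
                     prize_phases = baseline$meta$prize_phases) {
  cells <- list()
  for (ii in seq_along(indications)) {
    ind <- indications[ii]
    for (pp in seq_along(prize_phases)) {
      ph <- prize_phases[pp]
      fit <- pgo_fit_for(baseline, ind, ph)
      n_total <- n_per_cell * length(pgo_grid) * length(ineff_grid)
      sub_seed <- derive_seed(seed, purpose = 2L,
                              index = ii * 100L + pp)
      projects <- sample_projects(params, ind, n_total, seed = sub_seed)
      valued <- value_projects(projects, params)
      cell_idx <- 0L
      res <- vector("list", length(pgo_grid) * length(ineff_grid))
      for (gi in seq_along(pgo_grid)) {
        prize <- solve_prize(fit, pgo_grid[gi])
        for (ei in seq_along(ineff_grid)) {
          cell_idx <- cell_idx + 1L
          rows <- ((cell_idx - 1L) * n_per_cell + 1L):(cell_idx * n_per_cell)
          cell <- apply_prize(valued[rows, ], ph, prize,
                              inefficiency = ineff_grid[ei])
          kept <- cell$savings[cell$go_with]
          res[[cell_idx]] <- tibble(
            indication = ind, prize_phase = ph,
            target_pgo = pgo_grid[gi], inefficiency = ineff_grid[ei],
            prize_size = prize,
            mean_cost_savings = if (length(kept) > 0) mean(kept) else NA_real_,
            n_effective = length(kept)
          )
        }
      }
      cells[[length(cells) + 1]] <- bind_rows(res)
    }
  }
  out <- bind_rows(cells)
  class(out) <- c("abx_grid", class(out))
  out
}

#' Zero-savings frontier from a grid
#'
#' For each indication and prize phase, selects within every inefficiency
#' column the cell whose mean cost savings is closest to zero, restricted to
#' columns where the savings actually change sign, and fits a quadratic
#' polynomial of the target go-probability on inefficiency through those
#' points. The fitted curve estimates the largest go-probability a prize can
#' target before direct funding becomes equally expensive. Combinations with
#' fewer than three crossing columns are flagged and left unfitted.
#'
#' @param grid An [run_grid()] result.
#' @return A tibble of class `abx_frontier` with quadratic coefficients
#'   `a + b * inefficiency + c * inefficiency^2`, `n_points` and `flagged`.
#' @export
fit_frontier <- function(grid) {
  combos <- unique(grid[c("indication", "prize_phase")])
  out <- purrr::pmap_dfr(combos, function(indication, prize_phase) {
    g <- grid[grid$indication == indication &
                grid$prize_phase == prize_phase &
                !is.na(grid$mean_cost_savings), ]
    pts <- g %>%
      group_by(inefficiency) %>%
      summarise(
        crossing = min(mean_cost_savings) < 0 & max(mean_cost_savings) > 0,
        target_pgo = target_pgo[which.min(abs(mean_cost_savings))],
        .groups = "drop"
      ) %>%
      filter(crossing)
    if (nrow(pts) < 3) {
      return(tibble(indication = indication, prize_phase = prize_phase,
                    a = NA_real_, b = NA_real_, c = NA_real_,
                    n_points = nrow(pts), flagged = TRUE))
    }
    cf <- coef(lm(target_pgo ~ inefficiency + I(inefficiency^2), data = pts))
    tibble(indication = indication, prize_phase = prize_phase,
           a = unname(cf[1]), b = unname(cf[2]), c = unname(cf[3]),
           n_points = nrow(pts), flagged = FALSE)
  })
  class(out) <- c("abx_frontier", class(out))
  out
}

#' Scenario experiment: cost savings at fixed inefficiency and target
#'
#' Draws `n_samples` fresh projects per indication, and for every prize
#' phase sizes the prize from the baseline fits at `target_pgo`, removes
#' non-stimulated projects, and reports the mean per-market-approval cost
#' savings of direct funding (at the given inefficiency) over the prize,
#' together with the per-project cost distributions of both funding routes.
#'
#' @inheritParams run_grid
#' @param n_samples Projects per indication (default 1000).
#' @param inefficiency Direct-funding inefficiency (default 0.5).
#' @param target_pgo Target conditional go-probability (default 0.9).
#' @return An object of class `abx_scenario`: list with tibbles `savings`
#'   (mean savings per indication x phase), `samples` (per-project
#'   per-approval costs of both routes for retained projects) and `meta`.
#' @export
run_scenario <- function(baseline, params, n_samples = 1000,
                         inefficiency = 0.5, target_pgo = 0.9, seed = 1,
                         indications = baseline$meta$indications,
                         prize_phases = baseline$meta$prize_phases) {
  savings <- list(); samples <- list()
  for (ii in seq_along(indications)) {
    ind <- indications[ii]
    sub_seed <- derive_seed(seed, purpose = 3L, index = ii)
    projects <- sample_projects(params, ind, n_samples, seed = sub_seed)
    valued <- value_projects(projects, params)
    for (ph in prize_phases) {
      fit <- pgo_fit_for(baseline, ind, ph)
      prize <- solve_prize(fit, target_pgo)
      res <- apply_prize(valued, ph, prize, inefficiency = inefficiency)
      kept <- res[res$go_with, ]
      savings[[length(savings) + 1]] <- tibble(
        indication = ind, prize_phase = ph, prize_size = prize,
        mean_cost_savings = if (nrow(kept) > 0) mean(kept$savings)
                            else NA_real_,
        n_effective = nrow(kept), n = n_samples
      )
      samples[[length(samples) + 1]] <- tibble(
        indication = ind, prize_phase = ph, project = kept$project,
        direct_per_approval = -kept$enpv_direct / kept$p0,
        indirect_per_approval = -kept$enpv_indirect / kept$p0,
        savings = kept$savings
      )
    }
  }
  structure(
    list(savings = bind_rows(savings), samples = bind_rows(samples),
         meta = list(n_samples = n_samples, inefficiency = inefficiency,
                     target_pgo = target_pgo, seed = seed,
                     indications = indications,
                     prize_phases = prize_phases)),
    class = "abx_scenario"
  )
}

#' @export
print.abx_scenario <- function(x, ...) {
  cat("<abx_scenario> n =", x$meta$n_samples, "per indication, inefficiency",
      x$meta$inefficiency, ", target P(go)", x$meta$target_pgo, "\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.abx_scenario <- function(x, ...) {
  tidyr::pivot_wider(
    x$savings[c("indication", "prize_phase", "mean_cost_savings")],
    names_from = prize_phase, values_from = mean_cost_savings
  )
}

#' @export
glance.abx_scenario <- function(x, ...) {
  tibble(n_samples = x$meta$n_samples, inefficiency = x$meta$inefficiency,
         target_pgo = x$meta$target_pgo, seed = x$meta$seed,
         min_savings = min(x$savings$mean_cost_savings, na.rm = TRUE),
         max_savings = max(x$savings$mean_cost_savings, na.rm = TRUE))
}
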