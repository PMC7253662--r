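#' Load the development and market parameter tables
#'
#' Reads the packaged parameter tables (or a directory of user tables with the
#' same schema) describing hypothetical antibiotics for six indications:
#' per-phase development time, cost and probability-of-success triangulars,
#' market size, the 20-year market-share envelope, launch/generic-entry/
#' discount-rate parameters, and the additional cost items spread across
#' phases. All percentages are converted to fractions, all times to years and
#' all money is kept in million USD.
#'
#' @param path Directory containing the five parameter files
#'   (`phase_parameters.csv`, `market_size.csv`, `market_share.csv`,
#'   `additional_parameters.csv`, `additional_costs.csv`). Defaults to the
#'   tables shipped with the package.
#' @return An object of class `abx_parameters`: a list with tibbles `phases`,
#'   `market`, `shares`, `extra_costs`, the list `econ` of economy-wide
#'   parameters, and `tables`, the raw tables as read.
#' @examples
#' params <- abx_parameters()
#' params$phases
#' @export
abx_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", package = "abxfund")
  }
  files <- c(
    phases = "phase_parameters.csv",
    market = "market_size.csv",
    shares = "market_share.csv",
    extra_parameters = "additional_parameters.csv",
    extra_costs = "additional_costs.csv"
  )
  paths <- file.path(path, files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("parameter file(s) not found: ",
         paste(files[missing], collapse = ", "), call. = FALSE)
  }
  raw <- lapply(paths, function(p) {
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  })
  names(raw) <- names(files)

  phases <- raw$phases %>%
    rename(
      phase = "Phase", indication = "Indication",
      time_min = "Time min", time_mode = "Time mid", time_max = "Time max",
      cost_min = "Cost min", cost_mode = "Cost mid", cost_max = "Cost max",
      prob_min = "Prob min", prob_mode = "Prob mid", prob_max = "Prob max"
    ) %>%
    mutate(
      # a cell printed only as a mode is a fixed (degenerate) value
      cost_min = ifelse(is.na(cost_min), cost_mode, cost_min),
      cost_max = ifelse(is.na(cost_max), cost_mode, cost_max),
      across(all_of(c("time_min", "time_mode", "time_max")), ~ .x / 12),
      across(all_of(c("prob_min", "prob_mode", "prob_max")), ~ .x / 100)
    )

  market <- raw$market %>%
    rename(indication = "Indication", size_min = "Min", size_max = "Max")

  shares_raw <- raw$shares
  expand_years <- function(y) {
    if (grepl(":", y)) {
      r <- as.integer(strsplit(y, ":")[[1]])
      seq(r[1], r[2])
    } else {
      as.integer(y)
    }
  }
  shares <- purrr::pmap_dfr(shares_raw, function(Years, Min, Max) {
    tibble(year = expand_years(as.character(Years)),
           lower = Min / 100, upper = Max / 100)
  }) %>% arrange(year)

  ep <- raw$extra_parameters
  tri_row <- function(name, scale = 1) {
    r <- ep[ep$Parameter == name, ]
    if (nrow(r) != 1) stop("missing parameter row: ", name, call. = FALSE)
    c(min = r$Min / scale, mode = r$Mid / scale, max = r$Max / scale)
  }
  econ <- list(
    launch_success = tri_row("Launch success probability (%)", 100),
    generic_reduction = tri_row("Generic entry revenue reduction (%)", 100),
    generic_entry = tri_row("Generic entry (years)"),
    private_rate = tri_row("Private discount rate (%)", 100),
    social_rate = c(min = 0.035, max = 0.045),
    market_life = 20L
  )

  extra_costs <- raw$extra_costs %>%
    rename(item = "Activity", cost_min = "Min", cost_mode = "Mid",
           cost_max = "Max", spread = "Spread across") %>%
    mutate(allocation = purrr::map(spread, parse_allocation))

  out <- structure(
    list(phases = phases, market = market, shares = shares,
         extra_costs = extra_costs, econ = econ, tables = raw,
         source = normalizePath(path)),
    class = "abx_parameters"
  )
  validate_parameters(out)
}

# "P1, P2, P3" / "P3 (75%), P4 (25%)" / "M1, M2, M3" -> named weight vector
parse_allocation <- function(spread) {
  tokens <- trimws(strsplit(spread, ",")[[1]])
  m <- regmatches(tokens,
                  regexec("^(PC|P[1-4]|M[0-9]+)( \\(([0-9.]+)%\\))?$", tokens))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    stop("cannot parse cost allocation: ", spread, call. = FALSE)
  }
  targets <- vapply(m, `[`, character(1), 2)
  pct <- vapply(m, `[`, character(1), 4)
  if (all(pct == "")) {
    w <- rep(1 / length(targets), length(targets))
  } else if (all(pct != "")) {
    w <- as.numeric(pct) / 100
  } else {
    stop("allocation mixes weighted and unweighted targets: ", spread,
         call. = FALSE)
  }
  setNames(w, targets)
}

validate_parameters <- function(p) {
  chk <- function(ok, field, why) {
    if (!all(ok)) {
      stop(sprintf("invalid parameters: %s (%s)", field, why), call. = FALSE)
    }
  }
  ph <- p$phases
  chk(setequal(unique(ph$indication), .indications), "phases$indication",
      "expected exactly the six packaged indications")
  chk(setequal(unique(ph$phase), .dev_phases), "phases$phase",
      "expected phases PC, P1..P4")
  chk(nrow(ph) == 30, "phases", "expected 6 indications x 5 phases")
  for (v in c("time", "cost", "prob")) {
    lo <- ph[[paste0(v, "_min")]]; md <- ph[[paste0(v, "_mode")]]
    hi <- ph[[paste0(v, "_max")]]
    chk(lo <= md & md <= hi, paste0("phases$", v), "min <= mode <= max")
  }
  chk(ph$time_min > 0, "phases$time_min", "must be positive")
  chk(ph$prob_min >= 0 & ph$prob_max <= 1, "phases$prob",
      "probabilities must lie in [0, 1]")
  mk <- p$market
  chk(setequal(mk$indication, .indications), "market$indication",
      "expected exactly the six packaged indications")
  chk(is.na(mk$size_max) | mk$size_max >= mk$size_min, "market$size_max",
      "max must be at least min")
  sh <- p$shares
  chk(nrow(sh) == p$econ$market_life, "shares", "one row per market year")
  chk(sh$lower <= sh$upper, "shares", "lower bound above upper bound")
  chk(diff(sh$lower) >= 0 & diff(sh$upper) >= 0, "shares",
      "market share must be non-decreasing")
  ec <- p$extra_costs
  chk(ec$cost_min <= ec$cost_mode & ec$cost_mode <= ec$cost_max,
      "extra_costs", "min <= mode <= max")
  sums <- vapply(ec$allocation, sum, numeric(1))
  chk(abs(sums - 1) < 1e-9, "extra_costs$allocation", "weights must sum to 1")
  for (nm in c("launch_success", "generic_reduction", "generic_entry",
               "private_rate")) {
    tri <- p$econ[[nm]]
    chk(tri[1] <= tri[2] && tri[2] <= tri[3], paste0("econ$", nm),
        "min <= mode <= max")
  }
  p
}

#' @export
print.abx_parameters <- function(x, ...) {
  cat("<abx_parameters> ", nrow(x$phases), " phase rows, ",
      length(unique(x$phases$indication)), " indications, ",
      nrow(x$extra_costs), " additional cost items\n", sep = "")
  cat("source: ", x$source, "\n", sep = "")
  invisible(x)
}

#' Write parameter tables to a directory
#'
#' Serializes an [abx_parameters()] object back to the five CSV files it was
#' read from, preserving the original presentation (months, percent). A
#' written set of tables reloads to identical values.
#'
#' @param params An `abx_parameters` object.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_abx_parameters <- function(params, dir) {
  stopifnot(inherits(params, "abx_parameters"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    phases = "phase_parameters.csv",
    market = "market_size.csv",
    shares = "market_share.csv",
    extra_parameters = "additional_parameters.csv",
    extra_costs = "additional_costs.csv"
  )
  paths <- file.path(dir, files)
  for (i in seq_along(files)) {
    readr::write_csv(params$tables[[names(files)[i]]], paths[i], na = "")
  }
  invisible(paths)
}

#' Build and validate a run configuration
#'
#' Collects the economy-level knobs of a simulation run: the benefactor's
#' inefficiency fraction applied to direct funding, the prize placement and
#' size, the social discount-rate band, the sample count and the seed.
#'
#' @param inefficiency Fractional cost inflation of direct funding, in
#'   `[0, 1]` (larger values require `allow_extreme = TRUE`).
#' @param prize_phase One of `"none"`, `"P1"`..`"P4"`, `"M1"`.
#' @param prize_size Prize in million USD, `>= 0`.
#' @param social_discount_low,social_discount_high Annual social discount
#'   rate band (fractions); defaults 0.035 and 0.045.
#' @param n_samples Projects per indication; `NULL` lets each experiment pick
#'   its default.
#' @param seed Integer seed.
#' @param allow_extreme Permit inefficiency above 1.
#' @return A validated list of class `abx_config`.
#' @examples
#' abx_config(inefficiency = 0.5, prize_phase = "M1", prize_size = 100)
#' @export
abx_config <- function(inefficiency = 0, prize_phase = "none",
                       prize_size = 0, social_discount_low = 0.035,
                       social_discount_high = 0.045, n_samples = NULL,
                       seed = 1L, allow_extreme = FALSE) {
  cfg <- list(
    inefficiency = inefficiency, prize_phase = prize_phase,
    prize_size = prize_size, social_discount_low = social_discount_low,
    social_discount_high = social_discount_high, n_samples = n_samples,
    seed = as.integer(seed), allow_extreme = isTRUE(allow_extreme)
  )
  validate_abx_config(cfg)
}

validate_abx_config <- function(cfg) {
  if (!cfg$prize_phase %in% c("none", .prize_phases)) {
    stop("prize_phase must be one of none, ",
         paste(.prize_phases, collapse = ", "),
         " (pre-clinical entry prizes are not modelled)", call. = FALSE)
  }
  if (cfg$prize_size < 0) stop("prize_size must be >= 0", call. = FALSE)
  if (cfg$inefficiency < 0 ||
      (cfg$inefficiency > 1 && !cfg$allow_extreme)) {
    stop("inefficiency must lie in [0, 1] unless allow_extreme = TRUE",
         call. = FALSE)
  }
  if (cfg$social_discount_low > cfg$social_discount_high ||
      cfg$social_discount_low < 0) {
    stop("social discount band must satisfy 0 <= low <= high", call. = FALSE)
  }
  if (!is.null(cfg$n_samples) &&
      (cfg$n_samples < 1 || cfg$n_samples != round(cfg$n_samples))) {
    stop("n_samples must be a positive integer", call. = FALSE)
  }
  structure(cfg, class = "abx_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [abx_config()].
#' @return A validated `abx_config`.
#' @export
read_abx_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(abx_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(abx_config, vals)
}
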