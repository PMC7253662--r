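#' Write experiment results as CSV tables
#'
#' Serializes results to CSV files mirroring the presentation of the
#' published tables: probabilities as percentages, money in million USD,
#' with `Min`/`Max` summary rows on the prize and savings tables. A run
#' manifest (configuration echo, seed, fixture checksum, package version)
#' is written beside the tables so a run can be reproduced exactly.
#'
#' @param x An `abx_baseline`, `abx_grid`, `abx_frontier` or `abx_scenario`
#'   object.
#' @param dir Output directory, created if needed.
#' @param ... Unused.
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(x, dir, ...) UseMethod("write_tables")

#' @export
write_tables.abx_baseline <- function(x, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t6 <- x$decisions %>%
    mutate(Go = 100 * go, No = 100 * no) %>%
    select(Indication = indication, Go, No) %>%
    arrange(dplyr::desc(Go))
  p6 <- file.path(dir, "table6.csv")
  readr::write_csv(t6, p6)
  wide <- tidyr::pivot_wider(
    x$prizes[c("indication", "prize_phase", "prize_size")],
    names_from = prize_phase, values_from = prize_size
  ) %>% rename(Indication = indication)
  phase_cols <- setdiff(names(wide), "Indication")
  summary_rows <- bind_rows(
    c(Indication = "Min", purrr::map(wide[phase_cols], min)),
    c(Indication = "Max", purrr::map(wide[phase_cols], max))
  )
  t7 <- bind_rows(wide, summary_rows)
  p7 <- file.path(dir, "table7.csv")
  readr::write_csv(t7, p7)
  pf <- file.path(dir, "fits.csv")
  readr::write_csv(x$fits, pf)
  write_run_manifest(dir, meta = x$meta)
  invisible(c(p6, p7, pf))
}

#' @export
write_tables.abx_grid <- function(x, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, "grid.csv")
  readr::write_csv(as_tibble(x), p, na = "")
  write_run_manifest(dir)
  invisible(p)
}

#' @export
write_tables.abx_frontier <- function(x, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, "frontier.csv")
  readr::write_csv(as_tibble(x), p, na = "")
  write_run_manifest(dir)
  invisible(p)
}

#' @export
write_tables.abx_scenario <- function(x, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- tidy(x) %>% rename(Indication = indication)
  phase_cols <- setdiff(names(wide), "Indication")
  summary_rows <- bind_rows(
    c(Indication = "Min", purrr::map(wide[phase_cols], min, na.rm = TRUE)),
    c(Indication = "Max", purrr::map(wide[phase_cols], max, na.rm = TRUE))
  )
  t8 <- bind_rows(wide, summary_rows)
  p8 <- file.path(dir, "table8.csv")
  readr::write_csv(t8, p8, na = "")
  pd <- file.path(dir, "fig4_distributions.csv")
  readr::write_csv(x$samples, pd)
  write_run_manifest(dir, meta = x$meta)
  invisible(c(p8, pd))
}

#' Write a machine-readable run manifest
#'
#' @param dir Directory to write `manifest.json` into.
#' @param meta Optional list of run metadata (seed, sample sizes, ...).
#' @param params_path Path of the parameter fixture used (defaults to the
#'   packaged tables); the manifest stores a checksum of every file.
#' @return Invisibly, the manifest path.
#' @export
write_run_manifest <- function(dir, meta = list(), params_path = NULL) {
  if (is.null(params_path)) {
    params_path <- system.file("extdata", package = "abxfund")
  }
  files <- sort(list.files(params_path, pattern = "\\.csv$",
                           full.names = TRUE))
  manifest <- list(
    package = "abxfund",
    version = as.character(utils::packageVersion("abxfund")),
    meta = meta,
    fixture_checksums = as.list(tools::md5sum(files))
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatches `baseline`, `grid` and `scenario` subcommands over the
#' package's experiment functions. Flags: `--seed`, `--n-samples`,
#' `--out <dir>`, `--params <dir>` (override the packaged tables),
#' `--target-pgo`, `--inefficiency`, `--dry-run` (validate and print the
#' resolved configuration without simulating), `--quiet`.
#'
#' @param argv Character vector of arguments (defaults to the command
#'   line).
#' @return Exit status, invisibly: 0 on success, 1 on usage or validation
#'   errors.
#' @export
abx_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: abxfund <baseline|grid|scenario> [--seed N] [--n-samples N]",
    "[--out DIR] [--params DIR] [--target-pgo X] [--inefficiency X]",
    "[--dry-run] [--quiet]"
  )
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(if (length(argv) == 0) 1L else 0L))
  }
  cmd <- argv[1]
  if (!cmd %in% c("baseline", "grid", "scenario")) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(invisible(1L))
  }
  opts <- list(seed = 1L, n_samples = NULL, out = "abxfund-out",
               params = NULL, target_pgo = 0.9, inefficiency = 0.5,
               dry_run = FALSE, quiet = FALSE)
  i <- 2L
  while (i <= length(argv)) {
    a <- argv[i]
    take <- function() {
      if (i + 1L > length(argv)) stop("missing value for ", a, call. = FALSE)
      argv[i + 1L]
    }
    res <- tryCatch({
      switch(a,
        "--seed" = { opts$seed <- as.integer(take()); i <- i + 2L },
        "--n-samples" = { opts$n_samples <- as.integer(take()); i <- i + 2L },
        "--out" = { opts$out <- take(); i <- i + 2L },
        "--params" = { opts$params <- take(); i <- i + 2L },
        "--target-pgo" = { opts$target_pgo <- as.numeric(take()); i <- i + 2L },
        "--inefficiency" = { opts$inefficiency <- as.numeric(take()); i <- i + 2L },
        "--dry-run" = { opts$dry_run <- TRUE; i <- i + 1L },
        "--quiet" = { opts$quiet <- TRUE; i <- i + 1L },
        stop("unknown flag: ", a, call. = FALSE)
      )
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      message(res, "\n", usage)
      return(invisible(1L))
    }
  }
  log_msg <- function(...) if (!opts$quiet) message(...)
  result <- tryCatch({
    params <- abx_parameters(opts$params)
    n_default <- c(baseline = 2000L, grid = 2000L, scenario = 1000L)[[cmd]]
    n <- if (is.null(opts$n_samples)) n_default else opts$n_samples
    if (opts$dry_run) {
      log_msg("dry run: configuration valid")
      log_msg(sprintf("  command=%s seed=%d n_samples=%d out=%s", cmd,
                      opts$seed, n, opts$out))
      log_msg(sprintf("  target_pgo=%.4f inefficiency=%.2f",
                      opts$target_pgo, opts$inefficiency))
      return(invisible(0L))
    }
    log_msg("running baseline (", n, " projects per indication)")
    baseline <- run_baseline(params, n_samples = n, seed = opts$seed,
                             target_pgo = opts$target_pgo)
    if (cmd == "baseline") {
      write_tables(baseline, opts$out)
    } else if (cmd == "grid") {
      log_msg("running grid sweep")
      grid <- run_grid(baseline, params, seed = opts$seed)
      write_tables(grid, opts$out)
      write_tables(fit_frontier(grid), opts$out)
    } else {
      log_msg("running scenario")
      n_sc <- if (is.null(opts$n_samples)) 1000L else opts$n_samples
      scenario <- run_scenario(baseline, params, n_samples = n_sc,
                               inefficiency = opts$inefficiency,
                               target_pgo = opts$target_pgo,
                               seed = opts$seed)
      write_tables(scenario, opts$out)
    }
    log_msg("wrote results to ", opts$out)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(result)
}
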