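#' Fit the log-log prize-to-improvement model
#'
#' Ordinary least squares of `log10(improvement)` on `log10(prize_size)`,
#' fitted to one indication and prize-phase combination at a time. The
#' log-log form absorbs the strong heteroscedasticity of the raw
#' improvement: a lump-sum prize improves the intervened ENPV by
#' `prize * survival / (1 + r)^t`, so improvements are exactly positive and
#' close to log-linear in prize size with unit slope, and residual spread
#' comes from the per-project survival, timing and discount draws.
#'
#' @param data Tibble with columns `prize_size` (million USD, positive) and
#'   `improvement` (million USD, positive).
#' @param indication,prize_phase Optional labels stored on the fit.
#' @return An object of class `abx_fit` with fields `beta0`, `beta1`,
#'   `n_obs`, `p_value` (slope Wald test) and `model = "improvement_loglog"`.
#' @examples
#' d <- tibble::tibble(prize_size = 10^runif(50, 0, 4))
#' d$improvement <- 0.05 * d$prize_size^1
#' fit_improvement(d)
#' @export
fit_improvement <- function(data, indication = NA_character_,
                            prize_phase = NA_character_) {
  if (nrow(data) < 3) {
    stop("at least 3 observations are required", call. = FALSE)
  }
  if (any(data$prize_size <= 0)) {
    stop("prize sizes must be positive", call. = FALSE)
  }
  if (any(data$improvement <= 0)) {
    stop("improvements must be positive (a prize always improves ENPV)",
         call. = FALSE)
  }
  fit <- lm(log10(improvement) ~ log10(prize_size), data = data)
  cf <- coef(fit)
  sm <- summary(fit)$coefficients
  p_slope <- if (nrow(sm) >= 2) sm[2, 4] else NA_real_
  new_abx_fit("improvement_loglog", indication, prize_phase,
              beta0 = unname(cf[1]), beta1 = unname(cf[2]),
              se_beta0 = unname(sm[1, 2]),
              se_beta1 = if (nrow(sm) >= 2) unname(sm[2, 2]) else NA_real_,
              n_obs = nrow(data), p_value = p_slope, separated = FALSE)
}

#' Fit the logistic prize-response model
#'
#' Maximum-likelihood logistic regression of the binary stimulated
#' go-decision on `log10(prize_size)`:
#' `logit P(go) = beta0 + beta1 * log10(prize_size)`. The model is meant to
#' be fitted only to projects that faced a no-decision without the
#' intervention, so the fitted probability is the conditional probability of
#' turning a no-decision into a go-decision. If the data are completely (or
#' quasi-completely) separated the fit is rerun with a mild ridge penalty
#' and flagged via `separated = TRUE` rather than silently returned.
#'
#' @param data Tibble with columns `prize_size` (million USD) and `go_with`
#'   (logical); both outcome classes must be present.
#' @inheritParams fit_improvement
#' @return An `abx_fit` with `model = "pgo_logistic"`.
#' @export
fit_pgo <- function(data, indication = NA_character_,
                    prize_phase = NA_character_) {
  if (nrow(data) < 3) {
    stop("at least 3 observations are required", call. = FALSE)
  }
  if (any(data$prize_size <= 0)) {
    stop("prize sizes must be positive", call. = FALSE)
  }
  y <- as.logical(data$go_with)
  if (length(unique(y)) < 2) {
    stop("both go and no outcomes are required to fit the response model",
         call. = FALSE)
  }
  x <- log10(data$prize_size)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(fit)
  sm <- summary(fit)$coefficients
  p_slope <- if (nrow(sm) >= 2) sm[2, 4] else NA_real_
  se <- c(sm[1, 2], if (nrow(sm) >= 2) sm[2, 2] else NA_real_)
  if (separated || any(!is.finite(cf)) || abs(cf[2]) > 100) {
    cf <- ridge_logistic(x, y)
    separated <- TRUE
    p_slope <- NA_real_
    se <- c(NA_real_, NA_real_)
  }
  new_abx_fit("pgo_logistic", indication, prize_phase,
              beta0 = unname(cf[1]), beta1 = unname(cf[2]),
              se_beta0 = unname(se[1]), se_beta1 = unname(se[2]),
              n_obs = length(y), p_value = p_slope, separated = separated)
}

# Mildly penalized logistic fit used when ML estimates do not exist
# (complete separation); keeps the curve finite and monotone.
ridge_logistic <- function(x, y, lambda = 1e-3) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    log_denom <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    -sum(y * eta - log_denom) + lambda * sum(b^2)
  }
  stats::optim(c(0, 1), nll, method = "BFGS")$par
}

new_abx_fit <- function(model, indication, prize_phase, beta0, beta1,
                        n_obs, p_value, separated,
                        se_beta0 = NA_real_, se_beta1 = NA_real_) {
  structure(
    list(model = model, indication = indication, prize_phase = prize_phase,
         beta0 = beta0, beta1 = beta1,
         se_beta0 = se_beta0, se_beta1 = se_beta1,
         n_obs = n_obs, p_value = p_value, separated = separated),
    class = "abx_fit"
  )
}

#' @export
print.abx_fit <- function(x, ...) {
  cat(sprintf("<abx_fit %s> %s / %s: beta0 = %.4f, beta1 = %.4f, n = %d%s\n",
              x$model, x$indication, x$prize_phase, x$beta0, x$beta1,
              x$n_obs, if (x$separated) " (separated; ridge)" else ""))
  invisible(x)
}

#' @export
tidy.abx_fit <- function(x, ...) {
  tibble(term = c("beta0", "beta1"), estimate = c(x$beta0, x$beta1),
         std.error = c(x$se_beta0, x$se_beta1))
}

#' @export
glance.abx_fit <- function(x, ...) {
  tibble(model = x$model, indication = x$indication,
         prize_phase = x$prize_phase, beta0 = x$beta0, beta1 = x$beta1,
         se_beta0 = x$se_beta0, se_beta1 = x$se_beta1,
         n_obs = x$n_obs, p_value = x$p_value, separated = x$separated)
}

#' Predict the conditional go-probability for a prize size
#'
#' Logistic transform of `beta0 + beta1 * log10(prize_size)`; strictly
#' inside `(0, 1)`.
#'
#' @param fit A `pgo_logistic` [fit_pgo()] object.
#' @param prize_size Prize in million USD (positive).
#' @return Probability vector.
#' @export
predict_pgo <- function(fit, prize_size) {
  stopifnot(inherits(fit, "abx_fit"))
  if (any(prize_size <= 0)) {
    stop("prize_size must be positive", call. = FALSE)
  }
  plogis(fit$beta0 + fit$beta1 * log10(prize_size))
}

#' Solve for the prize size reaching a target go-probability
#'
#' Analytic inversion of the logistic response:
#' `prize = 10^((logit(target) - beta0) / beta1)`.
#'
#' @param fit A `pgo_logistic` [fit_pgo()] object with nonzero slope.
#' @param target_pgo Target conditional go-probability, strictly in (0, 1).
#' @return Prize size in million USD.
#' @export
solve_prize <- function(fit, target_pgo) {
  stopifnot(inherits(fit, "abx_fit"))
  if (any(target_pgo <= 0 | target_pgo >= 1)) {
    stop("target_pgo must lie strictly between 0 and 1", call. = FALSE)
  }
  if (fit$beta1 == 0) {
    stop("response slope is zero; prize size is unidentified", call. = FALSE)
  }
  10^((qlogis(target_pgo) - fit$beta0) / fit$beta1)
}
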