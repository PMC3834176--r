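#' Fit a log-probit dose-response curve to quantal data
#'
#' Maximum-likelihood probit regression of quantal response on log10 dose,
#' the modern equivalent of classical log-probit analysis. The model is
#' `probit(p_i) = slope * (log10(dose_i) - log10(ED50))`, with the probit
#' taken on the standard-normal quantile scale, so the fitted curve passes
#' through 50% response at the ED50 by construction. The Bernoulli
#' log-likelihood is maximized by iteratively reweighted least squares
#' (convergence tolerance 1e-10, at most 200 iterations); groups with 0%
#' or 100% response enter the likelihood as-is, without continuity
#' correction.
#'
#' The 95% confidence limits are computed on the log10 scale as
#' `log10(ED50) +/- 1.96 * SE(log10 ED50)` (delta-method standard error
#' from the ML covariance) and then exponentiated. The SEM on the
#' arithmetic dose scale is the delta-method back-transform
#' `ED50 * ln(10) * SE(log10 ED50)`, consistent with [ci_to_sem()].
#'
#' @param groups A [dose_groups()] data frame (or coercible data frame)
#'   with at least two distinct doses; responses must not be all zero nor
#'   all `n_total`, otherwise the ED50 is not estimable and an error is
#'   raised. Non-convergence is flagged via the `converged` element (with
#'   a warning), never silently ignored.
#'
#' @return An object of class `probit_fit`: a list with elements
#'   `ed50`, `slope` (probits per log10-dose unit), `log_ed50`,
#'   `ci95_lower`, `ci95_upper`, `sem_log`, `sem`, `n_window`
#'   (animals in the 4-6 probit window, see [probit_window_n()]),
#'   `converged`, and `n_groups`.
#' @seealso [probit_window_n()], [ci_to_sem()], [summary_fit()]
#' @export
#' @examples
#' g <- dose_groups(c(20, 30, 45, 70), 8, c(1, 3, 5, 7))
#' fit_log_probit(g)
fit_log_probit <- function(groups) {
  groups <- dose_groups(groups)
  if (length(unique(groups$dose)) < 2L) {
    stop("at least two distinct doses are required", call. = FALSE)
  }
  r <- groups$n_responding
  n <- groups$n_total
  if (all(r == 0) || all(r == n)) {
    stop("ED50 not estimable: all responses on one side", call. = FALSE)
  }

  fit <- suppressWarnings(stats::glm(
    cbind(n_responding, n_total - n_responding) ~ log10(dose),
    family = stats::binomial(link = "probit"),
    data = groups,
    control = stats::glm.control(epsilon = 1e-10, maxit = 200)
  ))
  b <- unname(stats::coef(fit))
  slope <- b[2]
  if (!is.finite(slope) || slope <= 0) {
    stop("ED50 not estimable: no increasing dose-response trend", call. = FALSE)
  }
  log_ed50 <- -b[1] / slope
  ed50 <- 10^log_ed50

  # delta-method SE of log10(ED50) = -b1/b2 from the ML covariance
  V <- stats::vcov(fit)
  grad <- c(-1 / slope, b[1] / slope^2)
  se_log <- sqrt(drop(t(grad) %*% V %*% grad))

  converged <- isTRUE(fit$converged) && is.finite(se_log) && se_log >= 0
  if (!converged) {
    warning("log-probit fit did not converge; estimates are unreliable",
            call. = FALSE)
    se_log <- if (is.finite(se_log)) se_log else NA_real_
  }

  out <- structure(list(
    ed50 = ed50,
    slope = slope,
    log_ed50 = log_ed50,
    ci95_lower = 10^(log_ed50 - 1.96 * se_log),
    ci95_upper = 10^(log_ed50 + 1.96 * se_log),
    sem_log = se_log,
    sem = ed50 * log(10) * se_log,
    n_window = NA_integer_,
    converged = converged,
    n_groups = nrow(groups)
  ), class = "probit_fit")
  out$n_window <- if (converged) probit_window_n(out, groups) else NA_integer_
  out
}

#' Transform 95% confidence limits of an ED50 to SEM
#'
#' Confidence limits from log-probit analysis are symmetric on the log10
#' scale, so the standard error is recovered there and carried back to the
#' arithmetic dose scale by the delta method:
#' `sem_log = (log10(upper) - log10(lower)) / (2 * 1.96)` and
#' `sem = ed50 * ln(10) * sem_log`.
#'
#' @param ed50 Median effective dose (mg/kg).
#' @param lower,upper 95% confidence limits (mg/kg), with
#'   `0 < lower <= ed50 <= upper`; a zero-width interval yields 0.
#' @return SEM on the arithmetic dose scale (mg/kg).
#' @export
#' @examples
#' ci_to_sem(48.61, 39.18, 60.31) # 5.35 mg/kg
ci_to_sem <- function(ed50, lower, upper) {
  if (!all(is.finite(c(ed50, lower, upper)))) {
    stop("ed50 and confidence limits must be finite", call. = FALSE)
  }
  if (lower <= 0 || lower > ed50 || upper < ed50) {
    stop("confidence limits must satisfy 0 < lower <= ed50 <= upper",
         call. = FALSE)
  }
  sem_log <- (log10(upper) - log10(lower)) / (2 * 1.96)
  ed50 * log(10) * sem_log
}

#' Animals within the 4-6 probit response window
#'
#' Counts the animals in groups whose fitted response probability lies
#' between 4 and 6 probits on the classical 5-centred probit scale, i.e.
#' in `[pnorm(-1), pnorm(1)]`, roughly 16-84% response. This is the `n`
#' conventionally reported alongside a log-probit ED50 and the `n` used in
#' the Welch comparison of experimental and additive ED50s.
#'
#' @param fit A converged [fit_log_probit()] result.
#' @param groups The [dose_groups()] the curve was fitted to (or any dose
#'   groups to evaluate against the fitted curve).
#' @return Integer: the sum of `n_total` over groups inside the window.
#' @export
probit_window_n <- function(fit, groups) {
  if (!inherits(fit, "probit_fit")) {
    stop("'fit' must be a probit_fit object", call. = FALSE)
  }
  if (!is.finite(fit$slope)) {
    stop("probit window requires a fitted slope (raw-data fit)", call. = FALSE)
  }
  if (isFALSE(fit$converged)) {
    stop("probit window requires a converged fit", call. = FALSE)
  }
  groups <- dose_groups(groups)
  p <- stats::pnorm(fit$slope * (log10(groups$dose) - fit$log_ed50))
  window <- p >= stats::pnorm(-1) & p <= stats::pnorm(1)
  as.integer(sum(groups$n_total[window]))
}

#' Build a fit summary from published ED50 and confidence limits
#'
#' Many studies print only the ED50 with its 95% confidence limits (and
#' the probit-window n). `summary_fit()` packs those into the same
#' container as [fit_log_probit()] so downstream additivity predictions
#' and interaction tests run identically in summary mode; the slope is
#' unknown and recorded as `NA`.
#'
#' @param ed50 Median effective dose (mg/kg).
#' @param ci95_lower,ci95_upper 95% confidence limits (mg/kg).
#' @param n Probit-window animal count reported with the fit, if any.
#' @return A `probit_fit` object with `sem` derived via [ci_to_sem()].
#' @export
#' @examples
#' summary_fit(48.61, 39.18, 60.31, n = 22)
summary_fit <- function(ed50, ci95_lower, ci95_upper, n = NA_integer_) {
  sem <- ci_to_sem(ed50, ci95_lower, ci95_upper)
  structure(list(
    ed50 = ed50,
    slope = NA_real_,
    log_ed50 = log10(ed50),
    ci95_lower = ci95_lower,
    ci95_upper = ci95_upper,
    sem_log = (log10(ci95_upper) - log10(ci95_lower)) / (2 * 1.96),
    sem = sem,
    n_window = as.integer(n),
    converged = NA,
    n_groups = NA_integer_
  ), class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Log-probit dose-response fit\n")
  cat(sprintf("  ED50: %.4g mg/kg (95%% CL %.4g-%.4g), SEM %.4g\n",
              x$ed50, x$ci95_lower, x$ci95_upper, x$sem))
  if (is.finite(x$slope)) {
    cat(sprintf("  slope: %.4g probits per log10-dose unit\n", x$slope))
  } else {
    cat("  slope: unknown (summary mode)\n")
  }
  if (!is.na(x$n_window)) {
    cat(sprintf("  n (4-6 probit window): %d\n", x$n_window))
  }
  if (isFALSE(x$converged)) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' @param fit A `probit_fit` object.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON text (invisibly, when written to `path`).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "probit_fit"))
  fields <- fit[c("ed50", "slope", "log_ed50", "ci95_lower", "ci95_upper",
                  "sem_log", "sem", "n_window", "converged")]
  json <- jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
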