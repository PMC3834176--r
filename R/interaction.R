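#' Welch's t-test from summary statistics
#'
#' Unpaired two-sample t-test with Welch's correction computed from group
#' means, standard errors of the means, and sample sizes — the form used
#' to compare an experimentally derived ED50 with a theoretically
#' calculated additive ED50, where only summary statistics exist. The
#' statistic is `t = (mean2 - mean1) / sqrt(sem1^2 + sem2^2)` and the
#' Welch-Satterthwaite degrees of freedom are
#' `(sem1^2 + sem2^2)^2 / (sem1^4/(n1-1) + sem2^4/(n2-1))` (fractional df,
#' not rounded). The p-value is two-sided.
#'
#' @param mean1,mean2 Group means (e.g. ED50s in mg/kg).
#' @param sem1,sem2 Standard errors of the means; nonnegative, not both
#'   zero.
#' @param n1,n2 Sample sizes, at least 2 each.
#' @return An object of class `htest` with `statistic` (t), `parameter`
#'   (df) and `p.value`.
#' @export
#' @examples
#' welch_t(51.66, 5.85, 32, 97.22, 10.69, 22) # t = 3.74, p < 0.001
welch_t <- function(mean1, sem1, n1, mean2, sem2, n2) {
  vals <- c(mean1, sem1, n1, mean2, sem2, n2)
  if (!all(is.finite(vals))) stop("all arguments must be finite", call. = FALSE)
  if (sem1 < 0 || sem2 < 0) stop("SEMs must be nonnegative", call. = FALSE)
  if (sem1 == 0 && sem2 == 0) {
    stop("t is undefined when both SEMs are zero", call. = FALSE)
  }
  if (n1 < 2 || n2 < 2) stop("sample sizes must be at least 2", call. = FALSE)

  v <- sem1^2 + sem2^2
  t <- (mean2 - mean1) / sqrt(v)
  df <- v^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)

  structure(list(
    statistic = c(t = t),
    parameter = c(df = df),
    p.value = p,
    estimate = c(`mean 1` = mean1, `mean 2` = mean2),
    method = "Welch two-sample t-test from summary statistics",
    data.name = sprintf("mean 1 = %g +/- %g (n = %g) vs mean 2 = %g +/- %g (n = %g)",
                        mean1, sem1, n1, mean2, sem2, n2)
  ), class = "htest")
}

#' Classify a drug-drug interaction against the additivity prediction
#'
#' Runs [welch_t()] on the experimental mixture ED50 (`ed50_exp` +/-
#' `sem_exp`, `n_exp`) versus the theoretical additive ED50 (`ed50_add`
#' +/- `sem_add`, `n_add`) and labels the interaction:
#' *supra-additive* (synergistic) when the experimental ED50 is
#' significantly below the additive one, *sub-additive* (antagonistic)
#' when significantly above, and *additive* otherwise. The significance
#' code is the most stringent of the alpha levels still exceeded by the
#' two-sided p-value (conventionally starred `*`, `**`, `***`).
#'
#' @param mix A [mixture_fit()] (or list with `ed50_exp`/`ed50`,
#'   `sem_exp`/`sem`, `n_exp`/`n`).
#' @param add An [additive_ed50()] prediction (or list with `ed50_add`,
#'   `sem_add`, `n_add`).
#' @param alpha_levels Decreasing significance thresholds; the default
#'   0.05/0.01/0.001 mirrors the usual one/two/three-star convention.
#' @return Object of class `interaction_result`: list with `t`, `df`,
#'   `p`, `significance` (`"ns"`, `"0.05"`, `"0.01"` or `"0.001"`),
#'   `label` (`"supra-additive"`, `"additive"`, `"sub-additive"`),
#'   `ed50_exp`, `ed50_add` and the underlying `htest`.
#' @export
classify_interaction <- function(mix, add,
                                 alpha_levels = c(0.05, 0.01, 0.001)) {
  get1 <- function(x, nm) for (n in nm) if (!is.null(x[[n]]) && !is.na(x[[n]])) return(x[[n]])
  m1 <- get1(mix, c("ed50_exp", "ed50"))
  s1 <- get1(mix, c("sem_exp", "sem"))
  n1 <- get1(mix, c("n_exp", "n_window", "n"))
  m2 <- get1(add, c("ed50_add", "ed50"))
  s2 <- get1(add, c("sem_add", "sem"))
  n2 <- get1(add, c("n_add", "n_window", "n"))
  if (any(vapply(list(m1, s1, n1, m2, s2, n2), is.null, logical(1)))) {
    stop("mix and add must carry ed50, sem and n summaries", call. = FALSE)
  }
  alpha_levels <- sort(as.numeric(alpha_levels), decreasing = TRUE)
  if (any(alpha_levels <= 0 | alpha_levels >= 1)) {
    stop("alpha levels must lie in (0, 1)", call. = FALSE)
  }

  ht <- welch_t(m1, s1, n1, m2, s2, n2)
  p <- ht$p.value
  passed <- alpha_levels[p < alpha_levels]
  significance <- if (length(passed) == 0L) "ns" else format(min(passed), trim = TRUE)
  label <- if (p < max(alpha_levels)) {
    if (m1 < m2) "supra-additive" else "sub-additive"
  } else "additive"

  structure(list(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = p,
    significance = significance,
    label = label,
    ed50_exp = m1,
    ed50_add = m2,
    htest = ht
  ), class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  stars <- c("0.05" = "*", "0.01" = "**", "0.001" = "***", ns = "")
  cat(sprintf("%s interaction%s: ED50_exp %.4g vs ED50_add %.4g\n",
              x$label, stars[[x$significance]], x$ed50_exp, x$ed50_add))
  cat(sprintf("  Welch t = %.3f, df = %.2f, p = %.4g (%s)\n",
              x$t, x$df, x$p,
              if (x$significance == "ns") "n.s." else paste0("p < ", x$significance)))
  invisible(x)
}
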