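#' Run a full type II combination analysis
#'
#' Chains the whole pipeline for one effective/ineffective drug pair over
#' a set of fixed ratios: alone-drug log-probit fit (or published
#' summary), CI-to-SEM transform, theoretical additive ED50 per ratio,
#' component-dose decomposition, and Welch classification of every
#' mixture against its additivity prediction. Two input modes are
#' supported, reflecting how such studies are published:
#'
#' * **raw mode** — `alone` and each element of `mixtures` are
#'   [dose_groups()] tables of quantal data; everything is fitted here.
#' * **summary mode** — `alone` is a [summary_fit()] (ED50 + 95% CL) and
#'   each mixture a list `list(ed50 = , sem = , n = )` of published
#'   summaries.
#'
#' The two modes can be mixed per input. Per-ratio failures are raised
#' with the offending ratio named; partial results are never silently
#' dropped.
#'
#' @param alone Alone-drug input (see modes above).
#' @param mixtures List, one element per ratio (raw table, summary list,
#'   or [mixture_fit()]).
#' @param ratios Character vector of "a:b" strings or list of
#'   [fixed_ratio()] objects; each ratio may appear only once.
#' @param n_add Animal count for the additive prediction; defaults to the
#'   alone fit's probit-window n when available.
#' @param effective_drug,ineffective_drug Display names.
#' @param alpha_levels Significance thresholds for
#'   [classify_interaction()].
#' @return Object of class `combination_study`: list with `effective_drug`,
#'   `ineffective_drug`, `alone` (the `probit_fit`), and `rows` — one
#'   entry per ratio holding the `fixed_ratio`, `additive_prediction`,
#'   `mixture_fit` and `interaction_result`. Use
#'   [as.data.frame.combination_study()] for a flat full-precision table,
#'   [render_table()] for the formatted report and [render_isobologram()]
#'   for the plot.
#' @export
run_combination_analysis <- function(alone, mixtures, ratios, n_add = NULL,
                                     effective_drug = "drug 1",
                                     ineffective_drug = "drug 2",
                                     alpha_levels = c(0.05, 0.01, 0.001)) {
  ratios <- lapply(ratios, parse_ratio)
  labels <- vapply(ratios, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("each fixed ratio may appear only once: duplicated ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(mixtures) || length(mixtures) != length(ratios)) {
    stop("'mixtures' must be a list with one element per ratio", call. = FALSE)
  }

  alone_fit <- if (inherits(alone, "probit_fit")) alone else fit_log_probit(alone)

  rows <- vector("list", length(ratios))
  for (i in seq_along(ratios)) {
    r <- ratios[[i]]
    rows[[i]] <- tryCatch({
      add <- additive_ed50(alone_fit, r, n_add = n_add)
      mx <- mixtures[[i]]
      mix <- if (inherits(mx, "mixture_fit")) {
        if (is.null(mx$ratio)) mixture_fit(mx$ed50_exp, mx$sem_exp, mx$n_exp, r) else mx
      } else if (is.data.frame(mx)) {
        mfit <- fit_log_probit(mx)
        mixture_fit(mfit$ed50, mfit$sem, mfit$n_window, r)
      } else {
        get1 <- function(x, nm) for (n in nm) if (!is.null(x[[n]])) return(x[[n]])
        mixture_fit(get1(mx, c("ed50_exp", "ed50")),
                    get1(mx, c("sem_exp", "sem")),
                    get1(mx, c("n_exp", "n")), r)
      }
      res <- classify_interaction(mix, add, alpha_levels = alpha_levels)
      list(ratio = r, additive = add, mixture = mix, result = res)
    }, error = function(e) {
      stop(sprintf("ratio %s: %s", r$label, conditionMessage(e)), call. = FALSE)
    })
  }

  structure(list(
    effective_drug = effective_drug,
    ineffective_drug = ineffective_drug,
    alone = alone_fit,
    rows = rows
  ), class = "combination_study")
}

#' Flatten a combination study to a data frame
#'
#' @param x A `combination_study`.
#' @param ... Unused.
#' @return Data frame with one row per fixed ratio, full precision.
#' @export
as.data.frame.combination_study <- function(x, ...) {
  if (length(x$rows) == 0L) {
    return(data.frame(FixedRatio = character(0)))
  }
  do.call(rbind, lapply(x$rows, function(row) {
    data.frame(
      FixedRatio = row$ratio$label,
      Drug1_exp = row$mixture$dose1_exp,
      Drug2_exp = row$mixture$dose2_exp,
      ED50_exp = row$mixture$ed50_exp,
      SEM_exp = row$mixture$sem_exp,
      n_exp = row$mixture$n_exp,
      ED50_add = row$additive$ed50_add,
      SEM_add = row$additive$sem_add,
      n_add = row$additive$n_add,
      Drug2_add = row$additive$dose2_add,
      Drug1_add = row$additive$dose1_add,
      t = row$result$t,
      df = row$result$df,
      p = row$result$p,
      significance = row$result$significance,
      label = row$result$label,
      stringsAsFactors = FALSE
    )
  }))
}

#' @export
print.combination_study <- function(x, ...) {
  cat(sprintf("Type II isobolographic study: %s (effective) + %s (ineffective)\n",
              x$effective_drug, x$ineffective_drug))
  cat(sprintf("  alone ED50: %.4g mg/kg (SEM %.4g)\n", x$alone$ed50, x$alone$sem))
  df <- as.data.frame(x)
  if (nrow(df) > 0L) {
    show <- df[, c("FixedRatio", "ED50_exp", "SEM_exp", "n_exp",
                   "ED50_add", "SEM_add", "n_add", "p", "label")]
    num <- vapply(show, is.numeric, logical(1))
    show[num] <- lapply(show[num], signif, digits = 4)
    print(show, row.names = FALSE)
  } else {
    cat("  (no fixed ratios)\n")
  }
  invisible(x)
}
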