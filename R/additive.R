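#' Theoretical additive ED50 for a type II fixed-ratio mixture
#'
#' For a mixture of one fully effective drug (proportion `p1` by mass) and
#' one drug ineffective alone, dose additivity predicts that the mixture
#' is equi-effective with the effective drug alone whenever it delivers
#' the same amount of that drug. The additive total ED50 is therefore
#' `ED50_add = ED50_alone / p1`, its SEM scales identically
#' (`SEM_add = SEM_alone / p1`, so the coefficient of variation is
#' preserved), and its effective-drug component equals the alone ED50 for
#' every ratio.
#'
#' @param fit1 Alone-drug fit of the fully effective drug: a
#'   [fit_log_probit()] or [summary_fit()] object, or any list carrying
#'   `ed50` and `sem`.
#' @param ratio A [fixed_ratio()] (or "a:b" string).
#' @param n_add Animal count attached to the theoretical prediction, used
#'   as the second-group n in the Welch comparison. Defaults to the alone
#'   fit's probit-window n when available.
#' @return Object of class `additive_prediction`: list with `ed50_add`,
#'   `sem_add`, `n_add`, `dose1_add` (effective-drug component, equal to
#'   the alone ED50 by construction), `dose2_add` and `ratio`.
#' @export
#' @examples
#' alone <- summary_fit(48.61, 39.18, 60.31)
#' additive_ed50(alone, "1:2", n_add = 22) # ED50_add = 145.83 mg/kg
additive_ed50 <- function(fit1, ratio, n_add = NULL) {
  ratio <- parse_ratio(ratio)
  if (is.null(fit1$ed50) || is.null(fit1$sem)) {
    stop("'fit1' must carry ed50 and sem (a probit_fit or summary_fit)",
         call. = FALSE)
  }
  if (!is.finite(ratio$p1) || ratio$p1 <= 0) {
    stop("additive ED50 undefined for p1 = 0", call. = FALSE)
  }
  if (is.null(n_add)) {
    n_add <- fit1$n_window
    if (is.null(n_add) || is.na(n_add)) {
      stop("'n_add' is required when the alone fit carries no probit-window n",
           call. = FALSE)
    }
  }
  ed50_add <- fit1$ed50 / ratio$p1
  structure(list(
    ed50_add = ed50_add,
    sem_add = fit1$sem / ratio$p1,
    n_add = as.integer(n_add),
    dose1_add = fit1$ed50,
    dose2_add = ed50_add - fit1$ed50,
    ratio = ratio
  ), class = "additive_prediction")
}

#' Split a mixture ED50 into its component doses
#'
#' Multiplies a total mixture dose by the mass proportions of the fixed
#' ratio; the two components reconstitute the total exactly.
#'
#' @param ed50_total Total mixture dose (mg/kg), positive.
#' @param ratio A [fixed_ratio()] (or "a:b" string).
#' @return Named numeric vector `c(dose1 = , dose2 = )`, effective drug
#'   first.
#' @export
#' @examples
#' decompose_mixture_dose(143.40, "1:10") # 13.04, 130.36
decompose_mixture_dose <- function(ed50_total, ratio) {
  ratio <- parse_ratio(ratio)
  if (!is.finite(ed50_total) || ed50_total <= 0) {
    stop("'ed50_total' must be positive", call. = FALSE)
  }
  dose1 <- ed50_total * ratio$p1
  c(dose1 = dose1, dose2 = ed50_total - dose1)
}

#' Experimental mixture fit summary
#'
#' Packs an experimentally determined mixture ED50 (from a log-probit fit
#' of the mixture's total-dose quantal data, or from published summaries)
#' together with its component doses under the fixed ratio.
#'
#' @param ed50_exp Experimental total-dose ED50 (mg/kg).
#' @param sem_exp Its SEM (mg/kg).
#' @param n_exp Probit-window animal count of the mixture experiment.
#' @param ratio Optional [fixed_ratio()] used to decompose the total dose.
#' @return Object of class `mixture_fit` with `ed50_exp`, `sem_exp`,
#'   `n_exp`, `dose1_exp`, `dose2_exp` and `ratio`.
#' @export
mixture_fit <- function(ed50_exp, sem_exp, n_exp, ratio = NULL) {
  if (!is.finite(ed50_exp) || ed50_exp <= 0) {
    stop("'ed50_exp' must be positive", call. = FALSE)
  }
  if (!is.finite(sem_exp) || sem_exp < 0) {
    stop("'sem_exp' must be nonnegative", call. = FALSE)
  }
  doses <- c(dose1 = NA_real_, dose2 = NA_real_)
  if (!is.null(ratio)) {
    ratio <- parse_ratio(ratio)
    doses <- decompose_mixture_dose(ed50_exp, ratio)
  }
  structure(list(
    ed50_exp = ed50_exp,
    sem_exp = sem_exp,
    n_exp = as.integer(n_exp),
    dose1_exp = unname(doses["dose1"]),
    dose2_exp = unname(doses["dose2"]),
    ratio = ratio
  ), class = "mixture_fit")
}
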