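#' Quantal dose groups
#'
#' Construct and validate a table of quantal dose-response groups: one row
#' per dose level, recording the dose administered (mg/kg), the number of
#' animals tested and the number responding (e.g. protected against tonic
#' seizures).
#'
#' @param dose Positive numeric vector of doses in mg/kg, or a data frame
#'   with columns `dose`, `n_total` and `n_responding` (in which case the
#'   other arguments are ignored).
#' @param n_total Positive integer vector, animals tested per group.
#' @param n_responding Integer vector, animals responding per group; must
#'   satisfy `0 <= n_responding <= n_total`.
#' @param drug Optional drug (or mixture) label attached to every group.
#'
#' @return A data frame of class `dose_groups` with columns `drug` (if
#'   given), `dose`, `n_total` and `n_responding`.
#' @seealso [fit_log_probit()], [read_dose_csv()]
#' @export
#' @examples
#' dose_groups(c(20, 30, 45, 70), 8, c(1, 3, 5, 7))
dose_groups <- function(dose, n_total = NULL, n_responding = NULL, drug = NULL) {
  if (is.data.frame(dose)) {
    df <- dose
    required <- c("dose", "n_total", "n_responding")
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols) > 0L) {
      stop("dose_groups data frame is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    df <- df[, intersect(c("drug", required), names(df)), drop = FALSE]
  } else {
    k <- length(dose)
    df <- data.frame(
      dose = as.numeric(dose),
      n_total = rep_len(as.numeric(n_total), k),
      n_responding = rep_len(as.numeric(n_responding), k)
    )
  }
  if (!is.null(drug)) df$drug <- as.character(drug)

  if (nrow(df) == 0L) stop("at least one dose group is required", call. = FALSE)
  if (any(!is.finite(df$dose)) || any(df$dose <= 0)) {
    stop("doses must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(df$n_total)) || any(df$n_total < 1) ||
      any(df$n_total != round(df$n_total))) {
    stop("n_total must be a positive integer for every group", call. = FALSE)
  }
  if (any(!is.finite(df$n_responding)) ||
      any(df$n_responding != round(df$n_responding)) ||
      any(df$n_responding < 0) || any(df$n_responding > df$n_total)) {
    stop("n_responding must be an integer in [0, n_total] for every group",
         call. = FALSE)
  }
  df$n_total <- as.integer(df$n_total)
  df$n_responding <- as.integer(df$n_responding)
  rownames(df) <- NULL
  class(df) <- c("dose_groups", "data.frame")
  df
}

#' Read quantal dose-response data from CSV
#'
#' Reads the standard input schema: one row per dose group with columns
#' `drug,dose_mg_kg,n_total,n_responding` (UTF-8, header required, dot
#' decimal separator).
#'
#' @param path Path to a CSV file.
#' @param drug Optional drug name; when given, only that drug's rows are
#'   returned.
#' @return A [dose_groups()] data frame.
#' @export
read_dose_csv <- function(path, drug = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("drug", "dose_mg_kg", "n_total", "n_responding")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(drug)) {
    df <- df[df$drug == drug, , drop = FALSE]
    if (nrow(df) == 0L) {
      stop(sprintf("%s: no rows for drug '%s'", path, drug), call. = FALSE)
    }
  }
  dose_groups(data.frame(drug = df$drug, dose = df$dose_mg_kg,
                         n_total = df$n_total, n_responding = df$n_responding))
}

#' Write quantal dose-response data to CSV
#'
#' Inverse of [read_dose_csv()]: writes `drug,dose_mg_kg,n_total,n_responding`.
#'
#' @param groups A [dose_groups()] data frame.
#' @param path Output file path.
#' @param drug Drug label used when `groups` carries none.
#' @return `path`, invisibly.
#' @export
write_dose_csv <- function(groups, path, drug = "drug") {
  groups <- dose_groups(groups)
  out <- data.frame(
    drug = if ("drug" %in% names(groups)) groups$drug else drug,
    dose_mg_kg = groups$dose,
    n_total = groups$n_total,
    n_responding = groups$n_responding
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
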