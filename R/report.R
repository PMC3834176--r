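#' Render a combination study as CSV text
#'
#' Produces the standard report layout for a type II study — one row per
#' fixed ratio with component doses, experimental and additive ED50s with
#' SEMs and animal counts, and the Welch classification. Dose, ED50, SEM,
#' t and df columns are formatted to 2 decimal places (the conventional
#' display precision); p is given to 3 significant digits. Full-precision
#' values are available from [as.data.frame.combination_study()] and
#' [study_to_json()].
#'
#' @param study A `combination_study`.
#' @param file Optional path; when given the CSV is written there.
#' @param digits Display precision for dose-scale columns.
#' @return CSV text as a single character string (invisibly when written
#'   to `file`).
#' @export
render_table <- function(study, file = NULL, digits = 2) {
  stopifnot(inherits(study, "combination_study"))
  df <- as.data.frame(study)
  if (nrow(df) > 0L) {
    two_dp <- c("Drug1_exp", "Drug2_exp", "ED50_exp", "SEM_exp",
                "ED50_add", "SEM_add", "Drug2_add", "Drug1_add", "t", "df")
    df[two_dp] <- lapply(df[two_dp], function(x) sprintf("%.*f", digits, x))
    df$p <- sprintf("%.3g", df$p)
  }
  con <- textConnection("render_table_out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
  text <- paste0(paste(render_table_out, collapse = "\n"), "\n")
  if (is.null(file)) return(text)
  cat(text, file = file)
  invisible(text)
}

#' Serialize a combination study to JSON
#'
#' Full-precision sidecar for the 2-decimal CSV report: the alone fit,
#' every per-ratio record and the classification, with no rounding.
#'
#' @param study A `combination_study`.
#' @param file Optional output path.
#' @return JSON text (invisibly when written to `file`).
#' @export
study_to_json <- function(study, file = NULL) {
  stopifnot(inherits(study, "combination_study"))
  payload <- list(
    effective_drug = study$effective_drug,
    ineffective_drug = study$ineffective_drug,
    alone = study$alone[c("ed50", "slope", "log_ed50", "ci95_lower",
                          "ci95_upper", "sem_log", "sem", "n_window",
                          "converged")],
    combinations = lapply(study$rows, function(row) {
      list(
        fixed_ratio = row$ratio$label,
        p1 = row$ratio$p1,
        p2 = row$ratio$p2,
        mixture = row$mixture[c("ed50_exp", "sem_exp", "n_exp",
                                "dose1_exp", "dose2_exp")],
        additive = row$additive[c("ed50_add", "sem_add", "n_add",
                                  "dose1_add", "dose2_add")],
        interaction = row$result[c("t", "df", "p", "significance", "label")]
      )
    })
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
  if (is.null(file)) return(json)
  writeLines(json, file)
  invisible(json)
}

#' Read back a rendered report
#'
#' Convenience reader for the CSV written by [render_table()].
#'
#' @param file Path or literal CSV text.
#' @return Data frame with the report columns, numerics parsed.
#' @export
read_table_csv <- function(file) {
  if (length(file) == 1L && !file.exists(file) && grepl("\n", file)) {
    return(utils::read.csv(text = file, stringsAsFactors = FALSE))
  }
  utils::read.csv(file, stringsAsFactors = FALSE)
}
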