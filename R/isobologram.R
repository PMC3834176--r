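#' Type II isobologram
#'
#' Plots the study in the classical type II layout: the ineffective
#' drug's dose on the X axis, the effective drug's dose on the Y axis.
#' Because the ineffective drug contributes no effect of its own under
#' additivity, the theoretical additivity "line" is horizontal at the
#' effective drug's alone ED50 (heavy line), flanked by dotted lines at
#' +/- SEM. Each fixed ratio contributes one point at the component doses
#' of the experimental mixture ED50, with error bars given by the
#' projection of the mixture SEM onto the two axes via the mass
#' proportions (vertical: `sem_exp * p1`; horizontal: `sem_exp * p2`) and
#' the significance stars of the Welch comparison annotated above the
#' point. Points below the heavy line indicate supra-additivity.
#'
#' @param study A `combination_study`.
#' @param file Optional path to write an SVG rendering.
#' @param width,height SVG size in inches.
#' @return A ggplot object (invisibly when written to `file`).
#' @export
render_isobologram <- function(study, file = NULL, width = 6, height = 5) {
  stopifnot(inherits(study, "combination_study"))
  alone <- study$alone

  df <- as.data.frame(study)
  if (nrow(df) > 0L) {
    p1 <- vapply(study$rows, function(r) r$ratio$p1, numeric(1))
    p2 <- vapply(study$rows, function(r) r$ratio$p2, numeric(1))
    df$err_y <- df$SEM_exp * p1
    df$err_x <- df$SEM_exp * p2
    stars <- c("0.05" = "*", "0.01" = "**", "0.001" = "***", ns = "")
    df$star <- unname(stars[df$significance])
  }

  gg <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = alone$ed50, linewidth = 1.2) +
    ggplot2::geom_hline(yintercept = alone$ed50 + alone$sem, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = alone$ed50 - alone$sem, linetype = "dotted") +
    ggplot2::labs(
      x = sprintf("%s dose (mg/kg)", study$ineffective_drug),
      y = sprintf("%s dose (mg/kg)", study$effective_drug),
      title = sprintf("Type II isobologram: %s + %s",
                      study$effective_drug, study$ineffective_drug)
    ) +
    ggplot2::expand_limits(x = 0, y = 0) +
    ggplot2::theme_classic()

  if (nrow(df) > 0L) {
    gg <- gg +
      ggplot2::geom_errorbar(
        data = df,
        ggplot2::aes(x = Drug2_exp,
                     ymin = Drug1_exp - err_y, ymax = Drug1_exp + err_y),
        width = 0
      ) +
      ggplot2::geom_errorbarh(
        data = df,
        ggplot2::aes(y = Drug1_exp,
                     xmin = Drug2_exp - err_x, xmax = Drug2_exp + err_x),
        height = 0
      ) +
      ggplot2::geom_point(data = df,
                          ggplot2::aes(x = Drug2_exp, y = Drug1_exp),
                          size = 2.5) +
      ggplot2::geom_text(data = df[df$star != "", , drop = FALSE],
                         ggplot2::aes(x = Drug2_exp, y = Drug1_exp,
                                      label = star),
                         vjust = -1.2, size = 5)
  }

  if (is.null(file)) return(gg)
  grDevices::svg(file, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(gg)
  invisible(gg)
}
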