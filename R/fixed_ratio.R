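#' Fixed-ratio mixture proportions
#'
#' A fixed-ratio two-drug mixture holds the two components at a constant
#' mass ratio `a:b` while the total dose varies. The mass proportions are
#' `p1 = a / (a + b)` for the effective drug and `p2 = b / (a + b)` for
#' the drug ineffective alone; `p1 + p2 = 1` exactly (`p2` is computed as
#' `1 - p1`).
#'
#' @param a Mass parts of the effective drug; must be positive.
#' @param b Mass parts of the ineffective drug; must be nonnegative.
#' @return An object of class `fixed_ratio`: list with `a`, `b`, `p1`,
#'   `p2` and a display `label` such as `"1:10"`.
#' @seealso [parse_ratio()], [additive_ed50()]
#' @export
#' @examples
#' fixed_ratio(1, 2)   # p1 = 1/3
#' fixed_ratio(200, 1) # p1 = 200/201
fixed_ratio <- function(a, b) {
  if (!is.finite(a) || a <= 0) {
    stop("'a' (effective-drug mass parts) must be positive", call. = FALSE)
  }
  if (!is.finite(b) || b < 0) {
    stop("'b' (ineffective-drug mass parts) must be nonnegative", call. = FALSE)
  }
  p1 <- a / (a + b)
  structure(list(
    a = a, b = b,
    p1 = p1,
    p2 = 1 - p1,
    label = paste0(format(a, trim = TRUE), ":", format(b, trim = TRUE))
  ), class = "fixed_ratio")
}

#' Parse an "a:b" ratio string
#'
#' @param x A string such as `"200:1"` or `"1:10"`.
#' @return A [fixed_ratio()] object.
#' @export
parse_ratio <- function(x) {
  if (inherits(x, "fixed_ratio")) return(x)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop(sprintf("cannot parse ratio '%s'; expected \"a:b\"", x), call. = FALSE)
  }
  ab <- suppressWarnings(as.numeric(parts))
  if (any(is.na(ab))) {
    stop(sprintf("cannot parse ratio '%s'; expected \"a:b\"", x), call. = FALSE)
  }
  fixed_ratio(ab[1], ab[2])
}

#' Mass proportions of a fixed-ratio mixture
#'
#' Convenience wrapper returning the proportions of a mass ratio directly.
#'
#' @inheritParams fixed_ratio
#' @return Named numeric vector `c(p1 = , p2 = )`.
#' @export
#' @examples
#' mixture_proportions(1, 2) # 0.3333, 0.6667
mixture_proportions <- function(a, b) {
  r <- fixed_ratio(a, b)
  c(p1 = r$p1, p2 = r$p2)
}

#' @export
print.fixed_ratio <- function(x, ...) {
  cat(sprintf("Fixed ratio %s (p1 = %.6g, p2 = %.6g)\n", x$label, x$p1, x$p2))
  invisible(x)
}
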