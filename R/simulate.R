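#' Specification of a simulated quantal experiment
#'
#' Describes the ground truth for simulating group-of-n Bernoulli quantal
#' responses from a log-probit curve, mirroring a maximal-electroshock
#' style design: a handful of dose levels spanning the ED50, 8 animals
#' per group. The defaults reproduce the effective drug's published curve
#' (ED50 48.61 mg/kg, doses 30-70 mg/kg); the slope (5 probits per
#' log10-dose unit) is a realistic steepness for this assay, chosen so
#' the default doses span roughly 15-80% response.
#'
#' @param true_ed50 True median effective dose (mg/kg).
#' @param slope True probit slope (probits per log10-dose unit).
#' @param doses Distinct positive dose levels (mg/kg).
#' @param n_per_group Animals per dose group.
#' @param seed Integer seed; every group draws from its own substream
#'   derived from `seed` and the dose value, so adding a dose level never
#'   perturbs the other groups' draws.
#' @param interaction_index Interaction index lambda for mixtures:
#'   1 = additive, < 1 = synergy, > 1 = antagonism. Must be positive.
#' @return Object of class `simulation_spec`.
#' @seealso [simulate_single_drug()], [simulate_mixture()]
#' @export
simulation_spec <- function(true_ed50 = 48.61, slope = 5,
                            doses = c(30, 40, 50, 60, 70),
                            n_per_group = 8, seed = 1,
                            interaction_index = 1) {
  if (!is.finite(true_ed50) || true_ed50 <= 0) stop("true_ed50 must be positive", call. = FALSE)
  if (!is.finite(slope) || slope <= 0) stop("slope must be positive", call. = FALSE)
  if (length(doses) < 1L || any(!is.finite(doses)) || any(doses <= 0)) {
    stop("doses must be positive and finite", call. = FALSE)
  }
  if (anyDuplicated(doses)) stop("doses must be distinct", call. = FALSE)
  if (!is.finite(n_per_group) || n_per_group < 1 || n_per_group != round(n_per_group)) {
    stop("n_per_group must be a positive integer", call. = FALSE)
  }
  if (!is.finite(interaction_index) || interaction_index <= 0) {
    stop("interaction_index must be positive", call. = FALSE)
  }
  structure(list(
    true_ed50 = true_ed50, slope = slope, doses = as.numeric(doses),
    n_per_group = as.integer(n_per_group), seed = as.integer(seed),
    interaction_index = interaction_index
  ), class = "simulation_spec")
}

# Deterministic per-group substream seed: a small polynomial string hash of
# the dose key folded into the experiment seed, kept below 2^31 - 1.
substream_seed <- function(seed, key) {
  s <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(key)) s <- (s * 31 + ch) %% 2147483647
  as.integer(s)
}

dose_key <- function(dose) sprintf("%.12g", dose)

# Draw one group's responders on an isolated RNG substream, restoring the
# caller's RNG state afterwards.
draw_group <- function(seed, key, n, prob) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, key))
  stats::rbinom(1L, n, prob)
}

#' Simulate a single-drug quantal experiment
#'
#' For each dose `d`, draws `n_responding ~ Binomial(n_per_group, p(d))`
#' with `p(d) = pnorm(slope * (log10 d - log10 true_ed50))`. Fully
#' reproducible from the spec seed; each dose level has its own RNG
#' substream.
#'
#' @param spec A [simulation_spec()].
#' @param drug Drug label for the output table.
#' @return A [dose_groups()] data frame.
#' @export
#' @examples
#' simulate_single_drug(simulation_spec(seed = 7))
simulate_single_drug <- function(spec, drug = "drug") {
  stopifnot(inherits(spec, "simulation_spec"))
  p <- stats::pnorm(spec$slope * (log10(spec$doses) - log10(spec$true_ed50)))
  r <- vapply(seq_along(spec$doses), function(i) {
    draw_group(spec$seed, dose_key(spec$doses[i]), spec$n_per_group, p[i])
  }, integer(1))
  dose_groups(spec$doses, spec$n_per_group, r, drug = drug)
}

#' Simulate a fixed-ratio mixture experiment
#'
#' Simulates total-dose quantal responses for a two-drug mixture of one
#' effective and one ineffective drug. The mixture's true total-dose ED50
#' is `lambda * true_ed50 / p1` — the theoretical additive ED50 scaled by
#' the interaction index — and the response curve keeps the effective
#' drug's slope. The dose grid is the alone-drug grid scaled by
#' `lambda / p1`, emulating the dose titration around the mixture's own
#' potency that a quantal assay requires. Doses are recorded as total
#' mixture dose.
#'
#' @param spec_effective [simulation_spec()] of the effective drug alone.
#' @param ratio A [fixed_ratio()] (or "a:b" string).
#' @param interaction_index Overrides the spec's lambda when given.
#' @param drug Label for the output table.
#' @return A [dose_groups()] data frame of total mixture doses.
#' @export
#' @examples
#' spec <- simulation_spec(seed = 7)
#' simulate_mixture(spec, "1:2") # true ED50 145.83 under lambda = 1
simulate_mixture <- function(spec_effective, ratio, interaction_index = NULL,
                             drug = "mixture") {
  stopifnot(inherits(spec_effective, "simulation_spec"))
  ratio <- parse_ratio(ratio)
  lambda <- if (is.null(interaction_index)) spec_effective$interaction_index else interaction_index
  if (!is.finite(lambda) || lambda <= 0) {
    stop("interaction_index must be positive", call. = FALSE)
  }
  scale <- lambda / ratio$p1
  true_mix_ed50 <- spec_effective$true_ed50 * scale
  doses_total <- spec_effective$doses * scale
  p <- stats::pnorm(spec_effective$slope * (log10(doses_total) - log10(true_mix_ed50)))
  r <- vapply(seq_along(doses_total), function(i) {
    draw_group(spec_effective$seed, dose_key(doses_total[i]),
               spec_effective$n_per_group, p[i])
  }, integer(1))
  dose_groups(doses_total, spec_effective$n_per_group, r, drug = drug)
}
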