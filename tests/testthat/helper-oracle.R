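# Brute-force Bernoulli log-likelihood oracle for the log-probit model,
# independent of the glm fitting path.
probit_loglik <- function(groups, log_ed50, slope) {
  p <- pnorm(slope * (log10(groups$dose) - log_ed50))
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  sum(groups$n_responding * log(p) +
        (groups$n_total - groups$n_responding) * log1p(-p))
}

# Dense grid search over (log_ed50, slope); returns the arg-max.
grid_argmax <- function(groups, log_ed50_range, slope_range, n_grid) {
  les <- seq(log_ed50_range[1], log_ed50_range[2], length.out = n_grid)
  sls <- seq(slope_range[1], slope_range[2], length.out = n_grid)
  best <- c(ll = -Inf, log_ed50 = NA, slope = NA)
  for (sl in sls) {
    ll <- vapply(les, function(le) probit_loglik(groups, le, sl), numeric(1))
    i <- which.max(ll)
    if (ll[i] > best["ll"]) best <- c(ll = ll[i], log_ed50 = les[i], slope = sl)
  }
  best
}

# One synthetic study replicate: simulate alone + mixture experiments, fit
# both, build the additivity prediction from the alone fit and classify.
# Returns the interaction label, or NA when a fit fails to converge.
simulate_and_classify <- function(i, ratio, lambda,
                                  true_ed50 = 48.61, slope = 5,
                                  doses = c(30, 40, 50, 60, 70),
                                  n_per_group = 8) {
  label <- tryCatch({
    spec_a <- simulation_spec(true_ed50, slope, doses, n_per_group, seed = i)
    fa <- fit_log_probit(simulate_single_drug(spec_a))
    spec_m <- simulation_spec(true_ed50, slope, doses, n_per_group,
                              seed = i + 1000003L)
    fm <- fit_log_probit(simulate_mixture(spec_m, ratio,
                                          interaction_index = lambda))
    r <- parse_ratio(ratio)
    add <- additive_ed50(fa, r, n_add = max(fa$n_window, 2L))
    mix <- mixture_fit(fm$ed50, fm$sem, max(fm$n_window, 2L), r)
    classify_interaction(mix, add)$label
  }, error = function(e) NA_character_, warning = function(w) NA_character_)
  label
}
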