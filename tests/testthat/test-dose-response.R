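test_that("symmetric two-dose data give the geometric-mean ED50", {
  fit <- fit_log_probit(dose_groups(c(10, 40), 8, c(2, 6)))
  expect_equal(fit$ed50, sqrt(10 * 40), tolerance = 1e-8)
  expect_true(fit$converged)
  # fitted curve passes through 50% at the ED50
  p_at_ed50 <- pnorm(fit$slope * (log10(fit$ed50) - fit$log_ed50))
  expect_identical(p_at_ed50, 0.5)
})

test_that("ML fit matches the brute-force likelihood grid", {
  g <- dose_groups(c(20, 30, 45, 70), 8, c(1, 3, 5, 7))
  fit <- fit_log_probit(g)

  # frozen arg-max of a 2000x2000 grid over log_ed50 in [1, 2.2],
  # slope in [0.5, 10], computed with probit_loglik()
  expect_equal(fit$ed50, 37.024077, tolerance = 1e-3)
  expect_equal(fit$slope, 4.140320, tolerance = 1e-3)

  # likelihood at the returned optimum dominates a fresh coarse grid
  grid <- grid_argmax(g, c(1, 2.2), c(0.5, 10), n_grid = 200)
  ll_fit <- probit_loglik(g, fit$log_ed50, fit$slope)
  expect_gte(ll_fit, grid["ll"])
})

test_that("fit agrees with an independent delta-method ED50 standard error", {
  skip_if_not_installed("MASS")
  g <- dose_groups(c(20, 30, 45, 70), 8, c(1, 3, 5, 7))
  fit <- fit_log_probit(g)
  glm_fit <- glm(cbind(n_responding, n_total - n_responding) ~ log10(dose),
                 family = binomial(link = "probit"), data = g)
  dp <- MASS::dose.p(glm_fit, p = 0.5)
  expect_equal(fit$log_ed50, unname(as.numeric(dp)), tolerance = 1e-8)
  expect_equal(fit$sem_log, unname(attr(dp, "SE")[1, 1]), tolerance = 1e-8)
})

test_that("fit is invariant to group order and equivariant to dose rescaling", {
  g <- dose_groups(c(20, 30, 45, 70), 8, c(1, 3, 5, 7))
  fit <- fit_log_probit(g)

  shuffled <- fit_log_probit(g[c(3, 1, 4, 2), ])
  expect_equal(shuffled$ed50, fit$ed50, tolerance = 1e-9)
  expect_equal(shuffled$slope, fit$slope, tolerance = 1e-9)

  scaled <- fit_log_probit(dose_groups(g$dose * 10, g$n_total, g$n_responding))
  expect_equal(scaled$ed50, 10 * fit$ed50, tolerance = 1e-9)
  expect_equal(scaled$ci95_lower, 10 * fit$ci95_lower, tolerance = 1e-9)
  expect_equal(scaled$ci95_upper, 10 * fit$ci95_upper, tolerance = 1e-9)
  expect_equal(scaled$sem, 10 * fit$sem, tolerance = 1e-9)
  expect_equal(scaled$slope, fit$slope, tolerance = 1e-9)
})

test_that("non-estimable inputs are rejected explicitly", {
  expect_error(fit_log_probit(dose_groups(c(10, 20), 8, c(0, 0))),
               "not estimable")
  expect_error(fit_log_probit(dose_groups(c(10, 20), 8, c(8, 8))),
               "not estimable")
  expect_error(fit_log_probit(dose_groups(c(10, 10), c(8, 8), c(2, 6))),
               "distinct doses")
  # responses falling with dose: no increasing trend
  expect_error(fit_log_probit(dose_groups(c(10, 20, 40), 8, c(7, 4, 1))),
               "not estimable")
})

test_that("CI-to-SEM transform reproduces the published alone-drug SEM", {
  expect_equal(ci_to_sem(48.61, 39.18, 60.31), 5.35, tolerance = 2e-3)
  expect_equal(ci_to_sem(100, 80, 125),
               100 * log(10) * (log10(125) - log10(80)) / 3.92)
  expect_equal(ci_to_sem(100, 80, 125), 11.39, tolerance = 1e-3)
  expect_equal(ci_to_sem(50, 50, 50), 0)
  expect_error(ci_to_sem(10, 12, 15), "confidence limits")
  expect_error(ci_to_sem(10, 5, 8), "confidence limits")
})

test_that("CI-to-SEM is strictly increasing in interval width", {
  widths <- seq(0, 40, length.out = 12)
  sems <- vapply(widths, function(w) ci_to_sem(50, 40, 50 + w), numeric(1))
  expect_true(all(diff(sems) > 0))
})

test_that("probit-window n counts animals between 4 and 6 probits", {
  fit_steep <- summary_fit(20, 15, 27)
  fit_steep$slope <- 10
  fit_steep$converged <- TRUE
  g3 <- dose_groups(c(5, 20, 80), 8, c(0, 4, 8))
  expect_identical(probit_window_n(fit_steep, g3), 8L)

  fit_flat <- fit_steep
  fit_flat$slope <- 1
  g_in <- dose_groups(c(15, 20, 27), 8, c(3, 4, 5))
  expect_identical(probit_window_n(fit_flat, g_in), 24L)

  # all predicted responses below the window
  g_low <- dose_groups(c(1, 2, 3), 8, c(0, 0, 1))
  expect_identical(probit_window_n(fit_steep, g_low), 0L)
})
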