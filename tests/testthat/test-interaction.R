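test_that("Welch t from summary statistics matches published comparisons", {
  # synergistic combination: experimental ED50 far below additive
  ht <- welch_t(51.66, 5.85, 32, 97.22, 10.69, 22)
  expect_equal(unname(ht$statistic), 3.74, tolerance = 1e-3)
  expect_lt(ht$p.value, 0.001)

  # identical groups: no difference
  ht0 <- welch_t(40, 3, 8, 40, 3, 8)
  expect_identical(unname(ht0$statistic), 0)
  expect_identical(ht0$p.value, 1)

  # non-significant comparison
  expect_gt(welch_t(42.70, 4.76, 8, 49.09, 5.40, 22)$p.value, 0.05)

  expect_error(welch_t(1, 0, 8, 2, 0, 8), "both SEMs")
  expect_error(welch_t(1, 1, 1, 2, 1, 8), "at least 2")
})

test_that("Welch t matches stats::t.test on reconstructed raw samples", {
  # build samples with exact means and SEMs so t.test is an independent
  # oracle for both the statistic and the Satterthwaite df
  make_sample <- function(m, sem, n) {
    base <- scale(seq_len(n))[, 1]
    m + sem * sqrt(n) * base
  }
  set.seed(42)
  for (k in 1:20) {
    m <- runif(2, 10, 500)
    s <- runif(2, 0.5, 50)
    n <- sample(5:40, 2, replace = TRUE)
    x <- make_sample(m[1], s[1], n[1])
    y <- make_sample(m[2], s[2], n[2])
    ref <- t.test(y, x)
    ht <- welch_t(m[1], s[1], n[1], m[2], s[2], n[2])
    expect_equal(unname(ht$statistic), unname(ref$statistic), tolerance = 1e-8)
    expect_equal(unname(ht$parameter), unname(ref$parameter), tolerance = 1e-8)
    expect_equal(ht$p.value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("swapping groups negates t and preserves df and p; p decreases with
           the mean difference", {
  a <- welch_t(30, 4, 12, 50, 6, 20)
  b <- welch_t(50, 6, 20, 30, 4, 12)
  expect_equal(unname(a$statistic), -unname(b$statistic))
  expect_equal(a$parameter, b$parameter)
  expect_equal(a$p.value, b$p.value)

  deltas <- seq(0, 40, by = 5)
  ps <- vapply(deltas, function(d) welch_t(50, 4, 12, 50 + d, 6, 20)$p.value,
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("interaction classification assigns labels and star levels", {
  # published synergistic row: clonazepam at 25:1
  res <- classify_interaction(
    mixture_fit(32.33, 1.54, 24),
    list(ed50_add = 50.48, sem_add = 5.55, n_add = 22)
  )
  expect_identical(res$label, "supra-additive")
  expect_identical(res$significance, "0.01")

  # published additive row: levetiracetam at 1:1
  res2 <- classify_interaction(
    mixture_fit(98.66, 8.58, 24),
    list(ed50_add = 97.22, sem_add = 10.69, n_add = 22)
  )
  expect_identical(res2$label, "additive")
  expect_identical(res2$significance, "ns")

  # mirrored inputs: significantly higher experimental ED50 is antagonism
  res3 <- classify_interaction(
    mixture_fit(50.48, 5.55, 22),
    list(ed50_add = 32.33, sem_add = 1.54, n_add = 24)
  )
  expect_identical(res3$label, "sub-additive")
  expect_identical(res3$significance, "0.01")
})

test_that("replaying every published summary row reproduces the full
           classification and star pattern", {
  replay <- methiq_replay()
  expected <- methiq_expected()
  key <- paste(replay$drug, replay$FixedRatio)
  expected <- expected[match(key, paste(expected$drug, expected$ratio)), ]

  expect_identical(sum(replay$label == "supra-additive"), 7L)
  expect_identical(sum(replay$label == "additive"), 17L)
  expect_identical(replay$label, expected$label)
  expect_identical(replay$significance, expected$star)
})
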