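test_that("event synthesis respects the mixture structure", {
  all_dim <- simulate_cytometry_events(0, 1e4, seed = 1)
  expect_false(any(all_dim$true_recombined))
  all_bright <- simulate_cytometry_events(1, 1e4, cytometry_model(immature_fraction = 0), seed = 2)
  expect_true(all(all_bright$true_recombined))
  expect_true(all(all_bright$true_mature))
  # rare-fraction regime: labelled count within 4 binomial sd of expectation
  fr <- 6.9e-4; n <- 150000
  ev <- simulate_cytometry_events(fr, n, seed = 3)
  expect_lt(abs(sum(ev$true_recombined) - fr * n), 4 * sqrt(n * fr * (1 - fr)))
})

test_that("label frequency converges to the requested fraction (LLN at n = 1e6)", {
  fr <- 0.037
  ev <- simulate_cytometry_events(fr, 1e6, seed = 4)
  expect_lt(abs(mean(ev$true_recombined) - fr), 3 * sqrt(fr * (1 - fr) / 1e6))
})

test_that("control-derived gates exclude the control at the requested rate", {
  ctrl <- simulate_cytometry_events(0, 5e4, sample_id = "ctrl", seed = 5)
  for (q in c(0.99, 0.999)) {
    g <- derive_gate(ctrl, q = q)
    est <- estimate_fraction(ctrl, g)
    expect_lte(est$x / est$n, 1 - q + 3 * sqrt((1 - q) / nrow(ctrl)))
  }
  # fl1 threshold is the empirical control quantile among FSC-passing events
  g <- derive_gate(ctrl, q = 0.999)
  passing <- ctrl$fl1_a[ctrl$fsc_a >= g$fsc_low]
  expect_equal(g$fl1_low, unname(quantile(passing, 0.999)))
  # a fully separated bright population is entirely recovered at any stringency
  bright <- simulate_cytometry_events(1, 2e4, cytometry_model(immature_fraction = 0), seed = 6)
  for (q in c(0.99, 0.9999)) {
    est <- estimate_fraction(bright, derive_gate(ctrl, q = q))
    expect_equal(est$x, est$n)
  }
  expect_error(derive_gate(ctrl[1:500, ]), "1000")
})

test_that("fraction estimates follow the binomial formulas", {
  # geometry fixed by hand: 104 of 150000 events above the boundary
  n <- 150000; x <- 104
  ev <- tibble::tibble(
    fsc_a = rep(10, n),
    fl1_a = c(rep(100, n - x), rep(1000, x))
  )
  est <- estimate_fraction(ev, manual_gate(fsc_low = 1, fl1_low = 500))
  expect_equal(est$x, 104L)
  expect_equal(est$p_hat, 0.00069333333, tolerance = 1e-8)
  expect_equal(est$se, 6.7963354e-05, tolerance = 1e-6)
  expect_false(est$smoothed)

  # empty gate: Jeffreys-style smoothing keeps p_hat > 0
  ev0 <- tibble::tibble(fsc_a = rep(10, 1e4), fl1_a = rep(100, 1e4))
  est0 <- estimate_fraction(ev0, manual_gate(1, 500))
  expect_true(est0$smoothed)
  expect_equal(est0$p_hat, 0.5 / (1e4 + 1))
  expect_equal(est0$se, sqrt(est0$p_hat * (1 - est0$p_hat) / 1e4))
})

test_that("gating is monotone in the FL1 boundary", {
  ev <- simulate_cytometry_events(0.2, 2e4, seed = 7)
  xs <- vapply(c(200, 500, 2000, 8000, 30000), function(thr) {
    estimate_fraction(ev, manual_gate(0, thr))$x
  }, integer(1))
  expect_true(all(diff(xs) <= 0))
})

test_that("estimated fractions are consistent for the mature subpopulation", {
  # with immature fraction iota, expected gated estimate ~ fraction * (1 - iota)
  fr <- 0.05; iota <- 0.3
  ctrl <- simulate_cytometry_events(0, 5e4, seed = 8)
  g <- derive_gate(ctrl, q = 0.9999)
  ev <- simulate_cytometry_events(fr, 1e6, cytometry_model(immature_fraction = iota), seed = 9)
  est <- estimate_fraction(ev, g)
  expect_equal(est$p_hat, fr * (1 - iota), tolerance = 0.03)
  # well-separated 5% fraction at n = 2e4 lands within 4 binomial sd of truth
  ev2 <- simulate_cytometry_events(0.05, 2e4, seed = 10)
  est2 <- estimate_fraction(ev2, g)
  expect_lt(abs(est2$p_hat - 0.05), 4 * est2$se)
})

test_that("the binomial se matches a large resampling experiment", {
  p <- 0.003; n <- 5e3
  se_formula <- sqrt(p * (1 - p) / n)
  sims <- withr::with_seed(11, rbinom(1e5, n, p) / n)
  expect_equal(sd(sims), se_formula, tolerance = 0.05)
})

test_that("median fluorescence estimates are robust and well-calibrated", {
  # constant channel: median = the constant, se = 0
  ev <- tibble::tibble(fsc_a = rep(10, 500), fl1_a = rep(42, 500))
  m <- estimate_median_fluorescence(ev, n_boot = 200, seed = 1)
  expect_equal(m$median, 42)
  expect_equal(m$se, 0)
  # symmetric contamination leaves the median unchanged
  base <- rep(100, 400)
  ev2 <- tibble::tibble(
    fsc_a = rep(10, 800),
    fl1_a = c(base + 25, base - 25)
  )
  m2 <- estimate_median_fluorescence(ev2, n_boot = 200, seed = 2)
  expect_equal(m2$median, 100)
  # bootstrap se within 25% of the asymptotic 1 / (2 f(m) sqrt(n)) oracle
  n <- 1e5
  ev3 <- withr::with_seed(3, tibble::tibble(
    fsc_a = rep(10, n), fl1_a = rlnorm(n, meanlog = 5, sdlog = 0.5)
  ))
  m3 <- estimate_median_fluorescence(ev3, n_boot = 300, seed = 4)
  expect_equal(m3$se, 0.2941050, tolerance = 0.25)
  expect_error(estimate_median_fluorescence(ev[1:50, ]), "100")
  expect_error(estimate_median_fluorescence(ev, n_boot = 50), "n_boot")
})

test_that("event tables and gates round-trip through their serialized forms", {
  dir <- withr::local_tempdir()
  ev <- simulate_cytometry_events(0.1, 2000, sample_id = "s1", seed = 12)
  p <- file.path(dir, "events.csv")
  write_events(ev, p)
  back <- read_events(p)
  expect_equal(back$fl1_a, ev$fl1_a)
  expect_equal(back$sample_id[1], "s1")
  expect_false("true_recombined" %in% names(back))

  ctrl <- simulate_cytometry_events(0, 5000, seed = 13)
  for (bins in list(NULL, 4)) {
    g <- derive_gate(ctrl, q = 0.995, fsc_bins = bins)
    gp <- file.path(dir, "gate.json")
    write_gate(g, gp)
    g2 <- read_gate(gp)
    expect_equal(g2$fsc_low, g$fsc_low)
    if (is.null(bins)) {
      expect_equal(g2$fl1_low, g$fl1_low)
    } else {
      expect_equal(as.data.frame(g2$fl1_low), as.data.frame(g$fl1_low))
    }
    # classification identical after round trip
    smp <- simulate_cytometry_events(0.02, 2000, seed = 14)
    expect_equal(estimate_fraction(smp, g2), estimate_fraction(smp, g))
  }
})

test_that("the FCS adapter is declared optional", {
  skip_if(requireNamespace("flowCore", quietly = TRUE))
  expect_error(read_fcs_events("whatever.fcs"), "flowCore")
})
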