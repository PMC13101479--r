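test_that("Welch tests match the textbook formula and its identities", {
  # frozen hand-computed example
  w <- welch_test(c(0.10, 0.12, 0.11), c(0.20, 0.22, 0.21))
  expect_equal(w$t, -12.2474487, tolerance = 1e-7)
  expect_equal(w$df, 4, tolerance = 1e-9)
  expect_equal(w$p, 0.000255217, tolerance = 1e-5)
  # identical groups
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_test(c(5, 5), c(5, 5))$p, 1)
  # strong separation drives p toward zero
  expect_lt(welch_test(c(1, 2, 3), c(1001, 1002, 1003))$p, 1e-8)
  # symmetric in its arguments
  a <- c(0.3, 0.5, 0.4); b <- c(0.9, 1.0, 0.8)
  expect_equal(welch_test(a, b)$p, welch_test(b, a)$p)
  # invariant to a common affine rescaling
  expect_equal(welch_test(2 * a + 7, 2 * b + 7)$p, welch_test(a, b)$p)
  expect_error(welch_test(1, c(1, 2)), "at least 2")
})

test_that("Fisher combination matches the chi-square tail", {
  f <- fisher_combine(c(0.5, 0.5, 0.5))
  expect_equal(f$chi2, 4.1588831, tolerance = 1e-7)
  expect_equal(f$df, 6)
  # frozen value from the closed-form even-df tail e^(-x/2)(1 + x/2 + (x/2)^2/2)
  expect_equal(f$p, 0.6551850, tolerance = 1e-6)
  expect_equal(fisher_combine(c(1, 1, 1))$p, 1)
  # a single p-value passes through (chi-square df = 2 identity)
  expect_equal(fisher_combine(0.0721)$p, 0.0721, tolerance = 1e-12)
  expect_warning(f0 <- fisher_combine(c(0, 0.5)), "floored")
  expect_lt(f0$p, 1e-100)
  expect_error(fisher_combine(numeric(0)), "at least one")
  expect_error(fisher_combine(c(0.5, 1.2)), "0, 1")
})

test_that("Fisher combination of uniform p-values stays uniform", {
  combined <- withr::with_seed(42, vapply(seq_len(5000), function(i) {
    fisher_combine(runif(3))$p
  }, numeric(1)))
  expect_gt(stats::ks.test(combined, "punif")$p.value, 0.01)
})

test_that("the detection ladder finds the first responsive concentration", {
  concs <- c(0, 15e-9, 30e-9, 60e-9)
  grid <- tidyr::expand_grid(experiment = 1:3, concentration = concs, tech = 1:3)
  # strong effect at and above 30 nM
  grid$value <- withr::with_seed(8, rnorm(
    nrow(grid),
    mean = ifelse(grid$concentration >= 30e-9, 0.5, 0.1),
    sd = 0.01
  ))
  lad <- detection_ladder(grid)
  expect_equal(lad$lowest_detected, 30e-9)
  expect_equal(nrow(lad$steps), 3)
  # step from 30 to 60 nM is null here and should not be significant
  expect_gt(lad$steps$p_combined[3], 0.05)
  # excluding one experiment recomputes on the remainder
  lad2 <- detection_ladder(grid, exclude = 3)
  expect_equal(length(lad2$steps$p_by_experiment[[1]]), 2)
  expect_equal(lad2$lowest_detected, 30e-9)
  # a missing level is reported, not silently dropped
  gap <- grid[!(grid$experiment == 2 & grid$concentration == 30e-9), ]
  expect_error(detection_ladder(gap), "missing concentration")
  # Holm option only adjusts across steps
  lad3 <- detection_ladder(grid, holm = TRUE)
  expect_gte(lad3$steps$p_combined[1], lad$steps$p_combined[1])
})

test_that("leakage summaries are medians of paired differences", {
  expect_equal(leakage_summary(c(0.01, 0.02), c(0.01, 0.02))$median_added_fraction, 0)
  l <- leakage_summary(rep(0, 3), c(0.0005, 0.0011, 0.0020))
  expect_equal(l$median_added_fraction, 0.0011)
  # negative differences are kept as-is
  expect_equal(leakage_summary(c(0.002), c(0.001))$median_added_fraction, -0.001)
  # exponential leak model: added fraction ~ f0 (exp(k_leak T) - 1)
  f0 <- 0.002; k_leak <- 0.005; T_exp <- 17
  expected_added <- f0 * (exp(k_leak * T_exp) - 1)
  added <- withr::with_seed(9, vapply(1:5, function(i) {
    tr <- simulate_switching(2e5, f0, k_leak, c(0, T_exp), fmax = 0.9, seed = 90 + i)
    tr$fraction[2] - tr$fraction[1]
  }, numeric(1)))
  l2 <- leakage_summary(rep(0, 5), added)
  expect_equal(l2$median_added_fraction, expected_added, tolerance = 0.25)
})

test_that("generation accounting follows the dilution-regrowth logarithm", {
  # regrowth to the same density after a 1e4-fold dilution
  g <- generations(1e4, rho = rep(1e9, 4), rho_prev = rep(1e9, 4))
  expect_equal(g$generations, rep(13.2877124, 4), tolerance = 1e-7)
  expect_equal(g$cumulative_generations[4], 53.1508495, tolerance = 1e-7)
  # dilution-only mode gives the same totals
  g2 <- generations(1e4, n_cycles = 4)
  expect_equal(g2$cumulative_generations, g$cumulative_generations)
  # no dilution, no regrowth: zero generations
  expect_equal(generations(1, rho = 1, rho_prev = 1)$generations, 0)
  # exact D-fold property
  for (D in c(10, 100, 12345)) {
    expect_equal(generations(D, n_cycles = 1)$generations, log2(D))
  }
  # measured densities shift the count
  g3 <- generations(1e4, rho = 2e9, rho_prev = 1e9)
  expect_equal(g3$generations, log2(1e4) + 1)
  expect_error(generations(0, n_cycles = 1), "dilution_factor")
  expect_error(generations(1e4, rho = -1, rho_prev = 1), "densities")
})

test_that("stability tracking reports declines relative to the post-exposure point", {
  track <- tibble::tibble(
    phase = c("pre_induction", "post_exposure", "passage_1", "passage_2"),
    p_hat = c(0.001, 0.40, 0.30, 0.16)
  )
  st <- stability_track(track)
  expect_equal(st$relative_change[st$phase == "post_exposure"], 0)
  expect_equal(st$relative_change[st$phase == "passage_2"], -0.6)
  # constant fractions: no decline anywhere
  flat <- tibble::tibble(phase = c("post_exposure", "passage_1"), p_hat = c(0.2, 0.2))
  expect_equal(stability_track(flat)$relative_change, c(0, 0))
  expect_error(stability_track(track, reference = "nope"), "reference")
  zero <- tibble::tibble(phase = c("post_exposure", "passage_1"), p_hat = c(0, 0.1))
  expect_error(stability_track(zero), "undefined")
})

test_that("selection-driven decline matches the two-type competition recursion", {
  s <- 0.017
  gens <- round(log2(1e4) * (0:4))
  truth <- competition_recursion(0.4, s, max(gens))[gens + 1]
  # binomially sampled measurements of the declining fraction
  p_hat <- withr::with_seed(10, rbinom(5, 2e5, truth) / 2e5)
  st <- stability_track(tibble::tibble(
    phase = c("post_exposure", paste0("passage_", 1:4)),
    p_hat = p_hat
  ))
  expect_equal(st$relative_change, truth / truth[1] - 1, tolerance = 0.02)
  # ~53 generations of s = 0.017 produce a decline of roughly half
  expect_lt(st$relative_change[5], -0.4)
})

test_that("mass-to-molar conversion reproduces the arsenic regulatory threshold", {
  expect_equal(ppb_to_nM(10), 133.4757, tolerance = 1e-6)
  expect_equal(ppb_to_nM(50), 5 * ppb_to_nM(10))
  expect_equal(ppb_to_nM(1000, molar_mass = 1000), 1000)
  expect_error(ppb_to_nM(10, molar_mass = 0), "molar_mass")
})
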