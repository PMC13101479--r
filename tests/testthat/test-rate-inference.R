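test_that("the binomial log-likelihood kernel is computed correctly", {
  tr <- tibble::tibble(time_h = c(0, 1), x = c(1, 5), n = c(100, 10))
  # kernel at p = 0.5 for the (x = 5, n = 10) point is 10 ln 0.5
  f0 <- 0.01
  k <- log(0.5 / f0) # makes the exponential prediction exactly 0.5 at t = 1
  ll <- switching_loglik(tr, "exponential", k = k)
  expect_equal(ll, -6.9314718, tolerance = 1e-6)
  # doubling all counts doubles the kernel
  tr2 <- tibble::tibble(time_h = c(0, 1), x = c(2, 10), n = c(200, 20))
  expect_equal(switching_loglik(tr2, "exponential", k = k), 2 * ll)
  # the MLE of a single binomial point is the observed proportion
  best <- switching_loglik(tr, "exponential", k = k)
  for (p in c(0.3, 0.45, 0.55, 0.7)) {
    expect_lt(switching_loglik(tr, "exponential", k = log(p / f0)), best)
  }
})

test_that("AICc matches hand evaluation and its limiting behaviour", {
  expect_equal(aicc(-10, 2, 8), 26.4)
  # equal likelihoods: fewer parameters always wins
  expect_lt(aicc(-10, 1, 8), aicc(-10, 2, 8))
  # AICc -> AIC as n grows; selection invariant to a shared loglik shift
  aic <- function(ll, p) -2 * ll + 2 * p
  expect_lt(abs(aicc(-10, 2, 1e6) - aic(-10, 2)), 1e-4)
  d1 <- aicc(-10, 2, 8) - aicc(-12, 1, 8)
  d2 <- aicc(-10 + 100, 2, 8) - aicc(-12 + 100, 1, 8)
  expect_equal(d1, d2)
  expect_error(aicc(-10, 2, 3), "n_obs")
})

test_that("exponential fits recover their generating parameters", {
  # noiseless fractions: k recovered essentially exactly
  tr <- exact_exp_trajectory(0.3, 0.01, seq(0, 8, 2))
  fit <- fit_exponential(tr)
  expect_equal(fit$k, 0.3, tolerance = 1e-6)
  expect_equal(fit$model, "exponential")
  expect_equal(fit$n_params, 1L)
  # two exact points: closed-form k = ln(f1/f0)/t1
  tr2 <- tibble::tibble(time_h = c(0, 5), x = c(10, 80), n = c(1000, 1000))
  fit2 <- fit_exponential(tr2)
  expect_equal(fit2$k, log(0.08 / 0.01) / 5, tolerance = 1e-6)
  expect_true(is.na(fit2$aicc)) # too few points for the correction term
  # constant data: boundary optimum at k = 0
  tr3 <- tibble::tibble(time_h = seq(0, 8, 2), x = rep(50, 5), n = rep(1000, 5))
  expect_equal(fit_exponential(tr3)$k, 0, tolerance = 1e-6)
})

test_that("f0 is fixed from the measured time-zero fraction, smoothed at zero counts", {
  tr <- tibble::tibble(time_h = c(0, 2, 4), x = c(0, 5, 12), n = rep(1000, 3))
  fit <- fit_exponential(tr)
  expect_true(fit$f0_smoothed)
  expect_equal(fit$f0, 0.5 / 1001)
})

test_that("the ensemble MCMC logistic fit recovers the rate and saturates correctly", {
  # regime where only k is well-identified (far from saturation at 8 h)
  tr <- sampled_trajectory(0.6, 0.8, f0 = 0.001, t_grid = seq(0, 8, length.out = 7),
                           n_events = 1e5, seed = 21)
  fit <- fit_logistic(tr, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$k, 0.6, tolerance = 0.1)
  expect_equal(fit$n_params, 2L)
  expect_lt(max(fit$diagnostics$rhat), 1.05)
  # saturating regime: fmax identified too
  tr2 <- sampled_trajectory(0.6, 0.8, f0 = 0.001, t_grid = seq(0, 16, length.out = 7),
                            n_events = 1e5, seed = 22)
  fit2 <- fit_logistic(tr2, seed = 2)
  expect_equal(fit2$fmax, 0.8, tolerance = 0.0625) # within 0.05 absolute
  expect_equal(fit2$k, 0.6, tolerance = 0.1)
  # reproducible under a fixed seed
  fit2b <- fit_logistic(tr2, seed = 2)
  expect_identical(fit2$k, fit2b$k)
})

test_that("flat trajectories are flagged non-identifiable", {
  tr <- tibble::tibble(time_h = seq(0, 8, 2), x = rep(10, 5), n = rep(1e4, 5))
  fit <- fit_logistic(tr, seed = 3)
  expect_true("non_identifiable" %in% fit$flags)
})

test_that("an observed fraction of 1 pins fmax and drops to one parameter", {
  tr <- tibble::tibble(time_h = c(0, 2, 4, 6), x = c(100, 600, 950, 1000), n = rep(1000, 4))
  fit <- fit_logistic(tr, seed = 4)
  expect_equal(fit$fmax, 1)
  expect_equal(fit$n_params, 1L)
  expect_true("fmax_fixed_at_1" %in% fit$flags)
})

test_that("with fmax pinned at 1 the logistic rate matches the exponential fit at small f", {
  tr <- sampled_trajectory(0.1, 0.9, f0 = 0.001, t_grid = seq(0, 8, length.out = 7),
                           n_events = 1e5, seed = 23)
  fe <- fit_exponential(tr)
  ks <- seq(max(fe$k - 0.05, 0), fe$k + 0.05, length.out = 2001)
  ll <- vapply(ks, function(k) switching_loglik(tr, "logistic", k = k, fmax = 1), numeric(1))
  k_log <- ks[which.max(ll)]
  expect_equal(k_log, fe$k, tolerance = 0.01)
})

test_that("model selection follows the AICc rule and its exceptions", {
  tr <- sampled_trajectory(0.4, 0.6, seed = 24)
  fe <- fit_exponential(tr)
  fl <- fit_logistic(tr, seed = 6)
  # saturating data: logistic has the lower AICc and is selected
  expect_lt(fl$aicc, fe$aicc)
  expect_equal(select_model(fe, fl, concentration = 1e-5)$model, "logistic")
  # zero inducer concentration forces the exponential fit regardless of AICc
  expect_equal(select_model(fe, fl, concentration = 0)$model, "exponential")
  # argmin on AICc, tie broken toward fewer parameters
  mk <- function(model, aicc_value, n_params) {
    f <- fe
    f$model <- model; f$aicc <- aicc_value; f$n_params <- n_params
    f
  }
  expect_equal(select_model(mk("exponential", 26, 1), mk("logistic", 20, 2))$model, "logistic")
  expect_equal(select_model(mk("exponential", 20, 1), mk("logistic", 20, 2))$model, "exponential")
  # both non-converged propagates an error
  bad_e <- fe; bad_e$converged <- FALSE
  bad_l <- fl; bad_l$converged <- FALSE
  expect_error(select_model(bad_e, bad_l), "converge")
})

test_that("a leak-free uninduced trajectory yields a rate indistinguishable from zero", {
  tr <- sampled_trajectory(0, 0.9, f0 = 0.01, seed = 25)
  fit <- fit_switching_rate(tr, concentration = 0)
  expect_equal(fit$model, "exponential")
  expect_gte(fit$k, 0)
  # over 16 h, k t_max must stay within ~3 sd of the log-fraction noise
  se_logf <- sqrt((1 - 0.01) / (0.01 * 2e4))
  expect_lt(fit$k * 16, 3 * se_logf * sqrt(6))
})

test_that("tidy, glance and predict expose the fit in broom style", {
  tr <- sampled_trajectory(0.4, 0.6, seed = 26)
  fit <- fit_logistic(tr, seed = 7)
  td <- tidy(fit)
  expect_setequal(td$term, c("k", "fmax"))
  expect_true(all(c("conf.low", "conf.high") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$model, "logistic")
  expect_equal(gl$k, fit$k)
  expect_equal(predict(fit, 0), fit$f0)
})

test_that("ensemble summaries average curves and bracket rates", {
  tr <- sampled_trajectory(0.3, 0.9, seed = 27)
  f1 <- fit_exponential(tr)
  # single replicate: mean curve equals that fit, degenerate envelope
  e1 <- ensemble_summary(list(f1), 0:8)
  expect_equal(e1$curves$mean, predict(f1, 0:8))
  expect_equal(e1$curves$min, e1$curves$max)
  # two synthetic replicates with k = 0.2 and 0.4: k_mean = 0.3, envelope brackets
  f2 <- f1; f2$k <- 0.2
  f3 <- f1; f3$k <- 0.4
  e2 <- ensemble_summary(list(f2, f3), 0:8)
  expect_equal(e2$k_mean, 0.3)
  expect_equal(e2$k_min, 0.2)
  expect_equal(e2$k_max, 0.4)
  expect_true(all(e2$curves$min <= pmin(predict(f2, 0:8), predict(f3, 0:8)) + 1e-12))
  expect_true(all(e2$curves$max >= pmax(predict(f2, 0:8), predict(f3, 0:8)) - 1e-12))
  expect_equal(glance(e2)$n_replicates, 2)
})

test_that("replicate envelopes shrink as per-point event counts grow", {
  width_at <- function(n_events) {
    fits <- lapply(1:3, function(r) {
      fit_switching_rate(
        sampled_trajectory(0.3, 0.9, n_events = n_events, seed = 300 + r),
        concentration = 1e-5, seed = 400 + r
      )
    })
    e <- ensemble_summary(fits, seq(0, 16, 2))
    mean(e$curves$max - e$curves$min)
  }
  expect_lt(width_at(1e6), width_at(1e4))
})
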