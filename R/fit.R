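new_switch_fit <- function(model, k, fmax, f0, f0_smoothed, max_loglik,
                           n_obs, n_params, aicc_value, converged,
                           flags = character(), diagnostics = list()) {
  structure(
    list(
      model = model, k = k, fmax = fmax, f0 = f0, f0_smoothed = f0_smoothed,
      max_loglik = max_loglik, n_obs = n_obs, n_params = n_params,
      aicc = aicc_value, converged = converged, flags = flags,
      diagnostics = diagnostics
    ),
    class = "switch_fit"
  )
}

#' @export
print.switch_fit <- function(x, ...) {
  cat(sprintf("<switch_fit: %s model>\n", x$model))
  cat(sprintf("  k = %.5g per hour", x$k))
  if (!is.na(x$fmax)) cat(sprintf(", fmax = %.4g", x$fmax))
  cat(sprintf(", f0 = %.4g%s\n", x$f0, if (x$f0_smoothed) " (smoothed)" else ""))
  cat(sprintf("  logLik = %.4g, n_obs = %d, AICc = %s\n",
              x$max_loglik, x$n_obs,
              if (is.na(x$aicc)) "NA" else sprintf("%.4g", x$aicc)))
  if (!x$converged) cat("  NOT CONVERGED\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.switch_fit <- function(x, ...) {
  out <- tibble(
    term = c("k", if (!is.na(x$fmax)) "fmax"),
    estimate = c(x$k, if (!is.na(x$fmax)) x$fmax)
  )
  q <- x$diagnostics$posterior
  if (!is.null(q)) {
    out$conf.low <- q$q025[match(out$term, q$term)]
    out$conf.high <- q$q975[match(out$term, q$term)]
  }
  out
}

#' @export
glance.switch_fit <- function(x, ...) {
  tibble(
    model = x$model, k = x$k, fmax = x$fmax, f0 = x$f0,
    logLik = x$max_loglik, AICc = x$aicc, n_obs = x$n_obs,
    n_params = x$n_params, converged = x$converged,
    non_identifiable = "non_identifiable" %in% x$flags
  )
}

#' Predicted fraction curve of a fitted switching model
#'
#' @param object A `switch_fit`.
#' @param t Times in hours.
#' @param ... Unused.
#' @return Predicted fractions at `t`.
#' @export
predict.switch_fit <- function(object, t, ...) {
  if (object$model == "exponential") {
    object$f0 * exp(object$k * t)
  } else {
    logistic_fraction(t, object$f0, object$fmax, object$k)
  }
}

# Multi-start bounded 1-d maximum-likelihood search. The clamped likelihood
# is flat over much of [0, k_upper], where a single golden-section search can
# stall, so the optimum is first bracketed on a grid.
max_loglik_1d <- function(ll_fun_raw, k_upper, n_grid = 201) {
  # floor -Inf so the local optimiser never sees non-finite values
  ll_fun <- function(k) max(ll_fun_raw(k), -1e300)
  ks <- seq(0, k_upper, length.out = n_grid)
  lls <- vapply(ks, ll_fun, numeric(1))
  i <- which.max(lls)
  lo <- ks[max(1, i - 1)]; hi <- ks[min(n_grid, i + 1)]
  if (hi > lo) {
    opt <- optimize(ll_fun, c(lo, hi), maximum = TRUE, tol = 1e-10)
    if (opt$objective >= lls[i]) return(list(k = opt$maximum, loglik = opt$objective))
  }
  list(k = ks[i], loglik = lls[i])
}

#' Fit the exponential switching model by maximum likelihood
#'
#' Fits \eqn{f(t) = f_0 e^{k t}} with `f0` fixed to the measured t = 0
#' fraction, maximising the trajectory log-likelihood over `k` in
#' `[0, k_upper]` by a grid-bracketed (multi-start) bounded one-dimensional
#' search.
#'
#' @param trajectory See [switching_loglik()]; needs a t = 0 row and at least
#'   one later time point.
#' @param k_upper Upper bound for the rate, per hour (default 10: saturation
#'   within minutes, far beyond the relevant regime).
#' @param f0 Optional override of the initial fraction.
#' @return A `switch_fit` (model `"exponential"`, 1 parameter). `aicc` is
#'   `NA` with a flag when fewer than 3 post-zero points make the correction
#'   term undefined.
#' @examples
#' traj <- simulate_switching(1e4, 0.01, 0.3, 0:6, fmax = 0.9, seed = 1)
#' fit_exponential(traj)
#' @export
fit_exponential <- function(trajectory, k_upper = 10, f0 = NULL) {
  prep <- prep_trajectory(trajectory)
  if (prep$n_obs < 1) abort("at least one post-zero time point is required.")
  f0 <- f0 %||% prep$f0
  ll_fun <- function(k) loglik_points(f0 * exp(k * prep$t), prep)
  best <- max_loglik_1d(ll_fun, k_upper)
  flags <- character()
  aicc_value <- if (prep$n_obs > 2) aicc(best$loglik, 1, prep$n_obs) else {
    flags <- c(flags, "aicc_undefined")
    NA_real_
  }
  if (!is.finite(best$loglik) || best$loglik <= -1e299) flags <- c(flags, "degenerate_likelihood")
  new_switch_fit(
    model = "exponential", k = best$k, fmax = NA_real_,
    f0 = f0, f0_smoothed = prep$f0_smoothed,
    max_loglik = best$loglik, n_obs = prep$n_obs, n_params = 1L,
    aicc_value = aicc_value,
    converged = is.finite(best$loglik) && best$loglik > -1e299, flags = flags
  )
}

# Goodman-Weare affine-invariant stretch-move ensemble sampler on a
# rectangle, with a flat prior. log_post must accept an n x 2 matrix and
# return a vector. Returns the flattened post-burn-in chain and diagnostics.
stretch_sampler <- function(log_post, lower, upper, n_walkers, n_steps,
                            burn_in, a = 2, seed = NULL, init = NULL) {
  stopifnot(n_walkers >= 4, n_walkers %% 2 == 0, n_steps > burn_in)
  d <- length(lower)
  with_seed_(seed, {
    if (is.null(init)) {
      X <- cbind(
        runif(n_walkers, lower[1], upper[1]),
        runif(n_walkers, lower[2], upper[2])
      )
    } else {
      # small ball around the supplied start (walkers spread along the
      # posterior during burn-in; affine moves handle ridge geometry)
      jit <- pmax(upper - lower, 1e-8) * 0.02
      X <- cbind(
        pmin(pmax(init[1] + rnorm(n_walkers, 0, jit[1]), lower[1]), upper[1]),
        pmin(pmax(init[2] + rnorm(n_walkers, 0, jit[2]), lower[2]), upper[2])
      )
    }
    ll <- log_post(X)
    # ensure at least one walker starts at finite posterior
    tries <- 0
    while (all(!is.finite(ll)) && tries < 100) {
      X <- cbind(runif(n_walkers, lower[1], upper[1]),
                 runif(n_walkers, lower[2], upper[2]))
      ll <- log_post(X)
      tries <- tries + 1
    }
    halves <- list(seq_len(n_walkers / 2), seq_len(n_walkers / 2) + n_walkers / 2)
    keep_k <- matrix(NA_real_, n_steps - burn_in, n_walkers)
    keep_f <- matrix(NA_real_, n_steps - burn_in, n_walkers)
    keep_ll <- matrix(NA_real_, n_steps - burn_in, n_walkers)
    n_acc <- 0L; n_prop <- 0L
    for (s in seq_len(n_steps)) {
      for (h in 1:2) {
        idx <- halves[[h]]; oth <- halves[[3 - h]]
        m <- length(idx)
        z <- ((a - 1) * runif(m) + 1)^2 / a
        partner <- oth[sample.int(length(oth), m, replace = TRUE)]
        Y <- X[partner, , drop = FALSE] + z * (X[idx, , drop = FALSE] - X[partner, , drop = FALSE])
        ll_y <- log_post(Y)
        log_acc <- (d - 1) * log(z) + ll_y - ll[idx]
        acc <- log(runif(m)) < log_acc
        acc[!is.finite(ll_y)] <- FALSE
        X[idx[acc], ] <- Y[acc, , drop = FALSE]
        ll[idx[acc]] <- ll_y[acc]
        n_acc <- n_acc + sum(acc); n_prop <- n_prop + m
      }
      if (s > burn_in) {
        keep_f[s - burn_in, ] <- X[, 1]
        keep_k[s - burn_in, ] <- X[, 2]
        keep_ll[s - burn_in, ] <- ll
      }
    }
    list(
      fmax = keep_f, k = keep_k, loglik = keep_ll,
      acceptance = n_acc / n_prop
    )
  })
}

# Split-chain potential scale reduction factor over a (draws x walkers)
# matrix: each walker chain is halved, giving 2 * n_walkers sub-chains.
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  chains <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(chains); nn <- nrow(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Fit the logistic switching model by ensemble MCMC
#'
#' Samples `(fmax, k)` under flat priors on
#' `[max measured fraction, 1] x [0, k_upper]` with an affine-invariant
#' stretch-move ensemble sampler (32 walkers, 2000 steps, 500 burn-in by
#' default), `f0` fixed to the measured t = 0 fraction. The reported point
#' estimate is the maximum-likelihood sample, so the resulting AICc is
#' comparable with the exponential fit's. Posterior quantiles are retained as
#' diagnostics, and convergence is checked with the split-chain potential
#' scale reduction factor (flagged when >= 1.05).
#'
#' When the maximum measured fraction is 1 the `fmax` interval is empty:
#' `fmax` is fixed at 1 and `k` is fitted alone (one free parameter).
#'
#' A trajectory that is statistically flat is flagged `non_identifiable`:
#' a time-invariant fraction arises either with `k = 0` (any `fmax`) or with
#' `fmax` at the initial fraction (any `k`), so the likelihood has a ridge
#' and the two parameters cannot be resolved.
#'
#' @param trajectory See [switching_loglik()]; needs a t = 0 row and at least
#'   two later time points.
#' @param k_upper Upper rate bound, per hour.
#' @param n_walkers,n_steps,burn_in Sampler settings.
#' @param f0 Optional override of the initial fraction.
#' @param seed Optional integer seed (fits are reproducible under a fixed
#'   seed).
#' @return A `switch_fit` (model `"logistic"`, 2 parameters — or 1 when
#'   `fmax` is pinned at 1) with posterior quantiles, split-chain R-hat and
#'   acceptance rate in `$diagnostics`.
#' @examples
#' traj <- simulate_switching(1e4, 0.01, 0.6, seq(0, 8, 2), fmax = 0.8, seed = 1)
#' fit_logistic(traj, seed = 1)
#' @export
fit_logistic <- function(trajectory, k_upper = 10, n_walkers = 32,
                         n_steps = 2000, burn_in = 500, f0 = NULL, seed = NULL) {
  prep <- prep_trajectory(trajectory)
  if (prep$n_obs < 2) abort("at least two post-zero time points are required.")
  f0 <- f0 %||% prep$f0
  fmax_lo <- min(max(prep$fmax_lower, f0), 1)
  flags <- character()

  ll_flat <- loglik_points(rep(f0, prep$n_obs), prep)

  if (fmax_lo >= 1) {
    # empty fmax interval: pin fmax at 1, one free parameter
    ll_fun <- function(k) loglik_points(logistic_fraction(prep$t, f0, 1, k), prep)
    best <- max_loglik_1d(ll_fun, k_upper)
    flags <- c(flags, "fmax_fixed_at_1")
    aicc_value <- if (prep$n_obs > 2) aicc(best$loglik, 1, prep$n_obs) else NA_real_
    if (best$loglik - ll_flat < 0.5) flags <- c(flags, "non_identifiable")
    return(new_switch_fit(
      model = "logistic", k = best$k, fmax = 1, f0 = f0,
      f0_smoothed = prep$f0_smoothed, max_loglik = best$loglik,
      n_obs = prep$n_obs, n_params = 1L, aicc_value = aicc_value,
      converged = is.finite(best$loglik) && best$loglik > -1e299, flags = flags
    ))
  }

  log_post <- function(theta) {
    fmax <- theta[, 1]; k <- theta[, 2]
    out <- rep(-Inf, nrow(theta))
    ok <- fmax >= fmax_lo & fmax <= 1 & k >= 0 & k <= k_upper & fmax >= f0
    if (any(ok)) {
      p <- fmax[ok] / (1 + (fmax[ok] / f0 - 1) * exp(-outer(k[ok], prep$t)))
      if (prep$has_counts) {
        pc <- pmin(pmax(p, 1e-300), 1 - 1e-16)
        out[ok] <- as.vector(
          (log(pc) %*% prep$x) + (log1p(-pc) %*% (prep$n - prep$x))
        )
      } else {
        ph <- pmin(pmax(prep$fraction, 0.5 / prep$n), 1 - 0.5 / prep$n)
        v <- ph * (1 - ph) / prep$n
        dev <- sweep(p, 2, prep$fraction)
        out[ok] <- -0.5 * as.vector(dev^2 %*% (1 / v)) - 0.5 * sum(log(2 * pi * v))
      }
    }
    out
  }

  # coarse maximum-likelihood grid locates the (possibly ridge-shaped)
  # high-likelihood region; walkers start in a small ball around it
  grid <- as.matrix(expand.grid(
    fmax = seq(fmax_lo, 1, length.out = 31),
    k = seq(0, k_upper, length.out = 101)
  ))
  init <- grid[which.max(log_post(grid)), ]

  ch <- stretch_sampler(log_post, lower = c(fmax_lo, 0), upper = c(1, k_upper),
                        n_walkers = n_walkers, n_steps = n_steps,
                        burn_in = burn_in, seed = seed, init = init)
  i_best <- which.max(ch$loglik)
  k_hat <- ch$k[i_best]; fmax_hat <- ch$fmax[i_best]
  ll_best <- ch$loglik[i_best]

  rhat_k <- split_rhat(ch$k); rhat_f <- split_rhat(ch$fmax)
  converged <- is.finite(ll_best) && max(rhat_k, rhat_f) < 1.05
  if (!converged) flags <- c(flags, "mcmc_not_converged")
  if (ll_best - ll_flat < 0.5) flags <- c(flags, "non_identifiable")

  qs <- function(x) unname(quantile(x, c(0.025, 0.5, 0.975)))
  qk <- qs(as.vector(ch$k)); qf <- qs(as.vector(ch$fmax))
  aicc_value <- if (prep$n_obs > 3) aicc(ll_best, 2, prep$n_obs) else {
    flags <- c(flags, "aicc_undefined")
    NA_real_
  }

  new_switch_fit(
    model = "logistic", k = k_hat, fmax = fmax_hat, f0 = f0,
    f0_smoothed = prep$f0_smoothed, max_loglik = ll_best,
    n_obs = prep$n_obs, n_params = 2L, aicc_value = aicc_value,
    converged = converged, flags = flags,
    diagnostics = list(
      rhat = c(fmax = rhat_f, k = rhat_k),
      acceptance = ch$acceptance,
      posterior = tibble(
        term = c("fmax", "k"),
        q025 = c(qf[1], qk[1]), q50 = c(qf[2], qk[2]), q975 = c(qf[3], qk[3])
      ),
      fmax_lower = fmax_lo
    )
  )
}

#' Select between the exponential and logistic fits by AICc
#'
#' Implements the identifiability-aware selection rule: with no inducer
#' (concentration 0) only the exponential fit is meaningful and it is
#' returned unconditionally; otherwise the fit with the lower AICc wins, with
#' exact ties going to the exponential model (fewer parameters). Fits that
#' failed to converge are excluded; if none remain, an error carrying both
#' fits' diagnostics is raised.
#'
#' @param fit_exp,fit_log `switch_fit` objects from [fit_exponential()] and
#'   [fit_logistic()].
#' @param concentration Inducer concentration (molar) of the trajectory;
#'   `0` forces the exponential fit. `NA` (default) applies the AICc rule.
#' @return The selected `switch_fit`.
#' @export
select_model <- function(fit_exp, fit_log, concentration = NA) {
  if (!inherits(fit_exp, "switch_fit") || !inherits(fit_log, "switch_fit")) {
    abort("`fit_exp` and `fit_log` must be switch_fit objects.")
  }
  if (!is.na(concentration) && concentration == 0) return(fit_exp)
  ok_exp <- fit_exp$converged; ok_log <- fit_log$converged
  if (!ok_exp && !ok_log) {
    abort(sprintf(
      "both fits failed to converge (exponential flags: %s; logistic flags: %s).",
      paste(fit_exp$flags, collapse = "/"), paste(fit_log$flags, collapse = "/")
    ))
  }
  if (!ok_log) return(fit_exp)
  if (!ok_exp) return(fit_log)
  if (is.na(fit_exp$aicc) || is.na(fit_log$aicc)) {
    abort("AICc undefined for at least one fit; cannot select.")
  }
  if (fit_log$aicc < fit_exp$aicc - 1e-9) fit_log else fit_exp
}

#' Estimate the switching rate of one trajectory (fit both models, select)
#'
#' Convenience wrapper running the full per-replicate procedure: fit the
#' exponential model (always) and the logistic model (unless
#' `concentration == 0` or `model` pins one), then select by AICc via
#' [select_model()].
#'
#' @inheritParams fit_logistic
#' @param concentration Inducer concentration (molar) or `NA`.
#' @param model `"auto"` (default), `"exponential"` or `"logistic"`.
#' @param ... Passed to the individual fitters.
#' @return The selected `switch_fit`; the unselected candidate is attached as
#'   attribute `"candidates"`.
#' @examples
#' traj <- simulate_switching(2e4, 0.01, 0.5, seq(0, 8, 2), fmax = 0.6, seed = 2)
#' fit_switching_rate(traj, concentration = 1e-5, seed = 1)
#' @export
fit_switching_rate <- function(trajectory, concentration = NA,
                               model = c("auto", "exponential", "logistic"),
                               seed = NULL, ...) {
  model <- match.arg(model)
  if (model == "exponential" || (!is.na(concentration) && concentration == 0)) {
    return(fit_exponential(trajectory, ...))
  }
  fl <- fit_logistic(trajectory, seed = seed, ...)
  if (model == "logistic") return(fl)
  fe <- fit_exponential(trajectory, ...)
  sel <- select_model(fe, fl, concentration)
  attr(sel, "candidates") <- list(exponential = fe, logistic = fl)
  sel
}
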