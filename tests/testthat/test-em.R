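test_that("E-step posteriors follow the density-ratio formula", {
  X <- random_data(12, 3, seed = 4)
  # single component: responsibilities are exactly one
  p1 <- toy_params(1L, 3L, seed = 1)
  expect_equal(unclass(e_step(X, p1)), matrix(1, 12, 1), ignore_attr = TRUE)

  # symmetric two-component model, sample at the midpoint
  Om <- diag(2)
  pars <- mixture_params(c(0.5, 0.5), rbind(c(-1, 0), c(1, 0)),
                         list(Om, Om), c(0, 0), Om)
  Xm <- ajgm_data(rbind(c(0, 0.4), c(0, -2)))
  Z <- e_step(Xm, pars)
  expect_equal(Z[1, ], c(0.5, 0.5), tolerance = 1e-12)

  # density-ratio oracle on a random two-component model
  pars2 <- toy_params(2L, 2L, seed = 9)
  X2 <- random_data(8, 2, seed = 10)
  Z2 <- e_step(X2, pars2)
  for (l in c(1L, 5L)) {
    lead <- vapply(1:2, function(k) {
      single <- mixture_params(1, pars2$means[k, , drop = FALSE],
                               pars2$precisions[k],
                               pars2$overall_mean, pars2$overall_precision)
      log(pars2$proportions[k]) + mixture_log_density(X2$values[l, ], single)
    }, numeric(1))
    expect_equal(Z2[l, ], exp(lead) / sum(exp(lead)), tolerance = 1e-10)
  }
})

test_that("E-step underflow falls back to uniform responsibilities", {
  Om <- diag(2)
  pars <- mixture_params(c(0.5, 0.5), rbind(c(0, 0), c(1, 0)),
                         list(Om, Om), c(0, 0), Om)
  Xfar <- ajgm_data(rbind(c(1e200, 0), c(0, 0)))
  expect_warning(Z <- e_step(Xfar, pars), "underflow")
  expect_equal(Z[1, ], c(0.5, 0.5))
  expect_gt(Z[2, 1], 0.5)
})

test_that("M-step moments equal the closed-form weighted statistics", {
  X <- random_data(5, 3, seed = 6)
  Xp <- make_overall(X, "identity")

  # uniform responsibilities: every subtype mean is the global mean
  Zu <- responsibilities(matrix(0.5, 5, 2))
  mu <- m_step_moments(X, Xp, Zu)
  expect_equal(mu$means[1, ], colMeans(X$values), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(mu$means[2, ], colMeans(X$values), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(mu$proportions, c(0.5, 0.5))

  # hard assignment: per-cluster means and fractions
  Zh <- responsibilities(matrix(c(1, 1, 0, 0, 0, 0, 0, 1, 1, 1), 5))
  mh <- m_step_moments(X, Xp, Zh)
  expect_equal(mh$means[1, ], colMeans(X$values[1:2, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(mh$proportions, c(0.4, 0.6))

  # random soft responsibilities against direct formulas
  withr::with_seed(8, {
    W <- matrix(stats::runif(10), 5)
    W <- W / rowSums(W)
  })
  Zr <- responsibilities(W)
  mr <- m_step_moments(X, Xp, Zr)
  for (k in 1:2) {
    wk <- W[, k]
    muk <- colSums(wk * X$values) / sum(wk)
    expect_equal(mr$means[k, ], muk, tolerance = 1e-12, ignore_attr = TRUE)
    Vc <- sweep(X$values, 2, muk)
    Sk <- t(Vc) %*% (wk * Vc) / sum(wk)
    expect_equal(mr$stats$scatter[[k]], Sk, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(mr$stats$sizes[k], sum(wk))
  }
  expect_equal(mr$stats$scatter[[3]],
               stats::cov(Xp$values) * (nrow(Xp$values) - 1) / nrow(Xp$values),
               tolerance = 1e-12, ignore_attr = TRUE)

  # degenerate component
  Zd <- responsibilities(cbind(c(1, 0.999, rep(1, 3)) - c(0, 0, 0, 0, 0),
                               c(0, 0.001, 0, 0, 0)))
  expect_error(m_step_moments(X, Xp, Zd), "effective size")
})

test_that("weight refresh evaluates the adaptive rules entrywise", {
  cfg <- penalty_config(lambda1 = 1, lambda2 = 0.5, lambda3 = 1,
                        gamma = 1, tre = 0.05)
  # identity precisions: all differences zero, weights at the cap, f = 1
  pars0 <- mixture_params(c(0.5, 0.5), matrix(0, 2, 3),
                          list(diag(3), diag(3)), rep(0, 3), diag(3))
  w0 <- refresh_weights(pars0, cfg)
  off <- !diag(TRUE, 3)
  expect_true(all(w0$subtype_fusion[[1]][off] == cfg$weight_cap))
  expect_true(all(w0$consensus == 1))

  # gamma 0: unit weights regardless of the estimates
  cfg0 <- penalty_config(gamma = 0, lambda2 = 0.5, lambda3 = 1)
  pars <- toy_params(2L, 3L, seed = 2)
  wg0 <- refresh_weights(pars, cfg0)
  expect_true(all(wg0$subtype_fusion[[1]] == 1))
  expect_true(all(wg0$overall_fusion == 1))

  # hand-set 2x2 precisions against the entrywise formulas
  mk <- function(v) matrix(c(1, v, v, 1), 2)
  ph <- mixture_params(c(0.5, 0.5), matrix(0, 2, 2),
                       list(mk(0.3), mk(0.1)), c(0, 0), mk(0.12))
  wh <- refresh_weights(ph, cfg)
  expect_equal(wh$subtype_fusion[[1]][1, 2], 1 / 0.2)
  expect_equal(wh$overall_fusion[1, 2], 1 / 0.02)
  expect_equal(wh$consensus[1, 2], cfg$lambda2 / cfg$lambda3)  # 0.2 >= tre
})

test_that("zero imputation draws from the conditional subtype Gaussian", {
  p1 <- toy_params(1L, 2L, seed = 3)
  # no mask: input returned unchanged
  X <- random_data(6, 2, seed = 11)
  Z <- responsibilities(matrix(1, 6, 1))
  expect_identical(impute_zeros(X, Z, p1, rng_seed = 1)$values, X$values)

  # masked positions are the only ones that change, reproducibly
  mask <- matrix(FALSE, 6, 2)
  mask[2, 1] <- mask[5, 2] <- TRUE
  Xm <- ajgm_data(X$values, zero_mask = mask)
  i1 <- impute_zeros(Xm, Z, p1, rng_seed = 42)
  i2 <- impute_zeros(Xm, Z, p1, rng_seed = 42)
  expect_identical(i1$values, i2$values)
  expect_identical(i1$values[!mask], Xm$values[!mask])
  expect_false(any(i1$values[mask] == Xm$values[mask]))

  # diagonal precision: conditional equals the marginal; Monte-Carlo mean
  mu <- c(3, -1)
  Om <- diag(c(4, 0.25))
  pd <- mixture_params(1, matrix(mu, 1), list(Om), mu, Om)
  n <- 10000L
  Xd <- ajgm_data(matrix(stats::rnorm(2 * n), n, 2),
                  zero_mask = cbind(rep(TRUE, n), rep(FALSE, n)))
  Zd <- responsibilities(matrix(1, n, 1))
  imp <- impute_zeros(Xd, Zd, pd, rng_seed = 7)
  se <- sqrt(1 / 4) / sqrt(n)
  expect_lt(abs(mean(imp$values[, 1]) - mu[1]), 3 * se)

  # fully masked sample warns and draws from the marginal
  Xall <- ajgm_data(matrix(0, 2, 2),
                    zero_mask = rbind(c(TRUE, TRUE), c(TRUE, FALSE)))
  expect_warning(impute_zeros(Xall, responsibilities(matrix(1, 2, 1)),
                              p1, rng_seed = 1),
                 "all entries masked")
})

test_that("imputation respects correlated conditionals", {
  # strong positive partial correlation: conditioning on a high observed
  # coordinate must shift the imputed mean accordingly
  Om <- matrix(c(1, -0.9, -0.9, 1), 2) * 5
  mu <- c(0, 0)
  pars <- mixture_params(1, matrix(mu, 1), list(Om), mu, Om)
  n <- 4000L
  xB <- 2
  Xc <- ajgm_data(matrix(c(rep(0, n), rep(xB, n)), n, 2),
                  zero_mask = cbind(rep(TRUE, n), rep(FALSE, n)))
  imp <- impute_zeros(Xc, responsibilities(matrix(1, n, 1)), pars,
                      rng_seed = 3)
  cond_mean <- mu[1] - (Om[1, 2] / Om[1, 1]) * (xB - mu[2])
  cond_sd <- sqrt(1 / Om[1, 1])
  expect_lt(abs(mean(imp$values[, 1]) - cond_mean), 3 * cond_sd / sqrt(n))
})

test_that("overall-sample construction covers both modes", {
  X <- random_data(20, 3, seed = 13)
  idX <- make_overall(X, "identity")
  expect_identical(idX$values, X$values)
  expect_equal(idX$source, "identity_of_X")

  s1 <- make_overall(X, "sampled", m = 500, rng_seed = 21)
  s2 <- make_overall(X, "sampled", m = 500, rng_seed = 21)
  expect_identical(s1$values, s2$values)
  expect_error(make_overall(X, "sampled"), "m >= 2")

  # moments of a large draw match the fitted Gaussian
  big <- make_overall(X, "sampled", m = 10000, rng_seed = 22)
  for (j in 1:3) {
    se <- stats::sd(X$values[, j]) / sqrt(10000)
    expect_lt(abs(mean(big$values[, j]) - mean(X$values[, j])), 4 * se)
  }
})

test_that("EM recovers well-separated clusters and ascends its objective", {
  sim <- two_cluster_data(n_per = 100L, p = 10L, sep = 5, seed = 31)
  fit <- ajgm_fit(sim$data, K = 2, cfg = penalty_config(lambda1 = 2),
                  admm = admm_config(max_iter = 1000, tol_primal = 1e-7,
                                     tol_dual = 1e-7),
                  max_iter = 20, seed = 3)
  expect_equal(adjusted_rand_index(fit$hard_labels, sim$labels), 1)
  expect_true(all(diff(fit$objective_trace) > -1e-8 *
                    pmax(1, abs(fit$objective_trace[-1]))))
  expect_true(fit$converged)
})

test_that("EM monotonicity holds across random fixtures with imputation off", {
  withr::with_seed(71, {
    for (r in 1:8) {
      n <- sample(30:60, 1)
      p <- sample(3:5, 1)
      X <- ajgm_data(matrix(stats::rnorm(n * p), n, p) +
                       rep(sample(0:1, n, replace = TRUE) * 2, p))
      fit <- ajgm_fit(X, K = 2,
                      cfg = penalty_config(lambda1 = 0.5, lambda2 = 0.2,
                                           lambda3 = 0.5),
                      admm = admm_config(max_iter = 3000, tol_primal = 1e-9,
                                         tol_dual = 1e-9),
                      max_iter = 12, seed = r)
      tr <- fit$objective_trace
      expect_true(all(diff(tr) > -1e-8 * pmax(1, abs(tr[-1]))))
    }
  })
})

test_that("fits are deterministic given a seed and invariant to row order", {
  sim <- two_cluster_data(n_per = 40L, p = 5L, sep = 6, seed = 41)
  f1 <- ajgm_fit(sim$data, K = 2, max_iter = 10, seed = 9)
  f2 <- ajgm_fit(sim$data, K = 2, max_iter = 10, seed = 9)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_identical(f1$hard_labels, f2$hard_labels)

  # permuting the samples permutes the responsibilities but leaves the
  # fitted networks unchanged (the subtype chain order is canonical)
  perm <- withr::with_seed(2, sample.int(80))
  Xp <- ajgm_data(sim$data$values[perm, ])
  f3 <- ajgm_fit(Xp, K = 2, max_iter = 10, seed = 9)
  expect_equal(f3$params$means, f1$params$means, tolerance = 1e-6)
  expect_equal(f3$hard_labels, f1$hard_labels[perm])
})

test_that("single-subtype fit agrees with a direct penalized solve", {
  X <- random_data(60, 4, seed = 51)
  cfg <- penalty_config(lambda1 = 1, lambda2 = 0, lambda3 = 0.5)
  fit <- ajgm_fit(X, K = 1, cfg = cfg,
                  admm = admm_config(max_iter = 4000, tol_primal = 1e-9,
                                     tol_dual = 1e-9),
                  max_iter = 10, seed = 1)
  # with K = 1 the E-step is trivial, so the M-step statistics are the plain
  # sample moments and the fit solves one penalized precision problem
  Xp <- make_overall(X, "identity")
  Z <- responsibilities(matrix(1, 60, 1))
  mom <- m_step_moments(X, Xp, Z)
  cfg2 <- cfg
  cfg2$lambda1 <- 2 * cfg$lambda1
  cfg2$lambda2 <- 2 * cfg$lambda2
  cfg2$lambda3 <- 2 * cfg$lambda3
  orc <- oracle_precisions(mom$stats, cfg2, fit$weights)
  expect_lt(max(abs(fit$params$precisions[[1]] - orc[[1]])), 1e-3)
  expect_lt(max(abs(fit$params$overall_precision - orc[[2]])), 1e-3)
})

test_that("parameter recovery on modular simulated data", {
  # scaled benchmark: 2 block slots, 3 subtypes
  scores <- lapply(1:3, function(r) {
    cfgs <- simulation_config(p = 20L, K = 3L, nk = 150L, seed = 600 + r)
    sim <- simulate_ajgm_data(cfgs)
    fit <- ajgm_fit(sim$data, K = 3,
                    cfg = penalty_config(lambda1 = 1, lambda2 = 0.25,
                                         lambda3 = 0.5, edge_threshold = 0.1),
                    admm = admm_config(max_iter = 300, tol_primal = 1e-5,
                                       tol_dual = 1e-5),
                    max_iter = 20, seed = r)
    score_fit(fit, sim$truth, sim$labels)
  })
  expect_equal(mean(vapply(scores, `[[`, numeric(1), "ARI")), 1)
  expect_gt(mean(vapply(scores, `[[`, numeric(1), "TPR")), 0.6)
})

test_that("fit validates K against the sample count", {
  X <- random_data(10, 3)
  expect_error(ajgm_fit(X, K = 0), "K must be")
  expect_error(ajgm_fit(X, K = 11), "cannot exceed")
})
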