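test_that("chi-squared thresholds match the conventional -1.92 / -3.00", {
  expect_equal(round(chisq_threshold(1), 2), -1.92)
  expect_equal(round(chisq_threshold(2), 2), -3.00)
})

test_that("confidence intervals interpolate a quadratic profile exactly", {
  thr <- chisq_threshold(1)
  w <- 0.004
  psi <- seq(0.05, 0.5, length.out = 200)
  v <- -(psi - 0.3)^2 / w
  iv <- layerwalk:::profile_intervals(psi, v, thr)
  half <- sqrt(-thr * w)
  expect_equal(iv$lower, 0.3 - half, tolerance = 1e-4)
  expect_equal(iv$upper, 0.3 + half, tolerance = 1e-4)
  expect_false(iv$lower_censored)
  expect_false(iv$upper_censored)
})

test_that("a flat profile yields the whole domain, censored at both ends", {
  psi <- seq(0.05, 0.5, length.out = 40)
  iv <- layerwalk:::profile_intervals(psi, rep(0, 40), chisq_threshold(1))
  expect_equal(nrow(iv), 1)
  expect_equal(c(iv$lower, iv$upper), c(0.05, 0.5))
  expect_true(iv$lower_censored && iv$upper_censored)
})

test_that("multiple threshold crossings report every interval", {
  psi <- seq(0, 1, length.out = 101)
  v <- -3 + 3 * (sin(4 * pi * psi) > 0)      # two plateaus above -1.92
  iv <- layerwalk:::profile_intervals(psi, v, -1.92)
  expect_equal(nrow(iv), 2)
})

test_that("single-layer profile equals brute-force grid evaluation", {
  g <- layered_geometry(c(0, 15), 0.35)
  tmpl <- layered_geometry(c(0, 15))
  dat <- simulate_exit_times(g, data.frame(release = 15, count = 200),
                             seed = 14)
  fit <- exit_fit(dat, tmpl, likelihood = "exact")
  pr <- profile(fit, grid_size = 30)
  d <- pr$profiles$h1
  brute <- vapply(d$psi, function(p) exit_loglik(p, dat, tmpl), numeric(1))
  expect_equal(d$loglik, brute - max(max(brute), fit$logLik),
               tolerance = 1e-8)
  expect_lte(max(d$loglik), 1e-8)
})

test_that("profile dominates the likelihood at any fixed nuisance value", {
  g <- two_layer_geometry()
  tmpl <- layered_geometry(c(0, 30, 70))
  dat <- simulate_exit_times(g, data.frame(release = c(30, 70),
                                           count = c(60, 60)), seed = 15)
  fit <- exit_fit(dat, tmpl, likelihood = "approx")
  pr <- profile(fit, which = 1, grid_size = 15)
  d <- pr$profiles$h1
  ll <- fit$loglik_fn
  for (i in seq(1, 15, by = 3)) {
    at_true <- as.numeric(ll(c(d$psi[i], 0.4))) - pr$l_max
    expect_gte(d$loglik[i] + 1e-6, at_true)
  }
  ## profile peaks near zero (the grid need not contain the MLE exactly)
  expect_lte(max(d$loglik), 1e-8)
  expect_gt(max(d$loglik), -0.5)
  i_hat <- which.min(abs(d$psi - coef(fit)[1]))
  expect_equal(max(d$loglik), d$loglik[i_hat])
})

test_that("bivariate profile with no nuisance equals the normalized
           log-likelihood surface and contains the MLE", {
  g <- two_layer_geometry()
  tmpl <- layered_geometry(c(0, 30, 70))
  dat <- simulate_exit_times(g, data.frame(release = c(30, 70),
                                           count = c(80, 80)), seed = 16)
  fit <- exit_fit(dat, tmpl, likelihood = "approx")
  pr2 <- profile_pair(fit, pair = c(1, 2), grid_size = 8)
  ll <- fit$loglik_fn
  for (i in c(1, 4, 8)) for (k in c(2, 6)) {
    direct <- as.numeric(ll(c(pr2$psi1[i], pr2$psi2[k]))) - pr2$l_max
    expect_equal(pr2$surface[i, k], direct, tolerance = 1e-9)
  }
  ## the cell nearest the MLE is inside the 95% region
  i0 <- which.min(abs(pr2$psi1 - coef(fit)[1]))
  k0 <- which.min(abs(pr2$psi2 - coef(fit)[2]))
  expect_gte(pr2$surface[i0, k0], pr2$threshold)
})

test_that("coverage study returns per-component coverage and censoring", {
  g <- layered_geometry(c(0, 12), 0.3)
  tmpl <- layered_geometry(c(0, 12))
  cs <- coverage_study(tmpl, 0.3, data.frame(release = 12, count = 150),
                       n_replicates = 4, likelihood = "approx", seed = 2,
                       grid_size = 25)
  expect_equal(cs$n_replicates, 4)
  expect_true(all(cs$coverage >= 0 & cs$coverage <= 1))
  expect_equal(nrow(cs$intervals), 4)
  ## single replicate: coverage is 0 or 1
  cs1 <- coverage_study(tmpl, 0.3, data.frame(release = 12, count = 150),
                        n_replicates = 1, likelihood = "approx", seed = 3,
                        grid_size = 25)
  expect_true(cs1$coverage %in% c(0, 1))
})
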