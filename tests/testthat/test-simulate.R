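test_that("two-site walk exit times follow the geometric law", {
  g <- layered_geometry(c(0, 1), 0.5)
  dat <- simulate_exit_times(g, data.frame(release = 1, count = 10000),
                             seed = 1)
  ## geometric with success probability 0.5: mean 2, variance 2
  se <- sd(dat$exit_time) / sqrt(nrow(dat))
  expect_lt(abs(mean(dat$exit_time) - 2), 3 * se)
  expect_true(all(dat$exit_time >= 1))
})

test_that("homogeneous walk matches the first-step mean-exit linear system", {
  g <- layered_geometry(c(0, 10), 0.5)
  ## independent oracle: E_x = 1 + h E_{x-1} + h E_{x+1} + (1 - 2h) E_x
  ## assembled directly as (I - Q) E = 1 on the transient positions
  h <- 0.5; L <- 10
  Q <- matrix(0, L, L)
  for (x in 1:L) {
    if (x > 1) Q[x, x - 1] <- h
    if (x < L) Q[x, x + 1] <- h
    Q[x, x] <- if (x == L) 1 - h else 1 - 2 * h
  }
  E <- solve(diag(L) - Q, rep(1, L))
  expect_equal(E[10], 110)   # closed form x(2L - x) at x = L, h = 1/2

  dat <- simulate_exit_times(g, data.frame(release = 10, count = 10000),
                             seed = 2)
  se <- sd(dat$exit_time) / sqrt(nrow(dat))
  expect_lt(abs(mean(dat$exit_time) - E[10]), 3 * se)
})

test_that("three-layer ensemble mean matches the Markov-chain mean", {
  dat <- fig2_ensemble()
  cm <- chain_moments(fig2_geometry(), 100)
  se <- sd(dat$exit_time) / sqrt(nrow(dat))
  expect_lt(abs(mean(dat$exit_time) - cm["mean"]), 3 * se)
  ## and the continuum mean, which carries an O(1/L) lattice correction
  expect_lt(abs(mean(dat$exit_time) - first_moment(fig2_geometry(), 100)),
            3 * se + abs(cm["mean"] - 20250))
})

test_that("simulation is deterministic given the master seed", {
  g <- two_layer_geometry()
  d1 <- simulate_exit_times(g, data.frame(release = c(30, 70),
                                          count = c(50, 50)), seed = 9)
  d2 <- simulate_exit_times(g, data.frame(release = c(30, 70),
                                          count = c(50, 50)), seed = 9)
  expect_identical(d1$exit_time, d2$exit_time)
  expect_equal(nrow(d1), 100)
  expect_equal(as.numeric(table(d1$release_position)), c(50, 50))
})

test_that("invalid designs and release positions are rejected", {
  g <- two_layer_geometry()
  expect_error(simulate_exit_times(g, data.frame(release = 0, count = 5)),
               "already absorbed")
  expect_error(simulate_exit_times(g, data.frame(release = 71, count = 5)))
  expect_error(simulate_exit_times(g, data.frame(release = 30, count = 0)),
               "count")
})

test_that("the hard step cap raises instead of looping", {
  g <- layered_geometry(c(0, 50), 0.05)
  expect_error(simulate_exit_times(g, data.frame(release = 50, count = 1),
                                   seed = 1, step_cap = 10), "step cap")
})

test_that("empirical summary counts, normalizes and flags degeneracy", {
  dat <- data.frame(release_position = c(5, 5, 5, 9),
                    exit_time = c(3, 3, 4, 7))
  s <- empirical_summary(dat, 5)
  expect_equal(unname(s$pmf), c(2 / 3, 1 / 3))
  expect_equal(names(s$pmf), c("3", "4"))
  expect_equal(s$mean, 10 / 3)
  expect_warning(s1 <- empirical_summary(dat, 9), "single record")
  expect_true(is.na(s1$variance))
  expect_error(empirical_summary(dat, 50), "no records")
})

test_that("the seeded ensemble matches the exact law at histogram
           resolution", {
  emp <- layerwalk:::empirical_distribution(fig2_ensemble(), 100)
  de <- fig2_exact_dist()
  cmp <- compare_distributions(de, emp, bins = 25)
  expect_lte(cmp$total_variation, 0.03)
  ## a mis-specified homogeneous walk is clearly distinguishable
  wrong <- exit_time_distribution(
    layered_geometry(c(0, 30, 60, 100), c(0.3, 0.3, 0.3)), 100)
  expect_gt(compare_distributions(de, wrong, bins = 25)$total_variation,
            0.03)
})
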