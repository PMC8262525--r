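test_that("first moment matches the quadrature route on the reference geometry", {
  g <- fig2_geometry()
  expect_equal(first_moment(g, 100), 20250)
  expect_equal(first_moment(g, 100), quadrature_mean(g, 100),
               tolerance = 1e-10)
  expect_equal(first_moment(g, 0), 0)
})

test_that("homogeneous closed forms hold for arbitrary L and D", {
  for (cfg in list(c(10, 0.5), c(70, 0.2), c(33, 0.41))) {
    L <- cfg[1]; h <- cfg[2]
    g <- layered_geometry(c(0, L), h)
    expect_equal(first_moment(g, L), L^2 / (2 * h), tolerance = 1e-12)
    expect_equal(raw_moment(g, L, 2), (5 / 12) * L^4 / h^2,
                 tolerance = 1e-10)
    mv <- mean_variance(g, L)
    expect_equal(mv[["mean"]], L^2 / (2 * h), tolerance = 1e-12)
    expect_equal(mv[["var"]], L^4 / (6 * h^2), tolerance = 1e-10)
    ## shape universality: T^2 / V = 3/2 independent of L, D
    expect_equal(mv[["mean"]]^2 / mv[["var"]], 1.5, tolerance = 1e-10)
  }
})

test_that("zeroth moment is identically one", {
  set.seed(21)
  g <- random_geometry()
  x <- runif(5, 0, g$L)
  expect_equal(raw_moment(g, x, 0), rep(1, 5))
})

test_that("BVP and closed-form first moments agree on random geometries", {
  set.seed(31)
  for (rep in 1:100) {
    g <- random_geometry()
    x <- c(runif(2, 0.01, g$L), g$L, g$interfaces[-1])
    expect_equal(raw_moment(g, x, 1), first_moment(g, x),
                 tolerance = 1e-10)
  }
})

test_that("first moment matches quadrature on random geometries, interior x", {
  set.seed(41)
  for (rep in 1:30) {
    g <- random_geometry()
    for (x in c(runif(2, 0.01, g$L), g$L)) {
      expect_equal(first_moment(g, x), quadrature_mean(g, x),
                   tolerance = 1e-8)
    }
  }
})

test_that("moments and fluxes are continuous at every interface", {
  set.seed(51)
  for (rep in 1:20) {
    g <- random_geometry(max_layers = 4)
    if (g$m < 2) next
    sol <- moment_solution(g, 2)
    D <- g$hop_rates
    for (n in 1:2) {
      ps <- sol$polys[[n + 1]]
      for (i in seq_len(g$m - 1)) {
        left_val <- layerwalk:::poly_eval(ps[[i]], g$lengths[i])
        right_val <- layerwalk:::poly_eval(ps[[i + 1]], 0)
        scale <- max(abs(left_val), 1)
        expect_lt(abs(left_val - right_val) / scale, 1e-9)
        lf <- D[i] * layerwalk:::poly_eval(layerwalk:::poly_deriv(ps[[i]]),
                                           g$lengths[i])
        rf <- D[i + 1] *
          layerwalk:::poly_eval(layerwalk:::poly_deriv(ps[[i + 1]]), 0)
        expect_lt(abs(lf - rf) / max(abs(lf), 1), 1e-9)
      }
    }
  }
})

test_that("equal-rate multilayer moments collapse to the single layer", {
  g3 <- layered_geometry(c(0, 12, 30, 50), c(0.3, 0.3, 0.3))
  g1 <- layered_geometry(c(0, 50), 0.3)
  for (x in c(5, 12, 27.5, 50)) {
    expect_equal(raw_moment(g3, x, 1), raw_moment(g1, x, 1),
                 tolerance = 1e-10)
    expect_equal(raw_moment(g3, x, 2), raw_moment(g1, x, 2),
                 tolerance = 1e-10)
  }
})

test_that("mean exit time is monotone in release point and in rates", {
  g <- fig2_geometry()
  x <- seq(1, 100, by = 1)
  expect_true(all(diff(first_moment(g, x)) > 0))
  for (j in 1:3) {
    h_lo <- h_hi <- c(0.2, 0.3, 0.4)
    h_hi[j] <- h_hi[j] + 0.05
    expect_gt(first_moment(layered_geometry(c(0, 30, 60, 100), h_lo), 100),
              first_moment(layered_geometry(c(0, 30, 60, 100), h_hi), 100))
  }
})

test_that("continuum moments track the Markov chain up to the O(1/L)
           lattice correction", {
  for (g in list(fig2_geometry(), two_layer_geometry())) {
    cm <- chain_moments(g, g$L)
    mv <- mean_variance(g, g$L)
    expect_lt(abs(mv[["mean"]] - cm[["mean"]]) / cm[["mean"]], 0.015)
    expect_lt(abs(mv[["var"]] - cm[["var"]]) / cm[["var"]], 0.03)
  }
  ## the correction shrinks with domain size at fixed rates
  small <- layered_geometry(c(0, 20), 0.3)
  large <- layered_geometry(c(0, 80), 0.3)
  err <- function(g) {
    cm <- chain_moments(g, g$L)
    abs(mean_variance(g, g$L)[["mean"]] - cm[["mean"]]) / cm[["mean"]]
  }
  expect_lt(err(large), err(small))
})

test_that("degenerate evaluation points are rejected", {
  g <- fig2_geometry()
  expect_error(mean_variance(g, 0), "degenerate")
  expect_error(first_moment(g, -1))
  expect_error(first_moment(g, 101))
})
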