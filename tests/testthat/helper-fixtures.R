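## Shared fixtures. Heavy objects (large simulated ensembles, exact pmfs)
## are computed lazily once per test run and cached in this environment.

fig2_geometry <- function() layered_geometry(c(0, 30, 60, 100), c(0.2, 0.3, 0.4))
two_layer_geometry <- function() layered_geometry(c(0, 30, 70), c(0.2, 0.4))

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

## 1e4-draw seeded ensemble on the three-layer reference geometry, S = 100
fig2_ensemble <- function() fixture("fig2_ensemble",
  simulate_exit_times(fig2_geometry(),
                      data.frame(release = 100, count = 10000), seed = 42))

## exact pmf for the same configuration
fig2_exact_dist <- function() fixture("fig2_exact_dist",
  exit_time_distribution(fig2_geometry(), 100))

## Random valid geometry for property-style loops (uses the current RNG).
random_geometry <- function(max_layers = 4, L_max = 60) {
  m <- sample.int(max_layers, 1)
  L <- sample(seq(2 * m, L_max), 1)
  inner <- if (m > 1) sort(sample(seq_len(L - 1), m - 1)) else integer(0)
  layered_geometry(c(0, inner, L), runif(m, 0.05, 0.5))
}

## Quadrature route for the continuum mean exit time, independent of the
## package's closed form and BVP solver: T(x) = int_0^x (L - s) / D(s) ds.
quadrature_mean <- function(geom, x) {
  L <- geom$L
  D <- geom$hop_rates
  tot <- 0
  for (i in seq_len(geom$m)) {
    lo <- geom$interfaces[i]
    hi <- min(geom$interfaces[i + 1], x)
    if (hi > lo)
      tot <- tot + stats::integrate(function(s) (L - s) / D[i], lo, hi,
                                    rel.tol = 1e-12)$value
    if (x <= geom$interfaces[i + 1]) break
  }
  tot
}
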