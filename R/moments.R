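## Continuum-limit exit-time moments for layered media.
##
## The n-th raw moment M_n(x) of the exit time for a particle released at
## continuous position x satisfies, layer by layer,
##     D_i M_n''(x) = -n M_{n-1}(x),   M_0 = 1,
## with absorbing condition M_n(0) = 0, reflecting condition M_n'(L) = 0,
## and continuity of M_n and of the flux D M_n' at every interface. Within
## layer i, M_n is a polynomial of degree 2n; the 2m free constants per
## order are fixed by one dense 2m x 2m linear solve.

## Polynomials as ascending coefficient vectors in the layer-local
## coordinate u = x - x_{i-1} (keeps high powers well-conditioned).
poly_eval <- function(p, u) {
  s <- 0
  for (k in rev(seq_along(p))) s <- s * u + p[k]
  s
}
poly_deriv <- function(p) if (length(p) <= 1) 0 else p[-1] * seq_len(length(p) - 1)
poly_antideriv <- function(p) c(0, p / seq_along(p))

## Solve one moment order given the previous order's per-layer polynomials.
solve_moment_order <- function(geom, prev, n) {
  m <- geom$m
  D <- diffusivities(geom)
  ell <- geom$lengths
  ## particular solution: double antiderivative of -n * prev / D_i
  part <- lapply(seq_len(m), function(i)
    poly_antideriv(poly_antideriv(-n * prev[[i]] / D[i])))
  ## unknowns alpha_i (constant) and beta_i (linear) per layer, interleaved
  ai <- function(i) 2L * i - 1L
  bi <- function(i) 2L * i
  A <- matrix(0, 2 * m, 2 * m)
  rhs <- numeric(2 * m)
  r <- 1L
  A[r, ai(1)] <- 1; rhs[r] <- -poly_eval(part[[1]], 0); r <- r + 1L
  if (m > 1) for (i in seq_len(m - 1)) {
    A[r, ai(i)] <- 1; A[r, bi(i)] <- ell[i]; A[r, ai(i + 1)] <- -1
    rhs[r] <- poly_eval(part[[i + 1]], 0) - poly_eval(part[[i]], ell[i])
    r <- r + 1L
    A[r, bi(i)] <- D[i]; A[r, bi(i + 1)] <- -D[i + 1]
    rhs[r] <- D[i + 1] * poly_eval(poly_deriv(part[[i + 1]]), 0) -
      D[i] * poly_eval(poly_deriv(part[[i]]), ell[i])
    r <- r + 1L
  }
  A[r, bi(m)] <- 1
  rhs[r] <- -poly_eval(poly_deriv(part[[m]]), ell[m])
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("internal error: singular moment assembly system", call. = FALSE))
  lapply(seq_len(m), function(i) {
    p <- part[[i]]
    p[1] <- p[1] + sol[ai(i)]
    p[2] <- p[2] + sol[bi(i)]
    p
  })
}

#' Continuum exit-time moment solution
#'
#' Solve the recursive boundary-value problems for the continuum-limit raw
#' moments of exit time up to order `n_max`, returning the per-layer
#' polynomial representation together with an evaluator.
#'
#' @inheritParams hop_probabilities
#' @param n_max Highest moment order (default 2; orders above 2 are
#'   supported but not used by the Gamma approximation).
#' @return Object of class `"moment_solution"`: list with `polys` (for each
#'   order `n`, a list of per-layer ascending coefficient vectors in the
#'   layer-local coordinate) and the geometry. Use [raw_moment()] /
#'   [mean_variance()] for evaluation.
#' @export
moment_solution <- function(geom, n_max = 2) {
  require_rates(geom)
  n_max <- as.integer(n_max)
  stopifnot(n_max >= 0)
  polys <- vector("list", n_max + 1L)
  polys[[1]] <- lapply(seq_len(geom$m), function(i) 1)  # M_0 = 1
  if (n_max >= 1) for (n in seq_len(n_max))
    polys[[n + 1L]] <- solve_moment_order(geom, polys[[n]], n)
  structure(list(polys = polys, geometry = geom, n_max = n_max),
            class = "moment_solution")
}

## Evaluate order-n moment of a moment_solution at positions x.
eval_moment <- function(sol, x, n) {
  geom <- sol$geometry
  ps <- sol$polys[[n + 1L]]
  vapply(x, function(xx) {
    if (xx == 0 && n >= 1) return(0)
    i <- layer_index(geom, xx)
    poly_eval(ps[[i]], xx - geom$interfaces[i])
  }, numeric(1))
}

#' Raw continuum moments of exit time
#'
#' `raw_moment()` evaluates the `n`-th raw moment `M_n(x)` by solving the
#' moment boundary-value problems; `first_moment()` evaluates the closed
#' form for `M_1(x)` (piecewise quadratic with layer cross terms), an
#' independent route to the same quantity.
#'
#' @inheritParams hop_probabilities
#' @param x Release position(s) in `[0, L]` (treated as continuous).
#' @param n Moment order, non-negative integer.
#' @return Numeric vector of moment values.
#' @examples
#' geom <- layered_geometry(c(0, 30, 60, 100), c(0.2, 0.3, 0.4))
#' first_moment(geom, 100)                      # 20250
#' raw_moment(geom, 100, 1)                     # same, via the BVP solve
#' @export
raw_moment <- function(geom, x, n) {
  require_rates(geom)
  n <- as.integer(n)
  stopifnot(n >= 0)
  if (any(x < 0) || any(x > geom$L))
    stop(sprintf("release position must lie in [0, %d]", geom$L), call. = FALSE)
  eval_moment(moment_solution(geom, n), x, n)
}

#' @rdname raw_moment
#' @export
first_moment <- function(geom, x) {
  require_rates(geom)
  if (any(x < 0) || any(x > geom$L))
    stop(sprintf("release position must lie in [0, %d]", geom$L), call. = FALSE)
  D <- diffusivities(geom)
  ell <- geom$lengths
  m <- geom$m
  L <- geom$L
  vapply(x, function(xx) {
    if (xx == 0) return(0)
    i <- layer_index(geom, xx)
    s <- xx * (2 * L - xx) / (2 * D[i])
    if (i >= 2) for (k in seq_len(i - 1)) {
      dk <- 1 / D[k] - 1 / D[i]
      s <- s + ell[k]^2 / 2 * dk
      if (k + 1 <= m) s <- s + ell[k] * sum(ell[(k + 1):m]) * dk
    }
    s
  }, numeric(1))
}

#' Continuum mean and variance of exit time
#'
#' `T(x) = M_1(x)` and `V(x) = M_2(x) - M_1(x)^2` from the continuum moment
#' boundary-value problems; the inputs to the moment-matched Gamma
#' approximation.
#'
#' @inheritParams raw_moment
#' @return Named vector `c(mean, var)` (both strictly positive for
#'   `0 < x <= L`).
#' @export
mean_variance <- function(geom, x) {
  require_rates(geom)
  if (length(x) != 1L || x <= 0 || x > geom$L)
    stop(sprintf("release position must lie in (0, %d] (variance is degenerate at 0)",
                 geom$L), call. = FALSE)
  sol <- moment_solution(geom, 2)
  m1 <- eval_moment(sol, x, 1)
  m2 <- eval_moment(sol, x, 2)
  c(mean = m1, var = m2 - m1^2)
}
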