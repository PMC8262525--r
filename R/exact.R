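#' Transition matrix of the absorbing walk
#'
#' The `(L + 1) x (L + 1)` row-stochastic tridiagonal transition matrix of
#' the walk over positions `0..L`, with position 0 absorbing and
#' accumulating (`P[1, 1] = 1`) and position `L` reflecting.
#'
#' @inheritParams hop_probabilities
#' @return A dense matrix with dimnames giving the lattice positions.
#' @examples
#' transition_matrix(layered_geometry(c(0, 2), 0.5))
#' @export
transition_matrix <- function(geom) {
  hv <- hop_vectors(require_rates(geom))
  n <- geom$L + 1L
  P <- matrix(0, n, n, dimnames = list(0:geom$L, 0:geom$L))
  diag(P) <- hv$stay
  for (j in 2:n) P[j, j - 1L] <- hv$left[j]
  for (j in seq_len(n - 1L)[-1]) P[j, j + 1L] <- hv$right[j]
  if (n >= 2) P[1, ] <- c(1, rep(0, n - 1L))
  P
}

## Spectral decomposition of the transient block Q (positions 1..L).
## Under the unbiased interface rule Q is symmetric tridiagonal, so the
## eigendecomposition is exact and stable. Survival from release S is
## 1' Q^t e_S = sum_j c_j lambda_j^t with c_j = (sum_k U_kj) U_Sj.
exit_spectrum <- function(geom) {
  hv <- hop_vectors(require_rates(geom))
  L <- geom$L
  left <- hv$left[-1L]; right <- hv$right[-1L]   # positions 1..L
  Q <- matrix(0, L, L)
  diag(Q) <- 1 - left - right
  if (L >= 2) {
    for (x in 2:L) Q[x, x - 1L] <- left[x]
    for (x in 1:(L - 1L)) Q[x, x + 1L] <- right[x]
  }
  e <- eigen(Q, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, colsum = colSums(e$vectors),
       L = L)
}

## lambda^t for integer t >= 0, elementwise over a vector of eigenvalues in
## (-1, 1). Returns a length(t) x length(lambda) matrix; handles lambda <= 0.
lambda_pow <- function(lambda, t) {
  la <- abs(lambda)
  logla <- ifelse(la > 0, log(la), -Inf)
  M <- exp(outer(t, logla))
  if (any(t == 0)) M[t == 0, ] <- 1       # 0^0 = 1 convention
  neg <- lambda < 0
  if (any(neg)) M[, neg] <- M[, neg] * (-1)^(t %% 2)
  M
}

## Survival probability P(T > t) from release S at integer times t.
spectral_survival <- function(spec, S, t) {
  cj <- spec$colsum * spec$vectors[S, ]
  as.vector(lambda_pow(spec$values, t) %*% cj)
}

## Exact pmf f(t) = F(t) - F(t-1) = survival(t-1) - survival(t)
##              = sum_j c_j lambda_j^(t-1) (1 - lambda_j), t >= 1.
spectral_pmf <- function(spec, S, t) {
  w <- spec$colsum * spec$vectors[S, ] * (1 - spec$values)
  f <- as.vector(lambda_pow(spec$values, t - 1) %*% w)
  pmax(f, 0)
}

## Smallest t with F(t) >= coverage, found by geometric growth. Returns the
## hard cap (with ok = FALSE) if coverage is never reached.
spectral_t_coverage <- function(spec, S, coverage = 1 - 1e-8,
                                hard_cap = 1e7) {
  t <- 16
  while (spectral_survival(spec, S, t) > 1 - coverage && t < hard_cap)
    t <- t * 2
  if (t >= hard_cap) return(list(t_max = as.integer(hard_cap), ok = FALSE))
  lo <- t %/% 2; hi <- t
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (spectral_survival(spec, S, mid) > 1 - coverage) lo <- mid else hi <- mid
  }
  list(t_max = as.integer(hi), ok = TRUE)
}

#' Exit-time distribution
#'
#' The distribution of the first-exit time for a walker released at `S`:
#' either the exact law of the absorbing Markov chain (`kind = "exact"`,
#' computed by eigendecomposition of the transient block) or the
#' moment-matched Gamma approximation (`kind = "approximate"`, integer
#' interval masses of the fitted Gamma law).
#'
#' @inheritParams hop_probabilities
#' @param S Release position in `(0, L]`.
#' @param t_max Truncation time. `NULL` (default) grows `t_max` until the
#'   cumulative mass reaches `coverage`; if a supplied `t_max` leaves
#'   `F(t_max) < coverage` the result carries `coverage_ok = FALSE` and a
#'   warning is issued.
#' @param kind `"exact"` or `"approximate"`.
#' @param coverage Target cumulative mass for automatic truncation
#'   (default `1 - 1e-8`).
#' @return An object of class `"exit_time_distribution"` with fields `t`,
#'   `f`, `F`, `release`, `kind`, `t_max`, `coverage_ok`.
#' @examples
#' geom <- layered_geometry(c(0, 10), 0.5)
#' d <- exit_time_distribution(geom, S = 10)
#' head(as.data.frame(d))
#' @export
exit_time_distribution <- function(geom, S, t_max = NULL,
                                   kind = c("exact", "approximate"),
                                   coverage = 1 - 1e-8) {
  kind <- match.arg(kind)
  require_rates(geom)
  S <- as.integer(S)
  if (S < 1L || S > geom$L)
    stop(sprintf("release position must lie in (0, %d]", geom$L), call. = FALSE)
  if (kind == "approximate")
    return(approx_exit_time_distribution(geom, S, t_max, coverage))
  spec <- exit_spectrum(geom)
  if (is.null(t_max)) {
    tc <- spectral_t_coverage(spec, S, coverage)
    t_max <- tc$t_max
    ok <- tc$ok
  } else {
    t_max <- as.integer(t_max)
    if (t_max < 1L) stop("`t_max` must be at least 1", call. = FALSE)
    ok <- spectral_survival(spec, S, t_max) <= 1 - coverage
  }
  ## survival in chunks to bound the size of the power matrix
  surv <- numeric(t_max + 1L)
  cj <- spec$colsum * spec$vectors[S, ]
  tt <- 0:t_max
  for (i in seq(1, length(tt), by = 20000L)) {
    j <- min(i + 19999L, length(tt))
    surv[i:j] <- as.vector(lambda_pow(spec$values, tt[i:j]) %*% cj)
  }
  F <- pmin(pmax(1 - surv, 0), 1)
  F <- cummax(F)
  f <- c(0, pmax(diff(F), 0))
  if (!ok)
    warning(sprintf("F(t_max) = %.6f < target coverage %.8f; tail truncated",
                    F[length(F)], coverage), call. = FALSE)
  new_exit_time_distribution(S, f = f, F = F, kind = "exact",
                             coverage_ok = ok)
}

#' Exact log probability of a single exit time
#'
#' `log f_e(t | theta)` for the absorbing Markov chain. Zero mass (including
#' `t = 0` and floating-point underflow deep in the tail) yields `-Inf`
#' with attribute `underflow = TRUE`, never an error.
#'
#' Spectral decompositions are cached per geometry within a session, so
#' repeated calls with the same geometry are cheap.
#'
#' @inheritParams exit_time_distribution
#' @param t Integer exit time(s), `>= 0`.
#' @return Numeric vector of log probabilities.
#' @export
exact_log_pmf <- function(geom, S, t) {
  require_rates(geom)
  if (any(t < 0) || any(abs(t - round(t)) > 1e-8))
    stop("`t` must contain non-negative integers", call. = FALSE)
  t <- as.integer(round(t))
  spec <- cached_spectrum(geom)
  out <- rep(-Inf, length(t))
  pos <- t >= 1L
  if (any(pos)) out[pos] <- log(spectral_pmf(spec, S, t[pos]))
  if (any(!is.finite(out))) attr(out, "underflow") <- TRUE
  out
}

## Session cache of spectral decompositions keyed on the geometry.
.spectrum_cache <- new.env(parent = emptyenv())
cached_spectrum <- function(geom) {
  key <- paste(c(geom$interfaces, signif(geom$hop_rates, 15)), collapse = "|")
  sp <- .spectrum_cache[[key]]
  if (is.null(sp)) {
    sp <- exit_spectrum(geom)
    ## keep the cache small: drop everything when it grows past a few entries
    if (length(ls(.spectrum_cache)) > 32)
      rm(list = ls(.spectrum_cache), envir = .spectrum_cache)
    .spectrum_cache[[key]] <- sp
  }
  sp
}

#' Exit-time moments from the fundamental matrix
#'
#' Mean and variance of the exact exit-time law obtained from the linear
#' solves `(I - Q) m1 = 1` and `(I - Q) m2 = 1 + 2 Q m1` on the transient
#' block, independent of the spectral pmf route.
#'
#' @inheritParams exit_time_distribution
#' @return Named vector `c(mean, var)`.
#' @export
chain_moments <- function(geom, S) {
  hv <- hop_vectors(require_rates(geom))
  L <- geom$L
  left <- hv$left[-1L]; right <- hv$right[-1L]
  Q <- matrix(0, L, L)
  diag(Q) <- 1 - left - right
  if (L >= 2) {
    for (x in 2:L) Q[x, x - 1L] <- left[x]
    for (x in 1:(L - 1L)) Q[x, x + 1L] <- right[x]
  }
  A <- diag(L) - Q
  m1 <- solve(A, rep(1, L))
  m2 <- solve(A, 1 + 2 * drop(Q %*% m1))
  c(mean = m1[S], var = m2[S] - m1[S]^2)
}
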