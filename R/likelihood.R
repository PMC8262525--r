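#' Exit-time log-likelihood
#'
#' Log-likelihood of the hop rates `theta` given an exit-time dataset,
#' pooled over all release positions. `likelihood = "exact"` uses the
#' absorbing Markov-chain pmf; `"approx"` uses the moment-matched Gamma
#' law (see [approx_log_pmf()] for the `approx_mode` discretization
#' choice). Observations with zero model mass contribute `-Inf` (flagged
#' via attribute `underflow`), never an error, so optimizers can recover.
#'
#' @param theta Hop-rate vector, one entry per layer of `template`.
#' @param data Exit-time data frame with columns `release_position`,
#'   `exit_time`.
#' @param template A [layered_geometry()] (rates, if any, are ignored: the
#'   interface layout is taken from it and `theta` supplies the rates).
#' @param likelihood `"exact"` or `"approx"`.
#' @param approx_mode Gamma discretization, `"density"` or `"interval"`.
#' @return Scalar log-likelihood.
#' @examples
#' geom <- layered_geometry(c(0, 30, 70), c(0.2, 0.4))
#' dat <- simulate_exit_times(geom, data.frame(release = 70, count = 30),
#'                            seed = 1)
#' exit_loglik(c(0.2, 0.4), dat, geom) > exit_loglik(c(0.4, 0.2), dat, geom)
#' @export
exit_loglik <- function(theta, data, template,
                        likelihood = c("exact", "approx"),
                        approx_mode = c("density", "interval")) {
  likelihood <- match.arg(likelihood)
  approx_mode <- match.arg(approx_mode)
  fn <- make_loglik(data, template, likelihood, approx_mode)
  fn(theta)
}

## Build a fast theta -> log-likelihood closure with the per-site exit-time
## tables precomputed. Each site stores unique times and their counts; the
## exact route shares one spectral decomposition across sites per theta.
make_loglik <- function(data, template,
                        likelihood = c("exact", "approx"),
                        approx_mode = "density") {
  likelihood <- match.arg(likelihood)
  if (nrow(data) == 0) stop("dataset is empty", call. = FALSE)
  if (any(data$exit_time < 1))
    stop("exit times must be >= 1", call. = FALSE)
  if (any(data$release_position < 1) ||
      any(data$release_position > template$L))
    stop(sprintf("release positions must lie in (0, %d]", template$L),
         call. = FALSE)
  sites <- lapply(split(data$exit_time, data$release_position), function(tt) {
    tab <- table(tt)
    list(t = as.integer(names(tab)), count = as.numeric(tab))
  })
  S_vals <- as.integer(names(sites))
  m <- template$m

  check_theta <- function(theta) {
    if (length(theta) != m)
      stop(sprintf("theta must have %d components", m), call. = FALSE)
    all(is.finite(theta)) && all(theta > 0) && all(theta <= 0.5)
  }

  if (likelihood == "exact") {
    function(theta) {
      if (!check_theta(theta)) return(-Inf)
      geom <- with_rates(template, theta)
      spec <- exit_spectrum(geom)
      ll <- 0
      for (k in seq_along(sites)) {
        f <- spectral_pmf(spec, S_vals[k], sites[[k]]$t)
        lf <- log(f)
        ll <- ll + sum(sites[[k]]$count * lf)
      }
      out <- ll
      if (!is.finite(out)) {
        out <- -Inf
        attr(out, "underflow") <- TRUE
      }
      out
    }
  } else {
    function(theta) {
      if (!check_theta(theta)) return(-Inf)
      geom <- with_rates(template, theta)
      ll <- 0
      for (k in seq_along(sites)) {
        gp <- gamma_parameters(geom, S_vals[k])
        ll <- ll + sum(sites[[k]]$count *
                         gamma_log_pmf(gp, sites[[k]]$t, approx_mode))
      }
      out <- ll
      if (!is.finite(out)) {
        out <- -Inf
        attr(out, "underflow") <- TRUE
      }
      out
    }
  }
}

#' Normalized log-likelihood
#'
#' `loglik(theta) - l_max`, the log-likelihood relative to its maximum;
#' non-positive by construction, and zero at the maximum-likelihood
#' estimate.
#'
#' @param loglik Function `theta -> scalar` log-likelihood.
#' @param theta Parameter vector.
#' @param l_max Maximized log-likelihood (see [maximize_loglik()]).
#' @return Scalar `<= 0` up to optimizer tolerance.
#' @export
normalized_loglik <- function(loglik, theta, l_max) {
  as.numeric(loglik(theta)) - l_max
}
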