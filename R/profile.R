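#' Chi-squared profile likelihood threshold
#'
#' Normalized log-likelihood threshold for an approximate `level`
#' confidence set: minus half the `level` quantile of the chi-squared
#' distribution with `df` degrees of freedom. At the 95% level this is
#' -1.92 for univariate (`df = 1`) and -3.00 for bivariate (`df = 2`)
#' profiles (2 d.p.).
#'
#' @param df Degrees of freedom (number of interest parameters).
#' @param level Confidence level.
#' @return Negative scalar threshold.
#' @export
chisq_threshold <- function(df = 1, level = 0.95) {
  -stats::qchisq(level, df = df) / 2
}

## Linear interpolation of the psi where v crosses thr between two grid pts.
interp_crossing <- function(p1, p2, v1, v2, thr) {
  p1 + (thr - v1) * (p2 - p1) / (v2 - v1)
}

## All intervals {psi : v >= thr} from a profile curve, with censoring flags
## where the profile is still above the threshold at a grid end.
profile_intervals <- function(psi, v, thr) {
  above <- v >= thr
  if (!any(above))
    stop("internal error: profile entirely below threshold", call. = FALSE)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i1 <- starts[k]; i2 <- ends[k]
    if (i1 == 1L) {
      lo <- psi[1]; lo_cens <- TRUE
    } else {
      lo <- interp_crossing(psi[i1 - 1L], psi[i1], v[i1 - 1L], v[i1], thr)
      lo_cens <- FALSE
    }
    if (i2 == length(psi)) {
      hi <- psi[length(psi)]; hi_cens <- TRUE
    } else {
      hi <- interp_crossing(psi[i2], psi[i2 + 1L], v[i2], v[i2 + 1L], thr)
      hi_cens <- FALSE
    }
    out[[length(out) + 1L]] <- data.frame(
      lower = lo, upper = hi,
      lower_censored = lo_cens, upper_censored = hi_cens)
  }
  do.call(rbind, out)
}

## Optimize the nuisance parameters out at one fixed interest value.
optimize_nuisance <- function(loglik, psi_idx, psi_val, nu_start,
                              lower, upper) {
  nu_idx <- setdiff(seq_along(lower), psi_idx)
  assemble <- function(lam) {
    th <- numeric(length(lower))
    th[psi_idx] <- psi_val
    th[nu_idx] <- lam
    th
  }
  if (length(nu_idx) == 0L)
    return(list(value = as.numeric(loglik(assemble(numeric(0)))),
                nuisance = numeric(0), ok = TRUE))
  neg <- function(lam) {
    v <- as.numeric(loglik(assemble(lam)))
    if (!is.finite(v)) 1e12 else -v
  }
  res <- tryCatch(
    stats::optim(pmin(pmax(nu_start, lower[nu_idx]), upper[nu_idx]), neg,
                 method = "L-BFGS-B",
                 lower = lower[nu_idx], upper = upper[nu_idx],
                 control = list(factr = 1e7)),
    error = function(e) NULL)
  if (is.null(res))
    return(list(value = NA_real_, nuisance = nu_start, ok = FALSE))
  list(value = -res$value, nuisance = res$par, ok = TRUE)
}

#' Univariate profile likelihoods
#'
#' For each requested component of `theta`, evaluates the profile
#' log-likelihood over a uniform grid: at each fixed interest value the
#' remaining (nuisance) rates are optimized out, warm-starting each grid
#' point from its already-profiled neighbour, sweeping outward from the
#' maximum-likelihood estimate in both directions. Profiles are normalized
#' by the maximized log-likelihood, so the maximum is 0.
#'
#' @param fitted An [exit_fit()] object.
#' @param which Integer indices (or `h`-names) of the parameters to
#'   profile; default all.
#' @param grid_size Number of grid points (default 40).
#' @param grid_range Interest-parameter interval; default the fit bounds.
#' @param ... Unused.
#' @return Object of class `"profile_exit_fit"`: per-parameter data frames
#'   with columns `psi`, `loglik` (normalized), the optimized nuisance
#'   values, and an `ok` flag; plus the MLE and normalization constant.
#'   Methods: `print`, `plot`, [confint.profile_exit_fit()].
#' @export
profile.exit_fit <- function(fitted, which = NULL, grid_size = 40,
                             grid_range = NULL, ...) {
  m <- length(fitted$coefficients)
  if (is.null(which)) which <- seq_len(m)
  if (is.character(which)) which <- match(which, names(fitted$coefficients))
  lower <- fitted$bounds["lower", ]
  upper <- fitted$bounds["upper", ]
  ll <- fitted$loglik_fn
  l_max <- fitted$logLik
  profiles <- list()
  for (j in which) {
    rng <- if (is.null(grid_range)) c(lower[j], upper[j]) else grid_range
    psi <- seq(rng[1], rng[2], length.out = grid_size)
    i0 <- which.min(abs(psi - fitted$coefficients[j]))
    raw <- rep(NA_real_, grid_size)
    ok <- rep(TRUE, grid_size)
    nuis <- matrix(NA_real_, grid_size, m - 1L)
    sweep_dir <- function(idx, raw, ok, nuis) {
      start <- fitted$coefficients[-j]
      for (i in idx) {
        r <- optimize_nuisance(ll, j, psi[i], start, lower, upper)
        raw[i] <- r$value; ok[i] <- r$ok
        if (m > 1) nuis[i, ] <- r$nuisance
        if (r$ok && length(r$nuisance)) start <- r$nuisance
      }
      list(raw = raw, ok = ok, nuis = nuis)
    }
    up <- sweep_dir(i0:grid_size, raw, ok, nuis)
    res <- sweep_dir(rev(seq_len(max(i0 - 1L, 1L))), up$raw, up$ok, up$nuis)
    raw <- res$raw; ok <- res$ok; nuis <- res$nuis
    df <- data.frame(psi = psi, raw = raw, ok = ok)
    if (m > 1) {
      nn <- names(fitted$coefficients)[-j]
      colnames(nuis) <- nn
      df <- cbind(df, nuis)
    }
    profiles[[names(fitted$coefficients)[j]]] <- df
  }
  ## renormalize if profiling found a better optimum than the global fit
  best <- max(vapply(profiles, function(d) max(d$raw, na.rm = TRUE),
                     numeric(1)))
  improved <- best > l_max + 1e-6
  l_norm <- max(l_max, best)
  for (k in seq_along(profiles))
    profiles[[k]]$loglik <- profiles[[k]]$raw - l_norm
  structure(list(profiles = profiles, mle = fitted$coefficients,
                 l_max = l_norm, improved = improved,
                 likelihood = fitted$likelihood),
            class = "profile_exit_fit")
}

#' @export
print.profile_exit_fit <- function(x, ...) {
  cat(sprintf("Profile likelihoods (%s likelihood) for: %s\n",
              x$likelihood, paste(names(x$profiles), collapse = ", ")))
  ci <- confint(x)
  print(ci)
  invisible(x)
}

#' @export
plot.profile_exit_fit <- function(x, level = 0.95, ...) {
  np <- length(x$profiles)
  old <- graphics::par(mfrow = c(1, np)); on.exit(graphics::par(old))
  thr <- chisq_threshold(1, level)
  for (nm in names(x$profiles)) {
    d <- x$profiles[[nm]]
    plot(d$psi, d$loglik, type = "l", xlab = nm,
         ylab = "normalized profile log-likelihood",
         ylim = c(min(thr - 1, min(d$loglik, na.rm = TRUE)), 0), ...)
    graphics::abline(h = thr, lty = 2)
    graphics::abline(v = x$mle[nm], col = "grey60")
  }
  invisible(x)
}

#' Profile-likelihood confidence intervals
#'
#' Intervals `{psi : profile >= threshold}` with the crossing points found
#' by linear interpolation on the profile grid. Where the profile is still
#' above the threshold at a parameter bound the interval endpoint is the
#' bound and the corresponding `*_censored` flag is set (the signature of
#' one-sided practical identifiability). Profiles with multiple crossings
#' report every interval via the `"intervals"` attribute; the returned row
#' is the interval containing the estimate.
#'
#' @param object A `"profile_exit_fit"` object.
#' @param parm Subset of profiled parameters (names); default all.
#' @param level Confidence level (default 0.95, threshold -1.92).
#' @param ... Unused.
#' @return Data frame with columns `estimate`, `lower`, `upper`,
#'   `lower_censored`, `upper_censored`; one row per parameter.
#' @export
confint.profile_exit_fit <- function(object, parm = NULL, level = 0.95,
                                     ...) {
  thr <- chisq_threshold(1, level)
  nms <- if (is.null(parm)) names(object$profiles) else parm
  rows <- lapply(nms, function(nm) {
    d <- object$profiles[[nm]]
    iv <- profile_intervals(d$psi, d$loglik, thr)
    est <- object$mle[nm]
    hit <- which(iv$lower - 1e-9 <= est & est <= iv$upper + 1e-9)
    main <- iv[if (length(hit)) hit[1] else which.max(iv$upper - iv$lower), ]
    cbind(data.frame(parameter = nm, estimate = unname(est)), main,
          row.names = NULL)
  })
  out <- do.call(rbind, rows)
  all_iv <- lapply(nms, function(nm) {
    d <- object$profiles[[nm]]
    profile_intervals(d$psi, d$loglik, thr)
  })
  names(all_iv) <- nms
  attr(out, "intervals") <- all_iv
  attr(out, "threshold") <- thr
  out
}

#' @rdname confint.profile_exit_fit
#' @param object,... For `confint.exit_fit`: the fit; extra arguments are
#'   passed to [profile.exit_fit()].
#' @export
confint.exit_fit <- function(object, parm = NULL, level = 0.95, ...) {
  pr <- profile(object, which = parm, ...)
  confint(pr, level = level)
}

#' Bivariate profile likelihood
#'
#' Normalized profile log-likelihood for a pair of interest parameters on
#' a uniform 2-D grid (default 20 x 20), optimizing out the remaining
#' rates at every grid cell with warm starts propagated from neighbouring
#' cells outward from the MLE. The approximate 95% confidence region is
#' `{psi : profile >= -3.00}` (chi-squared, 2 df).
#'
#' @inheritParams profile.exit_fit
#' @param pair Two parameter indices (or names).
#' @param grid_size Points per axis.
#' @return Object of class `"profile2d_exit_fit"`: grids `psi1`, `psi2`,
#'   normalized `surface` (matrix, rows index `psi1`), the MLE, and the
#'   2-df threshold. Methods: `print`, `plot` (filled region + contour).
#' @export
profile_pair <- function(fitted, pair = c(1, 2), grid_size = 20,
                         grid_range = NULL) {
  m <- length(fitted$coefficients)
  if (is.character(pair)) pair <- match(pair, names(fitted$coefficients))
  stopifnot(length(pair) == 2, !anyNA(pair))
  lower <- fitted$bounds["lower", ]
  upper <- fitted$bounds["upper", ]
  ll <- fitted$loglik_fn
  rng1 <- if (is.null(grid_range)) c(lower[pair[1]], upper[pair[1]]) else grid_range
  rng2 <- if (is.null(grid_range)) c(lower[pair[2]], upper[pair[2]]) else grid_range
  psi1 <- seq(rng1[1], rng1[2], length.out = grid_size)
  psi2 <- seq(rng2[1], rng2[2], length.out = grid_size)
  nu_idx <- setdiff(seq_len(m), pair)
  raw <- matrix(NA_real_, grid_size, grid_size)
  nu_store <- array(fitted$coefficients[nu_idx],
                    dim = c(grid_size, grid_size, length(nu_idx)))
  eval_cell <- function(i, k, start) {
    th_fix <- function(lam) {
      th <- numeric(m)
      th[pair] <- c(psi1[i], psi2[k])
      th[nu_idx] <- lam
      th
    }
    if (length(nu_idx) == 0L)
      return(list(value = as.numeric(ll(th_fix(numeric(0)))),
                  nuisance = numeric(0)))
    neg <- function(lam) {
      v <- as.numeric(ll(th_fix(lam)))
      if (!is.finite(v)) 1e12 else -v
    }
    res <- tryCatch(
      stats::optim(pmin(pmax(start, lower[nu_idx]), upper[nu_idx]), neg,
                   method = "L-BFGS-B", lower = lower[nu_idx],
                   upper = upper[nu_idx], control = list(factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res)) list(value = NA_real_, nuisance = start)
    else list(value = -res$value, nuisance = res$par)
  }
  i0 <- which.min(abs(psi1 - fitted$coefficients[pair[1]]))
  k0 <- which.min(abs(psi2 - fitted$coefficients[pair[2]]))
  row_order <- c(i0:grid_size, rev(seq_len(max(i0 - 1L, 1L))))
  row_order <- unique(row_order)
  for (i in row_order) {
    ## warm start for the row's pivot cell: from the previously done row
    col_order <- unique(c(k0:grid_size, rev(seq_len(max(k0 - 1L, 1L)))))
    for (k in col_order) {
      start <- if (length(nu_idx)) {
        if (k == k0 && !is.na(raw[ifelse(i > i0, i - 1L,
                                         min(i + 1L, grid_size)), k]))
          nu_store[ifelse(i > i0, i - 1L, min(i + 1L, grid_size)), k, ]
        else if (k > k0) nu_store[i, k - 1L, ]
        else if (k < k0) nu_store[i, k + 1L, ]
        else fitted$coefficients[nu_idx]
      } else numeric(0)
      r <- eval_cell(i, k, start)
      raw[i, k] <- r$value
      if (length(nu_idx)) nu_store[i, k, ] <- r$nuisance
    }
  }
  l_norm <- max(fitted$logLik, max(raw, na.rm = TRUE))
  structure(list(psi1 = psi1, psi2 = psi2,
                 pair = names(fitted$coefficients)[pair],
                 surface = raw - l_norm,
                 mle = fitted$coefficients,
                 l_max = l_norm,
                 threshold = chisq_threshold(2),
                 likelihood = fitted$likelihood),
            class = "profile2d_exit_fit")
}

#' @export
print.profile2d_exit_fit <- function(x, ...) {
  inside <- x$surface >= x$threshold
  cat(sprintf("Bivariate profile for (%s, %s), %s likelihood\n",
              x$pair[1], x$pair[2], x$likelihood))
  cat(sprintf("  %d x %d grid; %d cells inside the 95%% region (threshold %.2f)\n",
              length(x$psi1), length(x$psi2), sum(inside), x$threshold))
  invisible(x)
}

#' @export
plot.profile2d_exit_fit <- function(x, ...) {
  graphics::image(x$psi1, x$psi2, x$surface >= x$threshold,
                  col = c("white", "grey80"),
                  xlab = x$pair[1], ylab = x$pair[2], ...)
  graphics::contour(x$psi1, x$psi2, x$surface, levels = x$threshold,
                    add = TRUE)
  graphics::points(x$mle[x$pair[1]], x$mle[x$pair[2]], pch = 19)
  invisible(x)
}
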