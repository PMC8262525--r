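## Exit-time distribution container shared by the exact, Gamma-approximate,
## empirical and reduced-model routes.

new_exit_time_distribution <- function(release, f = NULL, F = NULL,
                                       kind = c("exact", "approximate",
                                                "empirical", "reduced"),
                                       coverage_ok = TRUE) {
  kind <- match.arg(kind)
  if (is.null(f) && is.null(F)) stop("need f or F")
  if (is.null(F)) F <- cumsum(f)
  if (is.null(f)) f <- c(F[1], diff(F))
  f <- pmax(f, 0)
  structure(list(release = release,
                 t = seq_along(f) - 1L,
                 f = f, F = F,
                 t_max = length(f) - 1L,
                 kind = kind,
                 coverage_ok = coverage_ok),
            class = "exit_time_distribution")
}

#' @export
print.exit_time_distribution <- function(x, ...) {
  mv <- distribution_moments(x)
  cat(sprintf("Exit-time distribution (%s), release position %s\n",
              x$kind, format(x$release)))
  cat(sprintf("  support 0..%d, F(t_max) = %.8f%s\n", x$t_max,
              x$F[length(x$F)],
              if (x$coverage_ok) "" else "  [warning: truncated tail]"))
  cat(sprintf("  mean = %.4g, variance = %.4g\n", mv[["mean"]], mv[["var"]]))
  invisible(x)
}

#' @export
as.data.frame.exit_time_distribution <- function(x, ...) {
  data.frame(t = x$t, F = x$F, f = x$f)
}

## Mean and variance of the (possibly truncated) pmf.
distribution_moments <- function(dist) {
  m1 <- sum(dist$t * dist$f)
  m2 <- sum(dist$t^2 * dist$f)
  c(mean = m1, var = m2 - m1^2)
}
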