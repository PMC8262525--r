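#' Partial homogenization: reduced geometry template
#'
#' Merge adjacent layers by keeping only a subset of the interfaces,
#' producing a geometry template with one free effective rate per merged
#' layer. Refitting such a reduced model to data generated by the full
#' model is the model-reduction route to identifiable effective transport
#' coefficients when the full per-layer rates are not identifiable.
#'
#' @param full A [layered_geometry()] or template (the full model).
#' @param keep Interface positions to retain; must be a subset of the full
#'   model's interfaces and include both `0` and `L`.
#' @return A geometry template (hop rates free) with `length(keep) - 1`
#'   layers.
#' @examples
#' full <- layered_geometry(c(0, 30, 60, 100), c(0.2, 0.3, 0.4))
#' reduce_geometry(full, c(0, 30, 100))  # two-layer effective model
#' @export
reduce_geometry <- function(full, keep) {
  keep <- sort(as.integer(keep))
  if (!all(keep %in% full$interfaces))
    stop("`keep` must be a subset of the full model's interfaces",
         call. = FALSE)
  if (!all(c(0L, full$L) %in% keep))
    stop("`keep` must include both domain ends (0 and L)", call. = FALSE)
  if (length(keep) < 2L)
    stop("at least two interfaces must be kept", call. = FALSE)
  layered_geometry(keep, NULL, spacing = full$spacing,
                   time_step = full$time_step)
}

#' Fit a reduced (partially homogenized) model
#'
#' Fits the effective rates `H = (H_1, ..., H_m')` of a reduced model to
#' exit-time data, typically data generated by (or observed from) a system
#' with more layers. Release positions interior to a merged layer are
#' allowed: the reduced model evaluates its likelihood at any lattice
#' release position.
#'
#' @inheritParams exit_fit
#' @param full The full-model geometry or template.
#' @param keep Interfaces retained in the reduced model (see
#'   [reduce_geometry()]).
#' @param ... Passed on to [exit_fit()].
#' @return An [exit_fit()] object (subclass `"reduced_exit_fit"`) whose
#'   template is the reduced geometry; carries `full_template` and `keep`.
#' @export
fit_reduced <- function(data, full, keep,
                        likelihood = c("exact", "approx"), ...) {
  reduced <- reduce_geometry(full, keep)
  fit <- exit_fit(data, reduced, likelihood = likelihood, ...)
  names(fit$coefficients) <- sub("^h", "H", names(fit$coefficients))
  fit$full_template <- full
  fit$keep <- keep
  class(fit) <- c("reduced_exit_fit", class(fit))
  fit
}

#' Compare two exit-time distributions
#'
#' Quantifies the agreement of two exit-time distributions over their
#' common integer support: total variation distance (the primary,
#' parameter-free metric), sup-norm of the pmf difference, and the
#' differences in mean and variance.
#'
#' When one distribution is an empirical histogram from finitely many
#' draws, per-integer total variation is dominated by sampling noise on a
#' wide support (most integers receive zero or one draw). Passing `bins`
#' compares at histogram resolution instead: the support is cut into
#' `bins` equal-mass bins of `dist_a`'s CDF and the total variation is
#' computed over the binned masses.
#'
#' @param dist_a,dist_b [exit_time_distribution()] objects (any kind).
#' @param bins Optional number of equal-mass bins (of `dist_a`) for the
#'   total variation; `NULL` compares per integer time.
#' @return List with `total_variation`, `sup_norm`, `mean_diff`,
#'   `var_diff`, `t_max` (common truncation), and `same_release`. A
#'   mismatch in release positions is flagged with a warning but the
#'   comparison is still computed.
#' @export
compare_distributions <- function(dist_a, dist_b, bins = NULL) {
  same_release <- identical(dist_a$release, dist_b$release)
  if (!same_release)
    warning("comparing distributions with different release positions",
            call. = FALSE)
  t_max <- min(dist_a$t_max, dist_b$t_max)
  fa <- dist_a$f[seq_len(t_max + 1L)]
  fb <- dist_b$f[seq_len(t_max + 1L)]
  ma <- distribution_moments(dist_a)
  mb <- distribution_moments(dist_b)
  tv <- if (is.null(bins)) {
    0.5 * sum(abs(fa - fb))
  } else {
    Fa <- cumsum(fa)
    cuts <- vapply(seq_len(bins - 1) / bins,
                   function(q) which(Fa >= q * Fa[length(Fa)])[1],
                   integer(1))
    grp <- findInterval(seq_along(fa), unique(cuts))
    0.5 * sum(abs(tapply(fa, grp, sum) - tapply(fb, grp, sum)))
  }
  list(total_variation = tv,
       sup_norm = max(abs(fa - fb)),
       mean_diff = unname(ma["mean"] - mb["mean"]),
       var_diff = unname(ma["var"] - mb["var"]),
       t_max = t_max,
       same_release = same_release)
}
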