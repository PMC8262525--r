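#' Simulate first-exit times of the layered random walk
#'
#' Draw seeded stochastic realizations of the walk: particles are released
#' at the positions given by `design` and stepped (left / right / stay, per
#' [hop_probabilities()]) until they reach the absorbing boundary at 0. The
#' recorded exit time is the index of the step during which absorption
#' occurs, so exit times are integers `>= 1`.
#'
#' @param geom A [layered_geometry()] with rates.
#' @param design Experimental design: a data frame with columns `release`
#'   (lattice positions in `(0, L]`) and `count` (particles per position,
#'   `>= 1`), or a single release position (then `count` gives the ensemble
#'   size).
#' @param seed Master seed passed to [set.seed()]. `NULL` leaves the RNG
#'   state untouched.
#' @param count Ensemble size when `design` is a bare release position.
#' @param step_cap Hard per-particle cap on steps; exceeding it raises an
#'   error rather than looping forever. Default `1e9`.
#'
#' @return A data frame of class `"exit_time_data"` with integer columns
#'   `release_position` and `exit_time`, one row per particle, and
#'   attributes `seed` and `geometry`.
#'
#' @examples
#' geom <- layered_geometry(c(0, 30, 70), c(0.2, 0.4))
#' dat <- simulate_exit_times(geom, data.frame(release = c(30, 70),
#'                                             count = c(50, 50)), seed = 1)
#' empirical_summary(dat, 70)
#' @export
simulate_exit_times <- function(geom, design, seed = NULL, count = 1L,
                                step_cap = 1e9) {
  require_rates(geom)
  if (!is.data.frame(design)) {
    design <- data.frame(release = as.integer(design),
                         count = rep_len(as.integer(count), length(design)))
  }
  if (!all(c("release", "count") %in% names(design)))
    stop("`design` needs columns `release` and `count`", call. = FALSE)
  if (any(design$count < 1L))
    stop("each design entry needs `count` >= 1", call. = FALSE)
  if (any(design$release < 1L) || any(design$release > geom$L))
    stop(sprintf("release positions must lie in (0, %d]; position 0 is already absorbed",
                 geom$L), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  hv <- hop_vectors(geom)
  release <- rep(as.integer(design$release), design$count)
  times <- walk_exit_times(hv$left, hv$right, release, step_cap)
  structure(
    data.frame(release_position = release, exit_time = times),
    seed = seed, geometry = geom, class = c("exit_time_data", "data.frame")
  )
}

#' @rdname simulate_exit_times
#' @param S Release position for a single walker.
#' @return `simulate_exit_time()` returns a single integer exit time.
#' @export
simulate_exit_time <- function(geom, S, seed = NULL, step_cap = 1e9) {
  simulate_exit_times(geom, S, seed = seed, count = 1L,
                      step_cap = step_cap)$exit_time
}

#' Empirical exit-time summary
#'
#' Normalized histogram (empirical pmf), sample mean and unbiased sample
#' variance of the exit times recorded at one release position.
#'
#' @param data An exit-time data frame (see [simulate_exit_times()] or
#'   [read_exit_times()]).
#' @param release_position Release position to summarize.
#' @return A list with `pmf` (named numeric vector over observed integer
#'   times), `mean`, `variance` (`NA` with a warning for a single record),
#'   and `n`.
#' @export
empirical_summary <- function(data, release_position) {
  t_obs <- data$exit_time[data$release_position == release_position]
  if (length(t_obs) == 0)
    stop(sprintf("no records at release position %s", release_position),
         call. = FALSE)
  tab <- table(t_obs)
  pmf <- as.numeric(tab) / length(t_obs)
  names(pmf) <- names(tab)
  v <- if (length(t_obs) < 2) {
    warning("variance undefined for a single record", call. = FALSE)
    NA_real_
  } else {
    stats::var(t_obs)
  }
  list(pmf = pmf, mean = mean(t_obs), variance = v, n = length(t_obs))
}

## Empirical exit-time distribution as an exit_time_distribution object.
empirical_distribution <- function(data, release_position,
                                   t_max = NULL) {
  s <- empirical_summary(data, release_position)
  tt <- as.integer(names(s$pmf))
  if (is.null(t_max)) t_max <- max(tt)
  f <- numeric(t_max + 1)
  keep <- tt <= t_max
  f[tt[keep] + 1L] <- s$pmf[keep]
  new_exit_time_distribution(as.integer(release_position), f = f,
                             kind = "empirical")
}
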