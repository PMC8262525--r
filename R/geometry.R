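#' Layered lattice geometry
#'
#' Construct the geometry of a one-dimensional medium partitioned into `m`
#' layers on the lattice `0, 1, ..., L`. Layer `i` occupies the interval
#' between interfaces `interfaces[i]` and `interfaces[i + 1]` and carries a
#' per-step hopping probability `hop_rates[i]`. Position 0 is an absorbing
#' boundary; position `L` is reflecting (right hops from `L` are aborted).
#'
#' At a position strictly inside layer `i` a walker hops left with
#' probability `h_i`, right with probability `h_i`, and stays put with
#' probability `1 - 2 h_i`. At an interior interface between layers `i` and
#' `i + 1` it hops left with probability `h_i`, right with probability
#' `h_{i+1}`, and stays with probability `1 - h_i - h_{i+1}`.
#'
#' `hop_rates` may be `NULL`, in which case the object is a geometry
#' *template*: the interface layout is fixed but the rates are free
#' parameters, as used by [exit_fit()] and [reduce_geometry()].
#'
#' @param interfaces Strictly increasing integer positions
#'   `0 = x0 < x1 < ... < xm = L` of the layer interfaces, including both
#'   domain ends.
#' @param hop_rates Numeric vector of `m` per-layer hopping probabilities,
#'   each in `(0, 0.5]`, or `NULL` for a template.
#' @param spacing Lattice spacing `Delta` (default 1).
#' @param time_step Step duration `tau` (default 1).
#'
#' @return An object of class `"layered_geometry"`: a list with elements
#'   `interfaces`, `hop_rates`, `m` (number of layers), `L` (domain length),
#'   `lengths` (layer lengths), `n_sites` (`L + 1`), `spacing`, `time_step`.
#'
#' @examples
#' geom <- layered_geometry(c(0, 30, 60, 100), c(0.2, 0.3, 0.4))
#' geom
#' diffusivity(geom, 1)
#' @seealso [hop_probabilities()], [diffusivity()], [exit_fit()]
#' @export
layered_geometry <- function(interfaces, hop_rates = NULL,
                             spacing = 1, time_step = 1) {
  if (length(interfaces) < 2)
    stop("`interfaces` must contain at least the two domain ends", call. = FALSE)
  if (any(!is.finite(interfaces)))
    stop("`interfaces` must be finite", call. = FALSE)
  if (any(abs(interfaces - round(interfaces)) > 1e-8))
    stop("every interface must coincide with a lattice site (integer position)",
         call. = FALSE)
  interfaces <- as.integer(round(interfaces))
  if (interfaces[1] != 0L)
    stop("the first interface must be the absorbing boundary at 0", call. = FALSE)
  if (any(diff(interfaces) < 1L))
    stop("`interfaces` must be strictly increasing", call. = FALSE)
  m <- length(interfaces) - 1L
  if (!is.null(hop_rates)) {
    if (length(hop_rates) != m)
      stop(sprintf("expected %d hop rates for %d layers, got %d",
                   m, m, length(hop_rates)), call. = FALSE)
    if (any(!is.finite(hop_rates)) || any(hop_rates <= 0))
      stop("hop rates must be strictly positive", call. = FALSE)
    if (any(hop_rates > 0.5))
      stop("hop rates must not exceed 0.5", call. = FALSE)
    hop_rates <- as.numeric(hop_rates)
  }
  stopifnot(spacing > 0, time_step > 0)
  structure(list(
    interfaces = interfaces,
    hop_rates  = hop_rates,
    m          = m,
    L          = interfaces[m + 1L],
    lengths    = diff(interfaces),
    n_sites    = interfaces[m + 1L] + 1L,
    spacing    = spacing,
    time_step  = time_step
  ), class = "layered_geometry")
}

#' @export
print.layered_geometry <- function(x, ...) {
  cat(sprintf("Layered lattice geometry: %d layer%s on [0, %d] (%d sites)\n",
              x$m, if (x$m > 1) "s" else "", x$L, x$n_sites))
  cat("  interfaces:", paste(x$interfaces, collapse = ", "), "\n")
  if (is.null(x$hop_rates)) {
    cat("  hop rates:  free (template)\n")
  } else {
    cat("  hop rates: ", paste(format(x$hop_rates), collapse = ", "), "\n")
  }
  invisible(x)
}

## TRUE when the geometry carries numeric rates (not a template)
has_rates <- function(geom) !is.null(geom$hop_rates)

require_rates <- function(geom) {
  if (!has_rates(geom))
    stop("geometry template has free hop rates; supply `hop_rates`", call. = FALSE)
  geom
}

## Substitute rates into a geometry/template.
with_rates <- function(geom, hop_rates) {
  layered_geometry(geom$interfaces, hop_rates,
                   spacing = geom$spacing, time_step = geom$time_step)
}

## Layer index for a position x in (0, L]: i such that x in (x_{i-1}, x_i].
## x = 0 returns 1 (the absorbing end belongs to the first layer's closure).
layer_index <- function(geom, x) {
  pmax(1L, findInterval(x, geom$interfaces, left.open = TRUE))
}

#' Per-position hop probabilities
#'
#' The probabilities of hopping left, hopping right, and staying put during
#' one time step, for a walker at a given lattice position. Position 0 is
#' absorbing (no outgoing hops); position `L` is reflecting, so the right
#' hop is aborted and its probability mass is added to staying.
#'
#' @param geom A [layered_geometry()] with rates.
#' @param position Integer lattice position in `0:L`.
#' @return Named numeric vector `c(left, right, stay)` summing to 1, with
#'   attribute `absorbing = TRUE` at position 0.
#' @examples
#' geom <- layered_geometry(c(0, 30, 60, 100), c(0.2, 0.3, 0.4))
#' hop_probabilities(geom, 15)   # interior of layer 1
#' hop_probabilities(geom, 30)   # interface between layers 1 and 2
#' hop_probabilities(geom, 100)  # reflecting end
#' @export
hop_probabilities <- function(geom, position) {
  require_rates(geom)
  if (length(position) != 1L || !is.finite(position) ||
      abs(position - round(position)) > 1e-8)
    stop("`position` must be a single integer lattice position", call. = FALSE)
  position <- as.integer(round(position))
  if (position < 0L || position > geom$L)
    stop(sprintf("position %d is off the lattice [0, %d]", position, geom$L),
         call. = FALSE)
  hv <- hop_vectors(geom)
  out <- c(left = hv$left[position + 1L], right = hv$right[position + 1L],
           stay = hv$stay[position + 1L])
  if (position == 0L) attr(out, "absorbing") <- TRUE
  out
}

## Vectors of left/right/stay probabilities over positions 0..L
## (element j corresponds to position j - 1).
hop_vectors <- function(geom) {
  require_rates(geom)
  L <- geom$L
  h <- geom$hop_rates
  pos <- 0:L
  lay <- layer_index(geom, pos)
  left  <- h[lay]
  right <- h[lay]
  ## interior interfaces: left rate from the layer below, right from above
  if (geom$m > 1) {
    inner <- geom$interfaces[-c(1L, geom$m + 1L)]
    idx <- inner + 1L
    left[idx]  <- h[match(inner, geom$interfaces) - 1L]
    right[idx] <- h[match(inner, geom$interfaces)]
  }
  right[L + 1L] <- 0          # reflecting: right hop aborted
  left[1L] <- 0               # absorbing: no outgoing hops
  right[1L] <- 0
  list(left = left, right = right, stay = 1 - left - right)
}

#' Macroscopic layer diffusivity
#'
#' The continuum-limit diffusivity of layer `i`,
#' `D_i = h_i * spacing^2 / time_step`. With the default unit lattice and
#' unit time step, `D_i = h_i`.
#'
#' @inheritParams hop_probabilities
#' @param layer Layer index in `1:m`.
#' @return Numeric diffusivity.
#' @export
diffusivity <- function(geom, layer) {
  require_rates(geom)
  if (any(layer < 1L) || any(layer > geom$m))
    stop(sprintf("layer index out of range 1..%d", geom$m), call. = FALSE)
  geom$hop_rates[layer] * geom$spacing^2 / geom$time_step
}

## Per-layer continuum diffusivities as a vector.
diffusivities <- function(geom) {
  require_rates(geom)
  geom$hop_rates * geom$spacing^2 / geom$time_step
}
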