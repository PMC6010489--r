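## Two-dimensional encounter theory for a straight-moving walker that turns
## on contact with substrate micro-cues.
##
## If the number of cues within distance r of the walker scales as
## n(r) = (r/delta)^D, the chance of meeting a cue while traversing an
## annulus [r, r + dr] is the fraction of its circumference occupied by cue
## cross-sections, q(r) dr. Exponentiating the accumulated hazard gives the
## free-path (step-length) density: an exponential when D = 2, a
## generalized stretched exponential for 1 < D < 2, and a pure power law in
## the limit D = 1.

#' Geometry of a micro-cue field
#'
#' @param rho Cue detection radius (m).
#' @param delta Characteristic cue spacing and inner cutoff of the fractal
#'   scaling (m). Cues must not overlap: `rho <= delta / 2`.
#' @param D Fractal dimension of the cue pattern, in (0, 2]. `D = 2` is a
#'   uniform random scatter; `D < 2` is clustering across scales.
#' @return An object of class `cue_geometry`.
#' @export
#' @examples
#' cue_geometry(rho = 0.05, delta = 1, D = 2)
cue_geometry <- function(rho, delta, D) {
  stopifnot(is.numeric(rho), is.numeric(delta), is.numeric(D))
  if (rho <= 0 || delta <= 0) stop("'rho' and 'delta' must be > 0")
  if (D <= 0 || D > 2) stop("'D' must be in (0, 2]")
  if (rho > delta / 2)
    stop("cue overlap violation: need rho <= delta/2")
  structure(list(rho = rho, delta = delta, D = D), class = "cue_geometry")
}

#' @export
print.cue_geometry <- function(x, ...) {
  cat(sprintf("cue field geometry: rho = %g m, delta = %g m, D = %g\n",
              x$rho, x$delta, x$D))
  invisible(x)
}

#' Encounter hazard per unit distance
#'
#' `q(r) = rho * D / (pi * delta^2) * (r / delta)^(D - 2)`: the probability
#' per unit distance of meeting a cue after having travelled freely a
#' distance `r`. Constant in `r` when `D = 2`.
#'
#' @param geom A [cue_geometry()].
#' @param r Distance(s) travelled since the last turn (m).
#' @return Hazard values (1/m).
#' @export
encounter_rate <- function(geom, r) {
  stopifnot(inherits(geom, "cue_geometry"))
  if (any(r < 0)) stop("'r' must be >= 0")
  geom$rho * geom$D / (pi * geom$delta^2) * (r / geom$delta)^(geom$D - 2)
}

## Integral of the hazard from delta to r (the log-survival with sign
## flipped); the D = 1 case is the documented logarithmic limit.
.hazard_integral <- function(geom, r) {
  with(geom, {
    if (D == 1) (rho / (pi * delta)) * log(r / delta)
    else (rho * D / (pi * delta^D)) * (r^(D - 1) - delta^(D - 1)) / (D - 1)
  })
}

#' Free-path (step-length) density of the cue-encounter process
#'
#' The density of the distance travelled freely before the next cue
#' encounter, for paths longer than the inner cutoff `delta`:
#' `p(r) = q(r) * exp(-integral_delta^r q)`. For `D = 2` this is a simple
#' exponential; for `1 < D < 2` its tail is the constrained generalized
#' stretched exponential with `gamma = D - 1`, `mu = D - 2`.
#'
#' @inheritParams encounter_rate
#' @return Density values (1/m); zero for `r < delta`.
#' @export
free_path_pdf <- function(geom, r) {
  stopifnot(inherits(geom, "cue_geometry"))
  out <- numeric(length(r))
  ok <- r >= geom$delta
  out[ok] <- encounter_rate(geom, r[ok]) * exp(-.hazard_integral(geom, r[ok]))
  out
}

#' @rdname free_path_pdf
#' @details `free_path_survival` is the probability that a free path
#'   exceeds `r` (1 for `r <= delta`).
#' @export
free_path_survival <- function(geom, r) {
  stopifnot(inherits(geom, "cue_geometry"))
  out <- rep(1, length(r))
  ok <- r > geom$delta
  out[ok] <- exp(-.hazard_integral(geom, r[ok]))
  out
}

#' Mean free path between cue encounters
#'
#' For a uniform field (`D = 2`) this is the classical two-dimensional
#' collision length `pi * delta^2 / (2 * rho)`; for `D < 2` it is computed
#' by quadrature of the survival function above the inner cutoff.
#'
#' @inheritParams encounter_rate
#' @return Expected free path (m).
#' @export
mean_free_path <- function(geom) {
  stopifnot(inherits(geom, "cue_geometry"))
  if (geom$D == 2) return(pi * geom$delta^2 / (2 * geom$rho))
  tail <- stats::integrate(function(r) free_path_survival(geom, r),
                           geom$delta, Inf, rel.tol = 1e-9)$value
  geom$delta + tail
}
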