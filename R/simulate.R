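## Synthetic-data engine: cue-field generators (uniform Poisson and the
## 3-of-4 quadrant-retention fractal), a box-counting dimension estimator,
## and the automaton walker that travels in straight lines and reorients
## uniformly at random on contact with a cue disc.

.local_seed <- function(seed) {
  if (is.null(seed)) return(invisible())
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  old
}

.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
}

#' A field of substrate micro-cues
#'
#' @param points Two-column matrix of cue centers (m), origin at the
#'   domain center.
#' @param rho Cue detection radius (m); must satisfy `rho <= delta / 2`.
#' @param delta Characteristic spacing / inner fractal cutoff (m).
#' @param D Nominal fractal dimension of the pattern.
#' @param domain Side length of the axis-aligned square domain (m),
#'   centered at the origin.
#' @return An object of class `cue_field`.
#' @export
cue_field <- function(points, rho, delta, D, domain) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, domain > 0, rho > 0, delta > 0)
  if (rho > delta / 2)
    stop("cue overlap violation: need rho <= delta/2")
  half <- domain / 2
  if (nrow(points) > 0 && any(abs(points) > half + 1e-9))
    stop("all cue points must lie inside the domain")
  structure(list(points = points, rho = rho, delta = delta, D = D,
                 domain = domain), class = "cue_field")
}

#' @export
print.cue_field <- function(x, ...) {
  cat(sprintf(
    "cue field: %d cues in %g x %g m, rho = %g m, delta = %g m, D = %g\n",
    nrow(x$points), x$domain, x$domain, x$rho, x$delta, x$D))
  invisible(x)
}

#' Uniform random (Poisson) cue field, D = 2
#'
#' A homogeneous Poisson scatter of cue centers. The characteristic
#' spacing is recorded as `delta = 1 / sqrt(pi * density)`, consistent
#' with the count scaling `n(r) = (r / delta)^D` at `D = 2`.
#'
#' @param density Cues per square meter (> 0).
#' @param domain Square side length (m).
#' @param rho Cue detection radius (m).
#' @param seed Optional integer seed.
#' @return A [cue_field()] with `D = 2`.
#' @export
uniform_field <- function(density, domain = 8, rho, seed = NULL) {
  if (!is.numeric(density) || density <= 0)
    stop("'density' must be > 0")
  expected <- density * domain^2
  if (expected < 10)
    warning("expected cue count below 10; field will be very sparse")
  old <- .local_seed(seed); on.exit(.restore_seed(old))
  n <- stats::rpois(1L, expected)
  half <- domain / 2
  pts <- cbind(stats::runif(n, -half, half), stats::runif(n, -half, half))
  cue_field(pts, rho = rho, delta = 1 / sqrt(pi * density), D = 2,
            domain = domain)
}

## Core retention recursion shared by quadrant_fractal / retention_fractal.
## Cells are (i, j) integer coordinates at each level; with probability
## `keep3_prob` a retained cell keeps a random 3 of its 4 children,
## otherwise all 4. Returns the retained deepest-level cell indices.
.retention_cells <- function(levels, keep3_prob) {
  ci <- 0L; cj <- 0L
  for (lev in seq_len(levels)) {
    np <- length(ci)
    ci <- rep(2L * ci, each = 4L) + c(0L, 1L, 0L, 1L)
    cj <- rep(2L * cj, each = 4L) + c(0L, 0L, 1L, 1L)
    drop3 <- stats::runif(np) < keep3_prob
    dropped <- sample.int(4L, np, replace = TRUE)
    dropped[!drop3] <- 0L
    child <- rep(seq_len(4L), times = np)
    keep <- child != rep(dropped, each = 4L)
    ci <- ci[keep]; cj <- cj[keep]
  }
  cbind(ci, cj)
}

#' Quadrant-retention fractal cue field
#'
#' Recursively keeps a random 3 of 4 sub-quadrants of every retained cell
#' (equivalently, uncovers one random quarter of each covered cell per
#' level). Carried on indefinitely the construction has similarity
#' dimension `log(3)/log(2) ~ 1.585`; three levels reproduce the
#' quasi-fractal experimental surface class with self-similar structure
#' across three spatial scales. Cue points are the centers of the retained
#' deepest-level cells; the retained area fraction is exactly
#' `(3/4)^levels`.
#'
#' @param levels Recursion depth (>= 1).
#' @param domain Square side length (m).
#' @param rho Cue detection radius (m); defaults to a quarter of the
#'   deepest cell size. Must not exceed half the cell size.
#' @param seed Optional integer seed.
#' @return A [cue_field()] with nominal `D = log(3)/log(2)`; `delta` is
#'   the measured mass-radius spacing (the scale for which the cue count
#'   obeys `n(r) = (r/delta)^D`), the deepest cell size — below which the
#'   scaling breaks down — is attached as `attr(, "cutoff")`, and the 0/1
#'   cover mask (`2^levels x 2^levels`) as `attr(, "mask")`.
#' @export
#' @examples
#' f <- quadrant_fractal(3, seed = 1)
#' mean(attr(f, "mask"))  # (3/4)^3
quadrant_fractal <- function(levels, domain = 8, rho = NULL, seed = NULL) {
  retention_fractal(levels, keep3_prob = 1, domain = domain, rho = rho,
                    seed = seed)
}

#' Generalized retention fractal with tunable dimension
#'
#' Each retained cell keeps a random 3 of its 4 children with probability
#' `keep3_prob` and all 4 otherwise, giving similarity dimension
#' `log(4 - keep3_prob) / log(2)` — an interpolation between the 3-of-4
#' quadrant fractal (`keep3_prob = 1`, D ~ 1.585) and the full grid
#' (`keep3_prob = 0`, D = 2) used for parameter-recovery experiments.
#'
#' @inheritParams quadrant_fractal
#' @param keep3_prob Probability in [0, 1] of dropping one child quadrant.
#' @return A [cue_field()]; see [quadrant_fractal()].
#' @export
retention_fractal <- function(levels, keep3_prob, domain = 8, rho = NULL,
                              seed = NULL) {
  stopifnot(levels >= 1, keep3_prob >= 0, keep3_prob <= 1, domain > 0)
  cell <- domain / 2^levels
  if (is.null(rho)) rho <- cell / 10
  if (cell < 2 * rho)
    stop("cue overlap violation: deepest cell size ", signif(cell, 4),
         " m is below 2 * rho")
  old <- .local_seed(seed); on.exit(.restore_seed(old))
  cells <- .retention_cells(levels, keep3_prob)
  half <- domain / 2
  pts <- cbind((cells[, 1L] + 0.5) * cell - half,
               (cells[, 2L] + 0.5) * cell - half)
  mask <- matrix(0L, nrow = 2^levels, ncol = 2^levels)
  mask[cells + 1L] <- 1L
  D <- log(4 - keep3_prob) / log(2)
  ## the characteristic spacing delta is defined by the mass-radius
  ## relation n(r) = (r/delta)^D; for this construction it is smaller
  ## than the cell size because retained cells touch, so measure it
  delta <- .mass_radius_delta(pts, cell, D, domain)
  fld <- cue_field(pts, rho = rho, delta = delta, D = D, domain = domain)
  attr(fld, "mask") <- mask
  attr(fld, "levels") <- levels
  attr(fld, "cutoff") <- cell
  fld
}

## Calibrate delta from the average number of cues within radius r of a
## cue, fitting the intercept of log n(r) = D (log r - log delta) with
## the slope fixed at D, over dyadic radii inside the scaling range.
## Centers are sampled away from the boundary to avoid edge truncation.
.mass_radius_delta <- function(pts, cell, D, domain) {
  n_oct <- 4L
  while (n_oct >= 1L && cell * 2^n_oct > domain / 4) n_oct <- n_oct - 1L
  if (n_oct < 1L || nrow(pts) < 50L) return(cell)
  radii <- cell * 2^seq_len(n_oct)
  half <- domain / 2 - max(radii)
  inner <- which(abs(pts[, 1L]) < half & abs(pts[, 2L]) < half)
  if (length(inner) < 50L) return(cell)
  idx <- if (length(inner) > 400L) sample(inner, 400L) else inner
  counts <- vapply(radii, function(r) {
    mean(vapply(idx, function(i)
      sum((pts[, 1L] - pts[i, 1L])^2 +
          (pts[, 2L] - pts[i, 2L])^2 <= r^2) - 1L, 0L))
  }, 0)
  if (any(counts <= 0)) return(cell)
  exp(mean(log(radii) - log(counts) / D))
}

#' Box-counting fractal dimension of a 2-D point set
#'
#' Counts occupied boxes on dyadic grids and returns the least-squares
#' slope of `log N` against `log(1/s)` over the scaling range. Scales
#' whose counts are saturated (nearly one point per box) or too sparse are
#' excluded automatically unless `scales` is supplied.
#'
#' @param points Two-column matrix of coordinates.
#' @param domain Side length of the bounding square; defaults to the point
#'   extent.
#' @param scales Optional vector of box sizes to use.
#' @return List with elements `D` (the estimate), `table` (box size,
#'   count), and `r_squared` of the log-log fit.
#' @export
box_counting_dimension <- function(points, domain = NULL, scales = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  n <- nrow(points)
  if (n < 100L) stop("need at least 100 points")
  ext <- apply(points, 2L, range)
  span <- max(ext[2L, ] - ext[1L, ])
  if (span == 0) stop("degenerate point set: all points identical")
  if (is.null(domain)) domain <- span
  x0 <- ext[1L, ]
  user_scales <- !is.null(scales)
  if (!user_scales) scales <- domain / 2^(1:14)
  ## clamp the exact upper edge into the last box of each dimension
  tx <- pmin(points[, 1L] - x0[1L], (ext[2L, 1L] - x0[1L]) * (1 - 1e-12))
  ty <- pmin(points[, 2L] - x0[2L], (ext[2L, 2L] - x0[2L]) * (1 - 1e-12))
  counts <- vapply(scales, function(s) {
    length(unique(complex(real = floor(tx / s), imaginary = floor(ty / s))))
  }, 0L)
  ## drop saturated scales (approaching one point per box) and the
  ## coarsest, nearly-single-box end; both flatten the log-log slope
  use <- if (user_scales) rep(TRUE, length(scales)) else
    counts >= 4L & counts <= n / 10
  if (sum(use) < 4L)
    stop("fewer than 4 usable scale octaves for box counting")
  fit <- stats::lm(log(counts[use]) ~ log(1 / scales[use]))
  list(D = unname(stats::coef(fit)[2L]),
       table = data.frame(box_size = scales, n_boxes = counts,
                          used = use),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Configuration of the automaton walker
#'
#' @param start Release point (m), inside the domain.
#' @param heading Initial heading in degrees; `NULL` draws it uniformly.
#' @param boundary `"reflect"` (the heading is mirrored at the domain wall
#'   and the current straight run keeps accumulating length) or `"stop"`
#'   (the simulation ends at the wall).
#' @param max_steps Stop after this many recorded steps (turns).
#' @param max_path Stop once the total path length reaches this (m).
#'   At least one of the two stop rules must be given.
#' @param seed Optional integer seed.
#' @return An object of class `walker_config`.
#' @export
walker_config <- function(start = c(0, 0), heading = NULL,
                          boundary = c("reflect", "stop"),
                          max_steps = NULL, max_path = NULL, seed = NULL) {
  boundary <- match.arg(boundary)
  if (is.null(max_steps) && is.null(max_path))
    stop("provide at least one stop rule ('max_steps' or 'max_path')")
  if (!is.null(max_steps) && max_steps < 1) stop("'max_steps' must be >= 1")
  if (!is.null(max_path) && max_path <= 0) stop("'max_path' must be > 0")
  structure(list(start = as.numeric(start), heading = heading,
                 boundary = boundary, max_steps = max_steps,
                 max_path = max_path, seed = seed),
            class = "walker_config")
}

#' Simulate the cue-driven automaton walker
#'
#' The walker advances along straight lines; at the first intersection of
#' its path with a cue disc (other than the cue that triggered the last
#' turn, which is refractory until left behind) it records the straight
#' distance traveled since the last turn as a step, draws a fresh heading
#' uniformly on the circle, and continues. Fully reproducible for a fixed
#' seed.
#'
#' @param field A [cue_field()]; may be empty only with a `max_path` stop
#'   rule.
#' @param config A [walker_config()].
#' @return List with elements `trajectory` (the polyline of release point
#'   and turn/boundary points), `steps` (numeric vector of recorded step
#'   lengths, m) and `n_turns`.
#' @export
simulate_walker <- function(field, config) {
  stopifnot(inherits(field, "cue_field"), inherits(config, "walker_config"))
  if (nrow(field$points) == 0L && is.null(config$max_path))
    stop("empty cue field never turns: a 'max_path' stop rule is required")
  old <- .local_seed(config$seed); on.exit(.restore_seed(old))
  half <- field$domain / 2
  pos <- config$start
  if (any(abs(pos) > half)) stop("start position outside the domain")
  ang <- if (is.null(config$heading)) stats::runif(1, 0, 360) else
    config$heading
  dir <- c(cos(ang * pi / 180), sin(ang * pi / 180))
  cues <- field$points
  rho2 <- field$rho^2
  path_x <- pos[1L]; path_y <- pos[2L]
  steps <- numeric(0)
  run_len <- 0
  total <- 0
  refractory <- 0L
  max_steps <- if (is.null(config$max_steps)) Inf else config$max_steps
  max_path <- if (is.null(config$max_path)) Inf else config$max_path
  eps <- 1e-12
  repeat {
    ## distance to the nearest wall along the current heading
    tw <- c(if (dir[1L] > eps) (half - pos[1L]) / dir[1L] else Inf,
            if (dir[1L] < -eps) (-half - pos[1L]) / dir[1L] else Inf,
            if (dir[2L] > eps) (half - pos[2L]) / dir[2L] else Inf,
            if (dir[2L] < -eps) (-half - pos[2L]) / dir[2L] else Inf)
    t_wall <- max(min(tw), 0)
    ## first cue-disc entry along the ray within (eps, t_wall]
    t_hit <- Inf; hit <- 0L
    if (nrow(cues) > 0L) {
      relx <- cues[, 1L] - pos[1L]
      rely <- cues[, 2L] - pos[2L]
      proj <- relx * dir[1L] + rely * dir[2L]
      perp2 <- relx^2 + rely^2 - proj^2
      cand <- which(perp2 < rho2 & proj > 0)
      if (refractory > 0L) cand <- cand[cand != refractory]
      if (length(cand)) {
        tt <- proj[cand] - sqrt(pmax(0, rho2 - perp2[cand]))
        ok <- tt > eps & tt <= t_wall
        if (any(ok)) {
          j <- which.min(tt[ok])
          t_hit <- tt[ok][j]
          hit <- cand[ok][j]
        }
      }
    }
    t_move <- min(t_hit, t_wall, max_path - total)
    pos <- pos + t_move * dir
    run_len <- run_len + t_move
    total <- total + t_move
    path_x <- c(path_x, pos[1L]); path_y <- c(path_y, pos[2L])
    if (total >= max_path) break
    if (t_move == t_hit) {
      steps <- c(steps, run_len)
      run_len <- 0
      refractory <- hit
      ang <- stats::runif(1, 0, 360)
      dir <- c(cos(ang * pi / 180), sin(ang * pi / 180))
      if (length(steps) >= max_steps) break
    } else {
      ## wall contact
      if (config$boundary == "stop") break
      if (abs(abs(pos[1L]) - half) < 1e-9) dir[1L] <- -dir[1L]
      if (abs(abs(pos[2L]) - half) < 1e-9) dir[2L] <- -dir[2L]
      refractory <- 0L
    }
  }
  list(trajectory = trajectory(path_x, path_y), steps = steps,
       n_turns = length(steps))
}

#' Build a fitting sample from walker steps
#'
#' Steps shorter than the inner cutoff `delta` — below which the fractal
#' count scaling breaks down — are excluded; the truncation bounds are
#' `[delta, domain diagonal]`, the simulation convention.
#'
#' @param run Output of [simulate_walker()].
#' @param field The [cue_field()] the run was simulated on.
#' @param min_len Exclusion threshold; defaults to the field's scaling
#'   cutoff (the deepest cell size for retention fractals, `delta`
#'   otherwise).
#' @return A [step_sample()].
#' @export
walker_step_sample <- function(run, field, min_len = NULL) {
  if (is.null(min_len)) min_len <- .field_cutoff(field)
  keep <- run$steps[run$steps >= min_len]
  if (length(keep) == 0L) stop("no steps at or above 'min_len'")
  upper <- max(field$domain * sqrt(2), max(keep))
  step_sample(keep, bounds = support_bounds(min_len, upper))
}

.field_cutoff <- function(field) {
  co <- attr(field, "cutoff")
  if (is.null(co)) field$delta else co
}

#' Recovery of the fractal dimension from simulated walks
#'
#' For each seed: generate a cue field of nominal dimension `D_true`
#' (uniform Poisson for `D_true = 2`, a retention fractal otherwise),
#' simulate the walker until `n_steps` steps at or above the inner cutoff
#' are collected, fit the constrained generalized stretched exponential,
#' and record the estimate.
#'
#' @param D_true Nominal dimension in (1, 2]; retention fractals cover
#'   `[log(3)/log(2), 2]`.
#' @param n_steps Steps per seed entering the fit.
#' @param seeds Integer vector of seeds.
#' @param levels Recursion depth of the fractal generator.
#' @param domain Square side length (m).
#' @param rho Cue radius; defaults per generator.
#' @param band Half-width of the recovery band summarized in `coverage`.
#' @return Data frame with one row per seed (`seed`, `D_hat`,
#'   `lambda_hat`, `n_used`); mean, SD and band coverage in
#'   `attr(, "summary")`.
#' @export
recovery_experiment <- function(D_true, n_steps = 500, seeds = 1:20,
                                levels = 8, domain = 8, rho = NULL,
                                band = 0.3) {
  stopifnot(D_true > 1, D_true <= 2)
  rows <- lapply(seeds, function(sd) {
    if (D_true == 2) {
      cell <- domain / 2^levels
      fld <- uniform_field(density = 1 / (pi * cell^2), domain = domain,
                           rho = if (is.null(rho)) cell / 10 else rho,
                           seed = sd)
    } else {
      p <- 4 - 2^D_true
      if (p > 1 + 1e-9)
        stop("retention generator covers D in [log(3)/log(2), 2]")
      fld <- retention_fractal(levels, keep3_prob = min(1, p),
                               domain = domain, rho = rho, seed = sd)
    }
    smp <- .collect_steps(fld, n_steps, seed = sd + 10000L)
    ## estimate on the branch where the encounter theory is defined
    ## (D > 1; below it walkers have a finite escape probability)
    fit <- fit_steplaw(smp, "GSE_CONSTRAINED", D_range = c(1, 3))
    data.frame(seed = sd, D_hat = fit$model$params[["D"]],
               lambda_hat = fit$model$params[["lambda"]],
               n_used = fit$n)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(
    D_true = D_true, mean = mean(out$D_hat), sd = stats::sd(out$D_hat),
    coverage = mean(abs(out$D_hat - D_true) <= band), band = band)
  out
}

## Simulate until n_steps valid (>= delta) steps are available, growing
## the run if the first attempt falls short.
.collect_steps <- function(field, n_steps, seed) {
  cutoff <- .field_cutoff(field)
  mult <- 3L
  for (try in 1:4) {
    run <- simulate_walker(field, walker_config(
      max_steps = n_steps * mult, seed = seed))
    valid <- run$steps[run$steps >= cutoff]
    if (length(valid) >= n_steps) {
      valid <- valid[seq_len(n_steps)]
      upper <- max(field$domain * sqrt(2), max(valid))
      return(step_sample(valid, bounds = support_bounds(cutoff, upper)))
    }
    mult <- mult * 3L
  }
  stop("could not collect ", n_steps, " steps above the inner cutoff")
}
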