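## Conversion of digitized 2-D search trajectories into straight segments.
##
## A vertex starts a new segment when the heading over the next `min_run`
## of path deviates from the direction of the current straight run by more
## than the turn-angle threshold. Measuring the turn run-to-run (rather
## than between adjacent digitization steps) keeps hand-digitization
## jitter, which is far below the threshold, from fragmenting runs, and
## the minimum-run requirement discards on-the-spot turns.

#' A digitized 2-D search trajectory
#'
#' Coordinates are in meters relative to the release point at the origin.
#' Consecutive duplicate points are removed on ingest.
#'
#' @param x,y Ordered coordinates (m).
#' @param id,condition Optional labels.
#' @return An object of class `trajectory` with a two-column matrix
#'   `points`.
#' @export
trajectory <- function(x, y, id = "", condition = "") {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  pts <- cbind(x = as.numeric(x), y = as.numeric(y))
  if (nrow(pts) >= 2L) {
    dup <- c(FALSE, rowSums(abs(diff(pts))) == 0)
    pts <- pts[!dup, , drop = FALSE]
  }
  if (nrow(pts) < 2L) stop("a trajectory needs at least 2 distinct points")
  structure(list(points = pts, id = id, condition = condition),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory%s%s: %d points, path length %.3g m\n",
              if (nzchar(x$id)) paste0(" '", x$id, "'") else "",
              if (nzchar(x$condition)) paste0(" (", x$condition, ")") else "",
              nrow(x$points), sum(sqrt(rowSums(diff(x$points)^2)))))
  invisible(x)
}

## Clip a polyline at the first crossing of `radius` from the origin,
## interpolating the crossing point linearly.
.clip_radius <- function(pts, radius) {
  d <- sqrt(rowSums(pts^2))
  out <- which(d > radius)
  if (length(out) == 0L) return(pts)
  i <- out[1L]
  if (i == 1L) return(pts[1L, , drop = FALSE])
  p0 <- pts[i - 1L, ]; p1 <- pts[i, ]
  ## solve |p0 + t (p1 - p0)| = radius for t in (0, 1]
  v <- p1 - p0
  aa <- sum(v^2); bb <- 2 * sum(p0 * v); cc <- sum(p0^2) - radius^2
  t <- (-bb + sqrt(max(0, bb^2 - 4 * aa * cc))) / (2 * aa)
  rbind(pts[seq_len(i - 1L), , drop = FALSE], p0 + t * v)
}

.angle_between <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  if (cu == 0 || cv == 0) return(0)
  acos(min(1, max(-1, sum(u * v) / (cu * cv)))) * 180 / pi
}

## Point at arc length s along the polyline (s within [0, total]).
.point_at_arclength <- function(pts, cs, s) {
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pts) - 1L)
  seg <- cs[i + 1L] - cs[i]
  t <- if (seg > 0) (s - cs[i]) / seg else 0
  pts[i, ] + t * (pts[i + 1L, ] - pts[i, ])
}

#' Segment a trajectory into straight runs
#'
#' Walks the polyline accumulating a straight run; a new segment starts at
#' a vertex where the turn away from the current run direction is strictly
#' sharper than `angle_threshold` both instantaneously (the outgoing edge)
#' and sustained over the next `min_run` of path — so jitter below the
#' threshold never fragments a run, and on-the-spot turns that revert
#' within `min_run` are ignored. The path is first clipped at `radius_cap`
#' from the origin (crossing found by linear interpolation).
#'
#' @param traj A [trajectory()].
#' @param angle_threshold Turn-angle threshold in degrees (strict `>`).
#' @param min_run Minimum continuation after a turn, in meters.
#' @param radius_cap Analysis radius in meters; `Inf` disables clipping.
#' @param length_type `"arc"` (default) reports the polyline arc length of
#'   each run, counting sub-threshold wiggle as part of the traveled step;
#'   `"chord"` reports the straight-line endpoint distance.
#' @param turn_convention `"run"` (default) additionally requires the
#'   heading over the next `min_run` of path to sustain the turn;
#'   `"vertex"` breaks on the outgoing edge alone.
#' @return An object of class `segment_list`: a data frame with one row
#'   per segment (`seg_index`, `x0`, `y0`, `x1`, `y1`, `length_m`,
#'   `heading_deg`, `turn_deg` — the absolute turn to the next segment, NA
#'   for the last — and `dist_m`, the end-point distance from the origin).
#' @export
#' @examples
#' tr <- trajectory(c(0, 1, 1), c(0, 0, 1))
#' segment_path(tr)
segment_path <- function(traj, angle_threshold = 45, min_run = 0.04,
                         radius_cap = 4,
                         length_type = c("arc", "chord"),
                         turn_convention = c("run", "vertex")) {
  stopifnot(inherits(traj, "trajectory"),
            angle_threshold > 0, min_run > 0, radius_cap > 0)
  length_type <- match.arg(length_type)
  turn_convention <- match.arg(turn_convention)
  pts <- .clip_radius(traj$points, radius_cap)
  if (nrow(pts) < 2L)
    stop("trajectory starts outside the radius cap")
  cs <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- cs[length(cs)]
  n <- nrow(pts)
  if (total < min_run) {
    warning("trajectory shorter than 'min_run'; single degenerate segment")
    breaks <- integer(0)
  } else {
    breaks <- integer(0)
    start <- 1L
    for (i in 2:(n - 1L)) {
      run_dir <- pts[i, ] - pts[start, ]
      if (sum(run_dir^2) == 0) next
      if (total - cs[i] < min_run) break
      edge_dir <- pts[i + 1L, ] - pts[i, ]
      if (sum(edge_dir^2) == 0) next
      sharp <- .angle_between(run_dir, edge_dir) > angle_threshold
      sustained <- if (turn_convention == "run") {
        out_dir <- .point_at_arclength(pts, cs, cs[i] + min_run) - pts[i, ]
        sum(out_dir^2) > 0 &&
          .angle_between(run_dir, out_dir) > angle_threshold
      } else TRUE
      if (sharp && sustained) {
        breaks <- c(breaks, i)
        start <- i
      }
    }
  }
  idx <- c(1L, breaks, n)
  m <- length(idx) - 1L
  seg <- data.frame(
    seg_index = seq_len(m),
    x0 = pts[idx[-length(idx)], 1L], y0 = pts[idx[-length(idx)], 2L],
    x1 = pts[idx[-1L], 1L], y1 = pts[idx[-1L], 2L])
  seg$length_m <- if (length_type == "arc") {
    cs[idx[-1L]] - cs[idx[-length(idx)]]
  } else {
    sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2)
  }
  seg$heading_deg <- atan2(seg$y1 - seg$y0, seg$x1 - seg$x0) * 180 / pi
  seg$turn_deg <- NA_real_
  if (m > 1L) {
    for (j in seq_len(m - 1L)) {
      seg$turn_deg[j] <- .angle_between(
        c(seg$x1[j] - seg$x0[j], seg$y1[j] - seg$y0[j]),
        c(seg$x1[j + 1L] - seg$x0[j + 1L], seg$y1[j + 1L] - seg$y0[j + 1L]))
    }
  }
  seg$dist_m <- sqrt(seg$x1^2 + seg$y1^2)
  structure(seg, class = c("segment_list", "data.frame"),
            id = traj$id, condition = traj$condition,
            length_type = length_type)
}

#' Per-segment metrics table
#'
#' One row per segment, in order: the absolute turn angle to the next
#' segment (degrees, NA for the last), the segment length (m) and the
#' Euclidean distance from the origin to the segment end (m).
#'
#' @param segments A `segment_list` from [segment_path()].
#' @return Data frame with columns `seg_index`, `turn_deg`, `length_m`,
#'   `dist_m`.
#' @export
segment_metrics <- function(segments) {
  stopifnot(inherits(segments, "segment_list"), nrow(segments) >= 1L)
  out <- segments[, c("seg_index", "turn_deg", "length_m", "dist_m")]
  attr(out, "id") <- attr(segments, "id")
  attr(out, "condition") <- attr(segments, "condition")
  class(out) <- "data.frame"
  out
}

#' Mean and confidence interval of the first k segments per condition
#'
#' For each condition, individuals with fewer than `k` segments are
#' excluded (the exclusion count is recorded); for each segment index 1..k
#' and metric, the across-individual mean and a normal-theory t-interval
#' are returned.
#'
#' @param groups Named list: condition -> list of metric tables from
#'   [segment_metrics()], one per individual.
#' @param k Number of leading segments to analyze.
#' @param conf Confidence level for the interval.
#' @return Data frame with columns `condition`, `seg_index`, `metric`,
#'   `mean`, `ci_lo`, `ci_hi`, `n_individuals`; the number of excluded
#'   individuals per condition is in `attr(, "excluded")`.
#' @export
first_k_summary <- function(groups, k = 20, conf = 0.95) {
  stopifnot(is.list(groups), length(groups) >= 1L, k >= 1)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("'groups' must be a named list (condition -> metric tables)")
  metrics <- c("turn_deg", "length_m", "dist_m")
  rows <- list()
  excluded <- integer(0)
  for (cond in names(groups)) {
    tabs <- groups[[cond]]
    keep <- vapply(tabs, function(tb) nrow(tb) >= k, TRUE)
    excluded[cond] <- sum(!keep)
    if (!any(keep))
      stop("no individual with >= ", k, " segments in condition '",
           cond, "'")
    tabs <- tabs[keep]
    for (met in metrics) {
      vals <- vapply(tabs, function(tb) tb[[met]][seq_len(k)],
                     numeric(k))
      vals <- matrix(vals, nrow = k)
      for (i in seq_len(k)) {
        v <- vals[i, ]
        v <- v[is.finite(v)]
        ni <- length(v)
        if (ni == 0L) next
        mu <- mean(v)
        half <- if (ni > 1L) {
          stats::qt(1 - (1 - conf) / 2, ni - 1L) * stats::sd(v) / sqrt(ni)
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, seg_index = i, metric = met, mean = mu,
          ci_lo = mu - half, ci_hi = mu + half, n_individuals = ni)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}
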