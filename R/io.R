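## Readers and writers for the interchange formats: step-length tables,
## trajectory tables, segment tables, cue fields (CSV points with a JSON
## sidecar) and the published per-individual fit summaries used for
## re-analysis.

.check_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("'", path, "' is missing required columns: ",
         paste(miss, collapse = ", "))
}

#' Read per-individual step lengths from CSV
#'
#' Expects columns `id`, `condition`, `length_m`. Rows with missing or
#' non-positive lengths are rejected individually and summarized in a
#' message and in `attr(, "rejected")`.
#'
#' @param path CSV file path.
#' @return Named list of [step_sample()] objects, one per individual.
#' @export
read_step_lengths <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("id", "condition", "length_m"), path)
  bad <- !is.finite(df$length_m) | df$length_m <= 0
  if (any(bad))
    message(sum(bad), " of ", nrow(df),
            " rows rejected (missing or non-positive length)")
  ok <- df[!bad, , drop = FALSE]
  if (nrow(ok) == 0L) stop("no valid step-length rows in ", path)
  out <- lapply(split(ok, ok$id), function(d)
    step_sample(d$length_m, id = as.character(d$id[1L]),
                condition = as.character(d$condition[1L])))
  attr(out, "rejected") <- sum(bad)
  out
}

#' @rdname read_step_lengths
#' @param samples List of [step_sample()] objects.
#' @export
write_step_lengths <- function(samples, path) {
  if (inherits(samples, "step_sample")) samples <- list(samples)
  df <- do.call(rbind, lapply(samples, function(s)
    data.frame(id = s$id, condition = s$condition, length_m = s$lengths)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read digitized trajectories from CSV
#'
#' Expects columns `id`, `condition`, `point_index`, `x_m`, `y_m`; points
#' are ordered by `point_index` within each individual. Rows with
#' non-finite coordinates are rejected with a summary.
#'
#' @param path CSV file path.
#' @return Named list of [trajectory()] objects.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("id", "condition", "point_index", "x_m", "y_m"),
                 path)
  bad <- !is.finite(df$x_m) | !is.finite(df$y_m)
  if (any(bad))
    message(sum(bad), " of ", nrow(df),
            " rows rejected (non-finite coordinates)")
  ok <- df[!bad, , drop = FALSE]
  if (nrow(ok) == 0L) stop("no valid trajectory rows in ", path)
  out <- lapply(split(ok, ok$id), function(d) {
    d <- d[order(d$point_index), , drop = FALSE]
    trajectory(d$x_m, d$y_m, id = as.character(d$id[1L]),
               condition = as.character(d$condition[1L]))
  })
  attr(out, "rejected") <- sum(bad)
  out
}

#' @rdname read_trajectories
#' @param trajectories List of [trajectory()] objects.
#' @export
write_trajectories <- function(trajectories, path) {
  if (inherits(trajectories, "trajectory"))
    trajectories <- list(trajectories)
  df <- do.call(rbind, lapply(trajectories, function(tr)
    data.frame(id = tr$id, condition = tr$condition,
               point_index = seq_len(nrow(tr$points)),
               x_m = tr$points[, 1L], y_m = tr$points[, 2L])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write per-individual segment tables to CSV
#'
#' Columns `id`, `condition`, `seg_index`, `length_m`, `turn_deg`,
#' `dist_m`.
#'
#' @param segment_lists List of `segment_list` objects from
#'   [segment_path()].
#' @param path Output CSV path.
#' @export
write_segments <- function(segment_lists, path) {
  if (inherits(segment_lists, "segment_list"))
    segment_lists <- list(segment_lists)
  df <- do.call(rbind, lapply(segment_lists, function(sg)
    data.frame(id = attr(sg, "id"), condition = attr(sg, "condition"),
               seg_index = sg$seg_index, length_m = sg$length_m,
               turn_deg = sg$turn_deg, dist_m = sg$dist_m)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / read a cue field (CSV points + JSON sidecar)
#'
#' @param field A [cue_field()].
#' @param path CSV path for the cue points; the sidecar is written next to
#'   it as `<path>.json` with `rho`, `delta`, `D` and `domain`.
#' @export
write_cue_field <- function(field, path) {
  stopifnot(inherits(field, "cue_field"))
  utils::write.csv(data.frame(x_m = field$points[, 1L],
                              y_m = field$points[, 2L]),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(rho = field$rho, delta = field$delta, D = field$D,
         domain = field$domain),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cue_field
#' @export
read_cue_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pts <- utils::read.csv(path)
  cue_field(cbind(pts$x_m, pts$y_m), rho = meta$rho, delta = meta$delta,
            D = meta$D, domain = meta$domain)
}

#' Published per-individual fit summaries for desert-ant channel searches
#'
#' Loads the bundled table of previously published maximum-likelihood fit
#' summaries for 23 *Melophorus bagoti* individuals searching in a linear
#' channel: per ant, the number of identified steps, the estimated fractal
#' dimension, the log-likelihoods of the constrained generalized stretched
#' exponential, bi-exponential and unconstrained generalized stretched
#' exponential fits, and the reported pairwise Akaike weights. One
#' individual (ant 13, two steps) was never fitted and carries `NA`s.
#' These printed summaries are re-analysis inputs: the package recomputes
#' the pairwise weights from the log-likelihoods and sample sizes via
#' [pairwise_weight_loglik()].
#'
#' @return Data frame with columns `ant`, `n_steps`, `D_hat`, `logL_gse`,
#'   `logL_biexp`, `logL_free`, `w_vs_biexp`, `w_vs_free`.
#' @export
bagoti_channel_fits <- function() {
  path <- system.file("extdata", "bagoti_channel_fits.tsv",
                      package = "cuewalk", mustWork = TRUE)
  utils::read.delim(path)
}
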