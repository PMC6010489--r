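## End-to-end study pipeline: simulate (or read) -> segment -> fit ->
## compare -> report. Defaults follow the field-standard analysis
## choices: 45 degree turn threshold, 4 cm minimum run, 4 m analysis
## radius, AICc model selection with exact binomial sign testing.

#' Configure an end-to-end study run
#'
#' Exactly one data source must be given: `simulate` (a list of condition
#' specs for the walker simulator), `step_file` (a CSV of step lengths,
#' see [read_step_lengths()]) or `trajectory_file` (a CSV of digitized
#' paths, see [read_trajectories()]; these are segmented first).
#'
#' @param simulate Optional list of condition specs, each a list with
#'   `name`, `field` (`"uniform"` or `"quadrant_fractal"`), `n_ants`,
#'   `n_steps` (steps per individual), and field parameters (`density`,
#'   `rho` for uniform; `levels`, `rho` for the fractal), plus `domain`.
#' @param step_file,trajectory_file Optional input CSV paths.
#' @param models Character vector of family names to fit.
#' @param angle_threshold,min_run,radius_cap Segmentation settings
#'   (degrees, m, m).
#' @param bounds_policy `"data"` (per-sample observed range) or `"delta"`
#'   (`[delta, domain diagonal]`, simulation convention).
#' @param seed Integer seed governing all simulation randomness.
#' @param outdir Optional output directory; when given, [run_study()]
#'   writes the report tables there.
#' @return An object of class `study_config`.
#' @export
study_config <- function(simulate = NULL, step_file = NULL,
                         trajectory_file = NULL,
                         models = c("EXP", "BIEXP", "GSE_CONSTRAINED",
                                    "POWER"),
                         angle_threshold = 45, min_run = 0.04,
                         radius_cap = 4,
                         bounds_policy = c("data", "delta"),
                         seed = 1L, outdir = NULL) {
  sources <- !vapply(list(simulate, step_file, trajectory_file), is.null,
                     TRUE)
  if (sum(sources) != 1L)
    stop("give exactly one of 'simulate', 'step_file', 'trajectory_file'")
  bad <- setdiff(models, .families)
  if (length(bad))
    stop("unknown model name(s): ", paste(bad, collapse = ", "))
  if (length(models) < 2L) stop("need at least two models to compare")
  stopifnot(angle_threshold > 0, min_run > 0, radius_cap > 0)
  bounds_policy <- match.arg(bounds_policy)
  for (f in c(step_file, trajectory_file))
    if (!file.exists(f)) stop("input file not found: ", f)
  if (!is.null(simulate)) {
    for (cs in simulate) {
      if (is.null(cs$name) || is.null(cs$field))
        stop("each simulation condition needs 'name' and 'field'")
      match.arg(cs$field, c("uniform", "quadrant_fractal"))
    }
  }
  structure(list(simulate = simulate, step_file = step_file,
                 trajectory_file = trajectory_file, models = models,
                 angle_threshold = angle_threshold, min_run = min_run,
                 radius_cap = radius_cap, bounds_policy = bounds_policy,
                 seed = as.integer(seed), outdir = outdir),
            class = "study_config")
}

.study_D_range <- function(fam) {
  if (fam == "GSE_CONSTRAINED") c(1, 3) else NULL
}

.sim_condition_field <- function(cs, seed) {
  domain <- if (is.null(cs$domain)) 8 else cs$domain
  if (cs$field == "uniform") {
    density <- if (is.null(cs$density)) 156.25 else cs$density
    rho <- if (is.null(cs$rho)) 1 / sqrt(pi * density) / 10 else cs$rho
    uniform_field(density, domain = domain, rho = rho, seed = seed)
  } else {
    levels <- if (is.null(cs$levels)) 6 else cs$levels
    quadrant_fractal(levels, domain = domain, rho = cs$rho, seed = seed)
  }
}

.acquire_samples <- function(config) {
  if (!is.null(config$step_file))
    return(read_step_lengths(config$step_file))
  if (!is.null(config$trajectory_file)) {
    trajs <- read_trajectories(config$trajectory_file)
    return(lapply(trajs, function(tr) {
      sg <- segment_path(tr, config$angle_threshold, config$min_run,
                         config$radius_cap)
      step_sample(sg$length_m[sg$length_m > 0], id = tr$id,
                  condition = tr$condition)
    }))
  }
  out <- list()
  for (ci in seq_along(config$simulate)) {
    cs <- config$simulate[[ci]]
    n_ants <- if (is.null(cs$n_ants)) 5L else cs$n_ants
    n_steps <- if (is.null(cs$n_steps)) 100L else cs$n_steps
    for (ant in seq_len(n_ants)) {
      seed_i <- config$seed + 1000L * ci + ant
      fld <- .sim_condition_field(cs, seed_i)
      smp <- .collect_steps(fld, n_steps, seed = seed_i + 500L)
      if (config$bounds_policy == "data")
        smp <- step_sample(smp$lengths)
      smp$id <- sprintf("%s_%02d", cs$name, ant)
      smp$condition <- cs$name
      out[[smp$id]] <- smp
    }
  }
  out
}

#' Run a full study
#'
#' Executes the pipeline stages in order — acquire (simulate, read, or
#' segment), per-individual fits, pairwise weights of the constrained
#' generalized stretched exponential against the bi-exponential, the
#' across-individuals sign test, pooled per-condition multi-model
#' comparisons and rank-frequency curves — and optionally writes the
#' report tables. Idempotent for a fixed seed.
#'
#' @param config A [study_config()].
#' @return An object of class `report_bundle`: `individual_fits` (a data
#'   frame mirroring a per-individual fit summary table), `comparisons`
#'   (per-condition multi-model weights), `sign_test`, `rank_frequency`
#'   (per condition), `samples`, `n_unfitted` and `log` (seed, settings,
#'   timings).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res
  }
  samples <- stage("acquire", .acquire_samples(config))
  t1 <- proc.time()[["elapsed"]]

  fit_rows <- list()
  all_fits <- list()
  n_unfitted <- 0L
  for (s in samples) {
    fits <- list()
    err <- NULL
    for (fam in config$models) {
      ## dimension estimates are confined to the branch on which the
      ## encounter theory is defined (published fits floor at D = 1)
      f <- tryCatch(fit_steplaw(s, fam, D_range = .study_D_range(fam)),
                    error = function(e) e)
      if (inherits(f, "error")) { err <- f; break }
      fits[[fam]] <- f
    }
    if (!is.null(err)) {
      n_unfitted <- n_unfitted + 1L
      fit_rows[[s$id]] <- data.frame(
        id = s$id, condition = s$condition, n = length(s$lengths),
        D_hat = NA_real_, stringsAsFactors = FALSE)
      next
    }
    all_fits[[s$id]] <- fits
    D_hat <- if ("GSE_CONSTRAINED" %in% names(fits))
      fits$GSE_CONSTRAINED$model$params[["D"]] else NA_real_
    row <- data.frame(id = s$id, condition = s$condition,
                      n = length(s$lengths), D_hat = D_hat)
    for (fam in names(fits)) {
      row[[paste0("logL_", tolower(fam))]] <- fits[[fam]]$logL
      row[[paste0("aicc_", tolower(fam))]] <- fits[[fam]]$aicc
    }
    if (all(c("GSE_CONSTRAINED", "BIEXP") %in% names(fits)))
      row$w_gse_vs_biexp <- pairwise_weight(fits$GSE_CONSTRAINED,
                                            fits$BIEXP)
    fit_rows[[s$id]] <- row
    ## internal consistency: AICc must recompute from logL, k, n
    for (fam in names(fits)) {
      f <- fits[[fam]]
      stopifnot(abs(f$aicc - aicc(f$logL, f$k, f$n)) < 1e-8)
    }
  }
  individual_fits <- do.call(rbind, c(fit_rows, make.row.names = FALSE))
  t2 <- proc.time()[["elapsed"]]

  st <- NULL
  if ("w_gse_vs_biexp" %in% names(individual_fits)) {
    w <- individual_fits$w_gse_vs_biexp
    w <- w[is.finite(w)]
    if (length(w) > 0L) st <- sign_test(sum(w > 0.5), length(w))
  }

  conds <- unique(vapply(samples, `[[`, "", "condition"))
  comparisons <- list()
  rank_freq <- list()
  for (cond in conds) {
    in_cond <- Filter(function(s) s$condition == cond, samples)
    pooled <- step_sample(unlist(lapply(in_cond, `[[`, "lengths")),
                          id = "pooled", condition = cond)
    fits <- lapply(config$models, function(fam)
      fit_steplaw(pooled, fam, D_range = .study_D_range(fam)))
    cmp <- multi_model_weights(fits)
    stopifnot(abs(sum(cmp$weight) - 1) < 1e-9)
    cmp$condition <- cond
    gse <- which(cmp$family == "GSE_CONSTRAINED")
    cmp$D_hat <- if (length(gse))
      fits[[gse]]$model$params[["D"]] else NA_real_
    comparisons[[cond]] <- cmp
    rank_freq[[cond]] <- rank_frequency(pooled)
  }
  t3 <- proc.time()[["elapsed"]]

  bundle <- structure(list(
    individual_fits = individual_fits,
    comparisons = do.call(rbind, c(comparisons, make.row.names = FALSE)),
    sign_test = st, rank_frequency = rank_freq, samples = samples,
    n_unfitted = n_unfitted,
    log = list(seed = config$seed, models = config$models,
               bounds_policy = config$bounds_policy,
               package_version = as.character(utils::packageVersion(
                 "cuewalk")),
               timing_s = c(acquire = t1 - t0, fit = t2 - t1,
                            compare = t3 - t2))),
    class = "report_bundle")
  if (!is.null(config$outdir)) write_report(bundle, config$outdir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("study report bundle\n")
  cat(sprintf("  individuals fitted: %d (unfitted: %d)\n",
              sum(!is.na(x$individual_fits$D_hat)), x$n_unfitted))
  cat("  per-condition comparisons:\n")
  print(x$comparisons[, c("condition", "family", "weight", "D_hat")])
  if (!is.null(x$sign_test))
    cat(sprintf("  sign test: %d/%d with weight > 0.5, p = %.4g\n",
                x$sign_test$statistic, x$sign_test$parameter,
                x$sign_test$p.value))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes `individual_fits.tsv`, `comparisons.tsv`, per-condition
#' rank-frequency CSVs and `run_log.json` into `outdir`.
#'
#' @param bundle A `report_bundle` from [run_study()].
#' @param outdir Output directory (created if absent).
#' @export
write_report <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bundle$individual_fits,
                     file.path(outdir, "individual_fits.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$comparisons,
                     file.path(outdir, "comparisons.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (cond in names(bundle$rank_frequency))
    utils::write.csv(bundle$rank_frequency[[cond]],
                     file.path(outdir,
                               paste0("rank_frequency_", cond, ".csv")),
                     row.names = FALSE)
  log <- bundle$log
  if (!is.null(bundle$sign_test))
    log$sign_test_p <- bundle$sign_test$p.value
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
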