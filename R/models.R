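## Step-length distribution families on a truncated support.
##
## All families share the generalized stretched exponential (GSE) kernel
##   k(l) = exp(-(lambda * l)^gamma) * l^mu
## except the bi-exponential, which is a two-component mixture of truncated
## exponentials. The constrained GSE ties the shape to a single fractal
## dimension D of the substrate micro-cue pattern: gamma = D - 1, mu = D - 2,
## so D = 2 collapses to a simple exponential and D = 1 to a pure power law.

.families <- c("EXP", "BIEXP", "STRETCHED", "GSE_CONSTRAINED", "GSE_FREE",
               "POWER")

.family_k <- c(EXP = 1L, BIEXP = 3L, STRETCHED = 2L, GSE_CONSTRAINED = 2L,
               GSE_FREE = 3L, POWER = 1L)

#' Truncation bounds for a step-length support
#'
#' Every density in the package lives on a finite-or-half-infinite interval
#' `[lower, upper]`; evaluations outside it are zero (log-density `-Inf`).
#'
#' @param lower Lower truncation point in meters, strictly positive.
#' @param upper Upper truncation point in meters, greater than `lower`;
#'   `Inf` is accepted where the kernel decays fast enough to be integrable.
#' @return An object of class `support_bounds`.
#' @export
#' @examples
#' support_bounds(0.1, 10)
support_bounds <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L)
  if (!is.finite(lower) || lower <= 0)
    stop("'lower' must be finite and > 0")
  if (is.na(upper) || upper <= lower)
    stop("'upper' must be > 'lower'")
  structure(list(lower = lower, upper = upper), class = "support_bounds")
}

#' @export
print.support_bounds <- function(x, ...) {
  cat(sprintf("step-length support: [%g, %g] m\n", x$lower, x$upper))
  invisible(x)
}

.as_bounds <- function(bounds) {
  if (inherits(bounds, "support_bounds")) return(bounds)
  if (is.numeric(bounds) && length(bounds) == 2L)
    return(support_bounds(bounds[1L], bounds[2L]))
  stop("'bounds' must be a support_bounds object or a numeric pair")
}

#' Specify a candidate step-length distribution family
#'
#' @param family One of `"EXP"`, `"BIEXP"`, `"STRETCHED"`,
#'   `"GSE_CONSTRAINED"`, `"GSE_FREE"`, `"POWER"`.
#' @param ... Named parameters for the family:
#'   * `EXP`: `lambda` (> 0, inverse meters).
#'   * `BIEXP`: `w` (mixing weight in (0,1)), `lambda1`, `lambda2`
#'     (both > 0, distinct; reported with `lambda1 < lambda2`).
#'   * `STRETCHED`: `lambda` (> 0), `gamma` (> 0); bare stretched kernel
#'     `exp(-(lambda l)^gamma)` with no power prefactor.
#'   * `GSE_CONSTRAINED`: `lambda` (> 0), `D` (> 0); shape derived as
#'     `gamma = D - 1`, `mu = D - 2`.
#'   * `GSE_FREE`: `lambda` (> 0), `gamma` (> 0), `mu` (real).
#'   * `POWER`: `mu` (< 0), the exponent of `l^mu`.
#' @return An object of class `steplaw_model` with elements `family`,
#'   `params` (named numeric) and `k` (free-parameter count).
#' @export
#' @examples
#' steplaw_model("GSE_CONSTRAINED", lambda = 1, D = 1.6)
steplaw_model <- function(family, ...) {
  family <- match.arg(family, .families)
  p <- c(...)
  need <- switch(family,
    EXP             = "lambda",
    BIEXP           = c("w", "lambda1", "lambda2"),
    STRETCHED       = c("lambda", "gamma"),
    GSE_CONSTRAINED = c("lambda", "D"),
    GSE_FREE        = c("lambda", "gamma", "mu"),
    POWER           = "mu")
  if (!all(need %in% names(p)))
    stop(sprintf("family %s needs parameters: %s", family,
                 paste(need, collapse = ", ")))
  p <- p[need]
  if (any(!is.finite(p))) stop("all parameters must be finite")
  ok <- switch(family,
    EXP             = p[["lambda"]] > 0,
    BIEXP           = p[["w"]] > 0 && p[["w"]] < 1 && p[["lambda1"]] > 0 &&
                      p[["lambda2"]] > 0 && p[["lambda1"]] != p[["lambda2"]],
    STRETCHED       = p[["lambda"]] > 0 && p[["gamma"]] > 0,
    GSE_CONSTRAINED = p[["lambda"]] > 0 && p[["D"]] > 0,
    GSE_FREE        = p[["lambda"]] > 0 && p[["gamma"]] > 0,
    POWER           = p[["mu"]] < 0)
  if (!ok) stop(sprintf("invalid parameters for family %s", family))
  if (family == "BIEXP" && p[["lambda1"]] > p[["lambda2"]]) {
    p <- c(w = 1 - p[["w"]], lambda1 = p[["lambda2"]],
           lambda2 = p[["lambda1"]])
  }
  structure(list(family = family, params = p, k = .family_k[[family]]),
            class = "steplaw_model")
}

#' @export
print.steplaw_model <- function(x, ...) {
  cat(sprintf("steplaw model [%s], k = %d\n", x$family, x$k))
  print(signif(x$params, 5))
  if (x$family == "GSE_CONSTRAINED")
    cat(sprintf("  derived shape: gamma = %.4g, mu = %.4g\n",
                x$params[["D"]] - 1, x$params[["D"]] - 2))
  invisible(x)
}

## Effective GSE kernel shape (gamma, mu) for the single-kernel families.
.kernel_shape <- function(model) {
  p <- model$params
  switch(model$family,
    EXP             = list(lambda = p[["lambda"]], gamma = 1, mu = 0),
    STRETCHED       = list(lambda = p[["lambda"]], gamma = p[["gamma"]],
                           mu = 0),
    GSE_CONSTRAINED = list(lambda = p[["lambda"]], gamma = p[["D"]] - 1,
                           mu = p[["D"]] - 2),
    GSE_FREE        = list(lambda = p[["lambda"]], gamma = p[["gamma"]],
                           mu = p[["mu"]]),
    POWER           = list(lambda = 1, gamma = 0, mu = p[["mu"]]),
    stop("no single kernel for family ", model$family))
}

## Unnormalized log kernel, vectorized over l (assumed inside bounds).
.log_kernel <- function(model, l) {
  if (model$family == "BIEXP")
    stop("internal: BIEXP has no single kernel")
  s <- .kernel_shape(model)
  if (s$gamma == 0) {
    ## stretch factor is the constant exp(-1); a pure power of l remains
    -1 + s$mu * log(l)
  } else {
    -(s$lambda * l)^s$gamma + s$mu * log(l)
  }
}

## log of integral_a^b exp(log_kernel) dl, by adaptive quadrature in a
## shifted log domain so large lambda*l never under/overflows.
.log_kernel_integral <- function(model, bounds) {
  a <- bounds$lower; b <- bounds$upper
  s <- .kernel_shape(model)
  if (!is.finite(b)) {
    if (s$gamma <= 0 && s$mu >= -1)
      stop("non-normalizable on bounds: kernel not integrable to Inf")
    if (s$gamma <= 0 && s$mu < -1) {
      ## pure (truncated) power with mu < -1 integrates in closed form
      return(-1 + log(a^(s$mu + 1) / (-(s$mu + 1))))
    }
  }
  ## scout the maximum of the log kernel on a log-spaced grid
  bb <- if (is.finite(b)) b else .effective_upper(model, a)
  grid <- exp(seq(log(a), log(bb), length.out = 257L))
  m <- max(.log_kernel(model, grid))
  f <- function(l) exp(.log_kernel(model, l) - m)
  val <- stats::integrate(f, a, b, rel.tol = 1e-10, abs.tol = 1e-9,
                          subdivisions = 500L)
  if (val$message != "OK" || !is.finite(val$value) || val$value <= 0)
    stop("non-normalizable on bounds: quadrature failed (", val$message, ")")
  m + log(val$value)
}

## Finite stand-in for an infinite upper bound: point where the kernel has
## decayed ~ exp(-45) below its scale.
.effective_upper <- function(model, a) {
  s <- .kernel_shape(model)
  if (s$gamma > 0) {
    up <- (45 + max(0, s$mu) * 10)^(1 / s$gamma) / s$lambda
    max(up, a * 10)
  } else {
    ## integrable pure power (mu < -1): tail mass below a*10^(45/(|mu|-1))
    a * 10^min(45 / max(1e-8, -(s$mu + 1)), 300)
  }
}

#' Normalization constant of a truncated step-length density
#'
#' Returns the factor `N` such that `N * kernel(l)` integrates to one over
#' the support. For the bi-exponential, whose two components are each
#' normalized truncated exponentials, `N` is 1 by construction.
#'
#' @param model A [steplaw_model()].
#' @param bounds A [support_bounds()] (or numeric pair).
#' @return Positive scalar `N`.
#' @export
#' @examples
#' m <- steplaw_model("EXP", lambda = 1)
#' steplaw_norm(m, support_bounds(0.1, 10))  # 1/(exp(-0.1) - exp(-10))
steplaw_norm <- function(model, bounds) {
  bounds <- .as_bounds(bounds)
  if (model$family == "BIEXP") return(1)
  exp(-.log_norm(model, bounds))
}

## log of the kernel integral (so log N = -.log_norm); closed forms where
## exact, quadrature otherwise.
.log_norm <- function(model, bounds) {
  a <- bounds$lower; b <- bounds$upper
  p <- model$params
  if (model$family == "EXP")
    return(.log_trunc_exp_mass(p[["lambda"]], a, b))
  if (model$family == "POWER") {
    mu <- p[["mu"]]
    if (abs(mu + 1) < 1e-12) return(-1 + log(log(b / a)))
    if (!is.finite(b)) {
      if (mu >= -1) stop("non-normalizable on bounds: power tail to Inf")
      return(-1 + log(a^(mu + 1) / (-(mu + 1))))
    }
    return(-1 + log((b^(mu + 1) - a^(mu + 1)) / (mu + 1)))
  }
  .log_kernel_integral(model, bounds)
}

## log of integral_a^b exp(-lambda l) dl, stable for large lambda*a.
.log_trunc_exp_mass <- function(lambda, a, b) {
  if (!is.finite(b)) return(-lambda * a - log(lambda))
  -lambda * a + log1p(-exp(-lambda * (b - a))) - log(lambda)
}

#' Log-density of a truncated step-length model
#'
#' @inheritParams steplaw_norm
#' @param l Numeric vector of step lengths (m). Values outside the bounds
#'   return `-Inf`.
#' @return Numeric vector of log-density values.
#' @export
steplaw_logpdf <- function(model, bounds, l) {
  bounds <- .as_bounds(bounds)
  out <- rep(-Inf, length(l))
  inside <- is.finite(l) & l >= bounds$lower & l <= bounds$upper
  if (!any(inside)) return(out)
  li <- l[inside]
  if (model$family == "BIEXP") {
    p <- model$params
    la <- log(p[["w"]]) + .log_trunc_exp_pdf(p[["lambda1"]], bounds, li)
    lb <- log(1 - p[["w"]]) + .log_trunc_exp_pdf(p[["lambda2"]], bounds, li)
    m <- pmax(la, lb)
    out[inside] <- m + log(exp(la - m) + exp(lb - m))
  } else {
    out[inside] <- .log_kernel(model, li) - .log_norm(model, bounds)
  }
  out
}

.log_trunc_exp_pdf <- function(lambda, bounds, l) {
  -lambda * l - .log_trunc_exp_mass(lambda, bounds$lower, bounds$upper)
}

#' @rdname steplaw_logpdf
#' @export
steplaw_pdf <- function(model, bounds, l) exp(steplaw_logpdf(model, bounds, l))

## Grid-based CDF shared by steplaw_cdf / steplaw_quantile / steplaw_sample:
## 4096 log-spaced nodes, trapezoid accumulation, monotone by construction.
.cdf_grid <- function(model, bounds, n_nodes = 4096L) {
  a <- bounds$lower
  b <- if (is.finite(bounds$upper)) bounds$upper else
    .effective_upper_model(model, a)
  x <- exp(seq(log(a), log(b), length.out = n_nodes))
  f <- steplaw_pdf(model, support_bounds(a, bounds$upper), x)
  cf <- cumsum(c(0, diff(x) * (utils::head(f, -1) + utils::tail(f, -1)) / 2))
  total <- cf[n_nodes]
  if (!is.finite(total) || total <= 0)
    stop("non-normalizable on bounds")
  list(x = x, cdf = cf / total)
}

.effective_upper_model <- function(model, a) {
  if (model$family == "BIEXP") {
    lam <- min(model$params[["lambda1"]], model$params[["lambda2"]])
    max(a * 10, 45 / lam)
  } else .effective_upper(model, a)
}

#' Distribution, survival and quantile functions
#'
#' Numerically integrated CDF of a truncated step-length model, its
#' complement, and its inverse (by monotone interpolation on a 4096-node
#' log-spaced grid, the same machinery used by [steplaw_sample()]).
#'
#' @inheritParams steplaw_logpdf
#' @param q Probabilities for `steplaw_quantile`.
#' @return Numeric vector.
#' @export
steplaw_cdf <- function(model, bounds, l) {
  bounds <- .as_bounds(bounds)
  g <- .cdf_grid(model, bounds)
  out <- stats::approx(g$x, g$cdf, xout = l, rule = 2, ties = "ordered")$y
  out[l < bounds$lower] <- 0
  out[l >= bounds$upper] <- 1
  out
}

#' @rdname steplaw_cdf
#' @export
steplaw_survival <- function(model, bounds, l) 1 - steplaw_cdf(model, bounds, l)

#' @rdname steplaw_cdf
#' @export
steplaw_quantile <- function(model, bounds, q) {
  stopifnot(all(q >= 0 & q <= 1))
  bounds <- .as_bounds(bounds)
  g <- .cdf_grid(model, bounds)
  keep <- c(TRUE, diff(g$cdf) > 0)
  stats::approx(g$cdf[keep], g$x[keep], xout = q, rule = 2,
                ties = "ordered")$y
}

#' Draw step lengths from a truncated model
#'
#' Sampling is by numeric inversion of the CDF on a log-spaced grid, which
#' works uniformly across all families.
#'
#' @inheritParams steplaw_logpdf
#' @param n Number of draws.
#' @param seed Optional integer seed applied locally for reproducibility.
#' @return A [step_sample()] holding `n` lengths inside the bounds.
#' @export
#' @examples
#' m <- steplaw_model("GSE_CONSTRAINED", lambda = 2, D = 1.6)
#' s <- steplaw_sample(m, support_bounds(0.05, 20), 100, seed = 1)
steplaw_sample <- function(model, bounds, n, seed = NULL) {
  stopifnot(n >= 1)
  bounds <- .as_bounds(bounds)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
      .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  u <- stats::runif(n)
  l <- steplaw_quantile(model, bounds, u)
  l <- pmin(pmax(l, bounds$lower),
            if (is.finite(bounds$upper)) bounds$upper else l)
  step_sample(l, bounds = bounds)
}
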