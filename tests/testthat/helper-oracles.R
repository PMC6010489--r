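## Independent oracles used across the suite. These deliberately avoid the
## package's own quadrature/inversion machinery.

## Brute-force Riemann-sum normalization of the GSE-type kernel
## exp(-(lambda l)^gamma) l^mu on [a, b] (midpoint rule, linear grid).
riemann_norm <- function(lambda, gamma, mu, a, b, nodes = 1e6) {
  h <- (b - a) / nodes
  x <- a + (seq_len(nodes) - 0.5) * h
  kern <- if (gamma == 0) exp(-1) * x^mu else exp(-(lambda * x)^gamma) * x^mu
  1 / sum(kern * h)
}

## Monte-Carlo of the sequential-interval hazard construction: walkers
## survive each interval of width dr with probability 1 - q(r) dr; returns
## the empirical survival of the resulting free paths on grid r_eval.
hazard_mc_survival <- function(geom, r_eval, n_walkers = 2e4, dr = 1e-4,
                               r_max = max(r_eval) * 1.5, seed = 1) {
  set.seed(seed)
  r <- seq(geom$delta, r_max, by = dr)
  q <- encounter_rate(geom, r)
  surv <- cumprod(1 - q * dr)
  u <- runif(n_walkers)
  ## first interval where the survival product drops below u
  idx <- findInterval(-u, -c(1, surv)) # survival is decreasing
  path <- r[pmin(idx, length(r))]
  vapply(r_eval, function(rr) mean(path >= rr), 0)
}

## A zig-zag trajectory with sub-threshold digitization jitter: straight
## runs of the given lengths joined by sharp turns, each run sampled as
## many small steps with small heading noise.
jittered_zigzag <- function(run_lengths, turn_angles_deg, step = 0.02,
                            jitter_deg = 8, seed = 1) {
  set.seed(seed)
  pos <- c(0, 0)
  heading <- 0
  xs <- pos[1]; ys <- pos[2]
  for (i in seq_along(run_lengths)) {
    n_sub <- max(2L, round(run_lengths[i] / step))
    for (j in seq_len(n_sub)) {
      h <- heading + runif(1, -jitter_deg, jitter_deg)
      pos <- pos + (run_lengths[i] / n_sub) *
        c(cos(h * pi / 180), sin(h * pi / 180))
      xs <- c(xs, pos[1]); ys <- c(ys, pos[2])
    }
    if (i <= length(turn_angles_deg))
      heading <- heading + turn_angles_deg[i]
  }
  trajectory(xs, ys)
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%.6g - %.6g| <= %g", object, expected, tol))
}
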