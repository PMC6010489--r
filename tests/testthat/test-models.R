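test_that("truncated-exponential normalization matches the closed form", {
  b <- support_bounds(0.1, 10)
  m <- steplaw_model("EXP", lambda = 1)
  expect_equal(steplaw_norm(m, b), 1 / (exp(-0.1) - exp(-10)),
               tolerance = 1e-10)
})

test_that("constrained GSE at D = 2 collapses to the exponential", {
  b <- support_bounds(0.1, 10)
  g <- steplaw_model("GSE_CONSTRAINED", lambda = 1, D = 2)
  e <- steplaw_model("EXP", lambda = 1)
  expect_equal(steplaw_norm(g, b), steplaw_norm(e, b), tolerance = 1e-7)
  l <- seq(0.1, 10, length.out = 50)
  expect_equal(steplaw_logpdf(g, b, l), steplaw_logpdf(e, b, l),
               tolerance = 1e-7)
})

test_that("GSE normalization agrees with a brute-force Riemann sum", {
  b <- support_bounds(0.1, 10)
  m <- steplaw_model("GSE_CONSTRAINED", lambda = 1, D = 1.5)
  expect_equal(steplaw_norm(m, b),
               riemann_norm(1, 0.5, -0.5, 0.1, 10, nodes = 1e6),
               tolerance = 1e-5)
})

test_that("every family integrates to one on random valid parameters", {
  set.seed(42)
  b <- support_bounds(0.05, 25)
  draws <- list(
    function() steplaw_model("EXP", lambda = runif(1, 0.2, 5)),
    function() steplaw_model("BIEXP", w = runif(1, 0.1, 0.9),
                             lambda1 = runif(1, 0.2, 2),
                             lambda2 = runif(1, 2.5, 10)),
    function() steplaw_model("STRETCHED", lambda = runif(1, 0.2, 5),
                             gamma = runif(1, 0.3, 2.5)),
    function() steplaw_model("GSE_CONSTRAINED", lambda = runif(1, 0.2, 5),
                             D = runif(1, 0.8, 2.5)),
    function() steplaw_model("GSE_FREE", lambda = runif(1, 0.2, 5),
                             gamma = runif(1, 0.3, 2.5),
                             mu = runif(1, -2, 2)),
    function() steplaw_model("POWER", mu = runif(1, -2.8, -0.2)))
  for (draw in draws) {
    for (rep in 1:3) {
      m <- draw()
      total <- stats::integrate(function(l) steplaw_pdf(m, b, l),
                                b$lower, b$upper, rel.tol = 1e-10)$value
      expect_equal(total, 1, tolerance = 1e-6,
                   label = paste("integral of", m$family))
    }
  }
})

test_that("log-pdf has the exponential slope at D = 2 and a pure power at D = 1", {
  b <- support_bounds(0.1, 10)
  g2 <- steplaw_model("GSE_CONSTRAINED", lambda = 2, D = 2)
  l <- c(0.3, 0.9, 2, 5)
  lp <- steplaw_logpdf(g2, b, l)
  expect_equal(diff(lp), -2 * diff(l), tolerance = 1e-8)
  g1 <- steplaw_model("GSE_CONSTRAINED", lambda = 2, D = 1)
  lp1 <- steplaw_logpdf(g1, b, l)
  expect_equal(diff(lp1), -diff(log(l)), tolerance = 1e-8)
})

test_that("bi-exponential log-pdf matches direct mixture arithmetic", {
  b <- support_bounds(0.1, 10)
  m <- steplaw_model("BIEXP", w = 0.5, lambda1 = 1, lambda2 = 5)
  z1 <- exp(-1 * 0.1) - exp(-1 * 10)
  z2 <- exp(-5 * 0.1) - exp(-5 * 10)
  direct <- 0.5 * 1 * exp(-1 * 0.5) / z1 + 0.5 * 5 * exp(-5 * 0.5) / z2
  expect_equal(steplaw_pdf(m, b, 0.5), direct, tolerance = 1e-10)
  expect_error(steplaw_model("BIEXP", w = 0.5, lambda1 = 2, lambda2 = 2),
               "invalid parameters")
})

test_that("GSE_FREE nests the exponential and degenerates to a power as gamma -> 0", {
  b <- support_bounds(0.1, 10)
  e <- steplaw_model("EXP", lambda = 1.5)
  f <- steplaw_model("GSE_FREE", lambda = 1.5, gamma = 1, mu = 0)
  l <- seq(0.2, 9, length.out = 20)
  expect_equal(steplaw_logpdf(f, b, l), steplaw_logpdf(e, b, l),
               tolerance = 1e-7)
  g <- steplaw_model("GSE_FREE", lambda = 1.5, gamma = 1e-6, mu = -1.5)
  p <- steplaw_model("POWER", mu = -1.5)
  expect_equal(steplaw_logpdf(g, b, l), steplaw_logpdf(p, b, l),
               tolerance = 1e-3)
})

test_that("survival decreases monotonically from 1 to 0 across the support", {
  b <- support_bounds(0.05, 15)
  for (m in list(steplaw_model("GSE_CONSTRAINED", lambda = 1, D = 1.6),
                 steplaw_model("BIEXP", w = 0.3, lambda1 = 0.5,
                               lambda2 = 4),
                 steplaw_model("POWER", mu = -2))) {
    l <- seq(b$lower, b$upper, length.out = 200)
    s <- steplaw_survival(m, b, l)
    expect_true(all(diff(s) <= 1e-12))
    expect_equal(s[1], 1, tolerance = 1e-6)
    expect_equal(s[length(s)], 0, tolerance = 1e-6)
  }
})

test_that("sampling is reproducible, contained and distributionally correct", {
  b <- support_bounds(0.05, 20)
  m <- steplaw_model("GSE_CONSTRAINED", lambda = 2, D = 1.6)
  s1 <- steplaw_sample(m, b, 1000, seed = 7)
  s2 <- steplaw_sample(m, b, 1000, seed = 7)
  expect_identical(s1$lengths, s2$lengths)
  expect_true(all(s1$lengths >= b$lower & s1$lengths <= b$upper))
  ## Kolmogorov-Smirnov style distance against the integrated CDF
  big <- steplaw_sample(m, b, 1e5, seed = 8)
  cdf <- steplaw_cdf(m, b, sort(big$lengths))
  expect_lt(max(abs(cdf - seq_len(1e5) / 1e5)), 0.01)
})

test_that("truncated-exponential sample mean matches the quadrature mean", {
  b <- support_bounds(0.01, 50)
  m <- steplaw_model("EXP", lambda = 2)
  s <- steplaw_sample(m, b, 1e5, seed = 9)
  mean_quad <- stats::integrate(function(l) l * steplaw_pdf(m, b, l),
                                b$lower, b$upper, rel.tol = 1e-10)$value
  expect_lt(abs(mean(s$lengths) / mean_quad - 1), 0.01)
})

test_that("degenerate and invalid inputs are rejected cleanly", {
  b <- support_bounds(0.1, 10)
  m <- steplaw_model("EXP", lambda = 1)
  expect_identical(steplaw_logpdf(m, b, c(0.05, 11)), c(-Inf, -Inf))
  ## a power with mu >= -1 cannot be normalized to infinity
  p <- steplaw_model("POWER", mu = -0.5)
  expect_error(steplaw_norm(p, support_bounds(0.1, Inf)),
               "non-normalizable")
  ## near-degenerate support still contains its single draw
  eps_b <- support_bounds(1, 1 + 1e-9)
  d <- steplaw_sample(m, eps_b, 1, seed = 1)
  expect_true(d$lengths >= 1 && d$lengths <= 1 + 1e-9)
  expect_error(support_bounds(0, 1), "must be finite and > 0")
  expect_error(support_bounds(2, 1))
})
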