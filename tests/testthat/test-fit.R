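test_that("AICc arithmetic is exact", {
  expect_equal(aicc(-27.79, 2, 20), 4 + 55.58 + 12 / 17, tolerance = 1e-12)
  expect_equal(aicc(-49.24, 2, 49), 4 + 98.48 + 12 / 46, tolerance = 1e-12)
  ## extra-parameter penalty at n = 28
  expect_equal(aicc(-10, 3, 28) - aicc(-10, 2, 28),
               2 + (24 / 24 - 12 / 25), tolerance = 1e-12)
  expect_error(aicc(-10, 3, 4), "n > k \\+ 1")
})

test_that("Akaike weights are a softmax invariant to common AICc shifts", {
  w <- akaike_weights(c(10, 10, 10))
  expect_equal(w, rep(1 / 3, 3), tolerance = 1e-12)
  a <- c(102.3, 104.8, 110.1)
  expect_equal(akaike_weights(a), akaike_weights(a + 57.3),
               tolerance = 1e-12)
  expect_equal(sum(akaike_weights(a)), 1, tolerance = 1e-12)
})

test_that("pairwise weights recompute published desert-ant rows", {
  ## ant 4 (n = 28): constrained GSE vs bi-exponential
  expect_close(pairwise_weight_loglik(-28.09, 2, -28.10, 3, 28), 0.78,
               0.005)
  ## ant 22 (n = 49): vs bi-exponential and vs the unconstrained GSE
  expect_close(pairwise_weight_loglik(-49.24, 2, -49.92, 3, 49), 0.86,
               0.005)
  expect_close(pairwise_weight_loglik(-49.24, 2, -49.20, 3, 49), 0.75,
               0.005)
  ## symmetry: equal likelihoods, equal complexity
  expect_equal(pairwise_weight_loglik(-10, 2, -10, 2, 30), 0.5,
               tolerance = 1e-12)
})

test_that("the bundled published fit table is consistent where expected", {
  tbl <- bagoti_channel_fits()
  expect_equal(nrow(tbl), 23L)
  expect_equal(sum(is.na(tbl$logL_gse)), 1L)  # ant 13, two steps, unfitted
  ok <- !is.na(tbl$logL_gse)
  recomputed <- mapply(pairwise_weight_loglik,
                       tbl$logL_gse[ok], 2, tbl$logL_biexp[ok], 3,
                       tbl$n_steps[ok])
  ## rows 4 and 22 recompute to the printed precision
  expect_close(recomputed[which(tbl$ant[ok] == 4)], 0.78, 0.005)
  expect_close(recomputed[which(tbl$ant[ok] == 22)], 0.86, 0.005)
  ## rows 1 and 16 are known printed inconsistencies (no AIC convention
  ## reproduces them); the recomputation deviates visibly
  expect_gt(abs(recomputed[which(tbl$ant[ok] == 1)] - 0.82), 0.02)
  expect_gt(abs(recomputed[which(tbl$ant[ok] == 16)] - 0.77), 0.02)
})

test_that("exponential rate is recovered from a large seeded sample", {
  s <- steplaw_sample(steplaw_model("EXP", lambda = 2),
                      support_bounds(0.01, 50), 1e4, seed = 3)
  f <- fit_steplaw(s, "EXP")
  expect_true(f$converged)
  lam <- f$model$params[["lambda"]]
  expect_true(lam > 1.94 && lam < 2.06)
})

test_that("small-sample constrained-GSE fit matches an exhaustive grid search", {
  s <- steplaw_sample(steplaw_model("GSE_CONSTRAINED", lambda = 2,
                                    D = 1.6),
                      support_bounds(0.05, 20), 30, seed = 5)
  f <- fit_steplaw(s, "GSE_CONSTRAINED")
  x <- s$lengths
  a <- s$bounds$lower; bb <- s$bounds$upper
  ## independent oracle: dense grid over (lambda, D), trapezoid
  ## normalization on a log-spaced node grid
  lam_grid <- exp(seq(log(0.1 / mean(x)), log(10 / mean(x)),
                      length.out = 400))
  D_grid <- seq(1.05, 2.5, length.out = 400)
  nodes <- exp(seq(log(a), log(bb), length.out = 512))
  dn <- diff(nodes)
  best <- -Inf
  for (D in D_grid) {
    gam <- D - 1; mu <- D - 2
    su_data <- colSums(outer(x, lam_grid)^gam)
    kern <- exp(-outer(nodes, lam_grid)^gam) * nodes^mu
    Z <- colSums((kern[-1, ] + kern[-nrow(kern), ]) / 2 * dn)
    ll <- -su_data + mu * sum(log(x)) - length(x) * log(Z)
    best <- max(best, max(ll))
  }
  expect_gte(f$logL, best - 1e-6)
  expect_lt(abs(f$logL - best), 1e-3)
})

test_that("fitted log-likelihood is monotone under family nesting", {
  for (seed in c(21, 22)) {
    s <- steplaw_sample(steplaw_model("GSE_CONSTRAINED", lambda = 1.5,
                                      D = 1.5),
                        support_bounds(0.05, 30), 300, seed = seed)
    ll <- vapply(c("EXP", "STRETCHED", "GSE_CONSTRAINED", "GSE_FREE",
                   "BIEXP"),
                 function(fam) fit_steplaw(s, fam)$logL, 0)
    expect_gte(ll[["STRETCHED"]], ll[["EXP"]] - 1e-6)
    expect_gte(ll[["GSE_CONSTRAINED"]], ll[["EXP"]] - 1e-6)
    expect_gte(ll[["GSE_FREE"]], ll[["STRETCHED"]] - 1e-6)
    expect_gte(ll[["GSE_FREE"]], ll[["GSE_CONSTRAINED"]] - 1e-6)
    expect_gte(ll[["BIEXP"]], ll[["EXP"]] - 1e-6)
  }
})

test_that("multi-model weights reduce to the pairwise weight for two fits", {
  s <- steplaw_sample(steplaw_model("EXP", lambda = 1),
                      support_bounds(0.05, 20), 200, seed = 6)
  f1 <- fit_steplaw(s, "EXP")
  f2 <- fit_steplaw(s, "GSE_CONSTRAINED")
  cmp <- multi_model_weights(list(f1, f2))
  expect_equal(cmp$weight[1], pairwise_weight(f1, f2), tolerance = 1e-12)
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-12)
})

test_that("penalty dominance picks the exponential on exponential data", {
  s <- steplaw_sample(steplaw_model("EXP", lambda = 2),
                      support_bounds(0.02, 30), 500, seed = 12)
  fits <- lapply(c("EXP", "GSE_CONSTRAINED", "BIEXP"),
                 function(fam) fit_steplaw(s, fam))
  cmp <- multi_model_weights(fits)
  expect_equal(cmp$family[which.max(cmp$weight)], "EXP")
})

test_that("true families win the model competition across seeds", {
  ## simulation-based recovery: data from each family, n = 1000, the
  ## highest multi-model weight should identify the generator
  b <- support_bounds(0.05, 30)
  truth <- list(
    EXP = steplaw_model("EXP", lambda = 1.5),
    GSE_CONSTRAINED = steplaw_model("GSE_CONSTRAINED", lambda = 1.5,
                                    D = 1.5),
    BIEXP = steplaw_model("BIEXP", w = 0.45, lambda1 = 0.4, lambda2 = 6),
    POWER = steplaw_model("POWER", mu = -1.8))
  fams <- names(truth)
  for (true_fam in fams) {
    hits <- 0L
    for (seed in 1:20) {
      s <- steplaw_sample(truth[[true_fam]], b, 1000, seed = 100 + seed)
      fits <- lapply(fams, function(fam) fit_steplaw(s, fam))
      cmp <- multi_model_weights(fits)
      if (cmp$family[which.max(cmp$weight)] == true_fam) hits <- hits + 1L
    }
    expect_gte(hits, 16L)
  }
})

test_that("constrained-GSE dimension is recovered where the family is identified", {
  ## the recovery band matches the across-individual 95% CI half-width of
  ## about 0.3
  b <- support_bounds(0.05, 30)
  for (D_true in c(1.6, 1.9)) {
    hits <- 0L
    for (seed in 1:20) {
      s <- steplaw_sample(steplaw_model("GSE_CONSTRAINED", lambda = 1.5,
                                        D = D_true),
                          b, 500, seed = 400 + seed)
      f <- fit_steplaw(s, "GSE_CONSTRAINED")
      if (abs(f$model$params[["D"]] - D_true) <= 0.3) hits <- hits + 1L
    }
    expect_gte(hits, 18L)
  }
})

test_that("low-D fits are bimodal between the true mode and the gamma < 0 branch", {
  ## near D = 1.3 the stretch exponent gamma = D - 1 is weak and a second
  ## likelihood mode with D < 1 (rising stretch factor, steeper power)
  ## can fit marginally better at n = 500; estimates land either in the
  ## true mode or in that documented alternative branch, never in between
  b <- support_bounds(0.05, 30)
  d_hat <- vapply(1:20, function(seed) {
    s <- steplaw_sample(steplaw_model("GSE_CONSTRAINED", lambda = 1.5,
                                      D = 1.3),
                        b, 500, seed = 400 + seed)
    fit_steplaw(s, "GSE_CONSTRAINED")$model$params[["D"]]
  }, 0)
  in_band <- abs(d_hat - 1.3) <= 0.3
  low_branch <- d_hat < 1
  expect_true(all(in_band | low_branch))
  expect_gte(sum(in_band), 13L)
})

test_that("the exact sign test doubles the smaller tail and caps at one", {
  expect_equal(sign_test(18, 22)$p.value,
               2 * sum(choose(22, 18:22)) / 2^22, tolerance = 1e-12)
  expect_lte(sign_test(18, 22)$p.value, 0.01)
  expect_equal(sign_test(11, 22)$p.value, 1)
  expect_equal(sign_test(0, 10)$p.value, 2 / 2^10, tolerance = 1e-12)
})

test_that("pooling concatenates samples and refits on the pooled range", {
  b <- support_bounds(0.02, 30)
  s1 <- steplaw_sample(steplaw_model("EXP", lambda = 1), b, 300,
                       seed = 31)
  s2 <- steplaw_sample(steplaw_model("EXP", lambda = 3), b, 300,
                       seed = 32)
  single <- pooled_fit(list(s1), "EXP")
  direct <- fit_steplaw(step_sample(s1$lengths), "EXP")
  expect_equal(single$logL, direct$logL, tolerance = 1e-8)
  l1 <- fit_steplaw(step_sample(s1$lengths), "EXP")$model$params[["lambda"]]
  l2 <- fit_steplaw(step_sample(s2$lengths), "EXP")$model$params[["lambda"]]
  lp <- pooled_fit(list(s1, s2), "EXP")$model$params[["lambda"]]
  expect_true(lp > min(l1, l2) && lp < max(l1, l2))
})

test_that("insufficient samples are refused with an informative error", {
  s <- step_sample(c(0.5, 0.8))
  expect_error(fit_steplaw(s, "EXP"), "insufficient steps")
  expect_error(fit_steplaw(step_sample(runif(4) + 0.1), "BIEXP"),
               "insufficient steps")
})

test_that("rank frequency is the survival complement with tie collapsing", {
  rf <- rank_frequency(c(1, 2, 3, 4))
  expect_equal(rf$fraction, c(1, 0.75, 0.5, 0.25))
  rf2 <- rank_frequency(c(2, 1, 2, 3))
  expect_equal(rf2$length, c(1, 2, 3))
  expect_equal(rf2$fraction, c(1, 0.75, 0.25))
  expect_true(all(diff(rf2$fraction) < 0))
  ## exponential data: -log(fraction) is linear in length with slope lambda
  s <- steplaw_sample(steplaw_model("EXP", lambda = 2),
                      support_bounds(1e-4, 60), 1e4, seed = 33)
  rf3 <- rank_frequency(s)
  keep <- rf3$fraction > 0.01
  slope <- stats::coef(stats::lm(-log(rf3$fraction[keep]) ~
                                   rf3$length[keep]))[2]
  expect_close(unname(slope), 2, 0.1)
})
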