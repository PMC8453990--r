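test_that("Hedges g matches the closed form with its small-sample correction", {
  es <- hedges_g(10, 2, 5, 8, 2, 5)
  expect_equal(es$g, (1 - 3 / 31) * (-1))
  expect_equal(es$v, 10 / 25 + es$g^2 / 20)
  expect_equal(es$g, -0.9032258, tolerance = 1e-6)
  expect_equal(es$v, 0.4407908, tolerance = 1e-6)
  # no difference, no effect
  expect_equal(hedges_g(10, 2, 5, 10, 2, 5)$g, 0)
  # antisymmetric under arm swap; variance invariant
  a <- hedges_g(10, 2, 5, 8, 3, 7)
  b <- hedges_g(8, 3, 7, 10, 2, 5)
  expect_equal(a$g, -b$g)
  expect_equal(a$v, b$v)
  # scale invariance of the standardized difference
  k <- 3.7
  expect_equal(hedges_g(10 * k, 2 * k, 5, 8 * k, 2 * k, 5), es)
  expect_error(hedges_g(10, 0, 5, 8, 0, 5), "zero pooled SD")
  expect_warning(hedges_g(10, 0, 5, 10, 0, 5), "zero SD")
  expect_error(hedges_g(10, 2, 1, 8, 2, 5), "n >= 2")
  expect_equal(se_to_sd(2, 9), 6)
})

test_that("fixed-effect fits collapse to inverse-variance weighted closed forms", {
  set.seed(3)
  d <- data.frame(g = rnorm(20), v = runif(20, 0.1, 0.5),
                  x = rep(c(0, 1), 10))
  # equal variances, no moderators: intercept is the arithmetic mean
  deq <- transform(d, v = 0.2)
  f <- fit_meta(deq, ~ 1, random = NULL)
  expect_equal(unname(f$beta), mean(deq$g))
  # single moderator: equals weighted least squares with weights 1/v
  f2 <- fit_meta(d, ~ x, random = NULL)
  lmw <- lm(g ~ x, data = d, weights = 1 / d$v)
  expect_equal(unname(f2$beta), unname(coef(lmw)), tolerance = 1e-10)
  # model-based covariance equals the GLS closed form
  X <- cbind(1, d$x)
  expect_equal(unname(f2$vb),
               unname(solve(t(X) %*% diag(1 / d$v) %*% X)), tolerance = 1e-10)
})

test_that("REML tau2 is clamped to zero when heterogeneity is below expectation", {
  set.seed(4)
  d <- data.frame(g = rnorm(40, 0, 0.05), v = rep(0.3, 40),
                  cluster = rep(1:20, each = 2))
  f <- fit_meta(d, ~ 1, random = "cluster")
  expect_identical(unname(f$tau2), 0)
})

test_that("random-intercept REML agrees with metafor::rma.mv", {
  library(metafor)
  d <- parametric_effects(generator_truth(n_clusters = 30, cluster_size = 3,
                                          tau2 = 0.08), seed = 7)
  f <- fit_meta(d, ~ x, random = "cluster")
  m <- rma.mv(g ~ x, V = v, random = ~ 1 | cluster, data = d,
              method = "REML")
  expect_equal(unname(f$beta), as.numeric(coef(m)), tolerance = 1e-6)
  expect_equal(unname(f$tau2), as.numeric(m$sigma2), tolerance = 1e-6)
  expect_equal(unname(f$se), as.numeric(m$se), tolerance = 1e-6)
  # ML refit used for LRTs matches too
  fml <- fit_meta(d, ~ x, random = "cluster", method = "ML")
  mml <- rma.mv(g ~ x, V = v, random = ~ 1 | cluster, data = d,
                method = "ML")
  expect_equal(fml$ll_ml, as.numeric(logLik(mml)), tolerance = 1e-6)
})

test_that("continuous-time AR serial structure agrees with metafor's CAR", {
  library(metafor)
  tr <- generator_truth(beta = c(0, -0.5), tau2 = 0, tau2_series = 0.15,
                        rho = 0.5, n_clusters = 60,
                        times = seq(0.5, 3, by = 0.5))
  d <- parametric_effects(tr, seed = 11)
  f <- fit_meta(d, ~ x, random = NULL,
                ar = list(series = "series", time = "time"))
  m <- rma.mv(g ~ x, V = v, random = ~ time | series, struct = "CAR",
              data = d, method = "REML")
  expect_equal(unname(f$beta), as.numeric(coef(m)), tolerance = 1e-5)
  expect_equal(f$tau2_ar, as.numeric(m$tau2), tolerance = 1e-4)
  expect_equal(f$phi, as.numeric(m$rho), tolerance = 1e-4)
  # a single-timepoint series degenerates gracefully to an intercept
  d1 <- d[!duplicated(d$series), ]
  f1 <- fit_meta(d1, ~ x, random = NULL,
                 ar = list(series = "series", time = "time"))
  expect_true(is.finite(f1$ll))
})

test_that("cluster-robust sandwich reduces to the sample-mean formula", {
  # one effect per cluster, equal v, no heterogeneity, intercept only
  set.seed(8)
  g <- rnorm(50, 0.2, 0.3)
  d <- data.frame(g = g, v = rep(0.1, 50), cluster = 1:50)
  f <- fit_meta(d, ~ 1, random = NULL)
  ri <- robust_inference(f, "cluster")
  # with the G/(G-1) scaling the sandwich is exactly the empirical SE of
  # the sample mean
  expect_equal(ri$table$se_robust, sd(g) / sqrt(50), tolerance = 1e-10)
  expect_equal(ri$df, 49)
  expect_error(robust_inference(
    fit_meta(data.frame(g = 1:2 / 10, v = c(0.1, 0.1), cluster = c(1, 1)),
             ~ 1, random = NULL), "cluster"), ">= 2 clusters")
})

test_that("duplicating every cluster leaves coefficients unchanged", {
  d <- parametric_effects(generator_truth(n_clusters = 20), seed = 5)
  d2 <- rbind(d, transform(d, cluster = cluster + 1000, series = series + 1000))
  # exact at fixed variance components
  f <- fit_meta(d, ~ x, random = NULL)
  f2 <- fit_meta(d2, ~ x, random = NULL)
  expect_equal(f$beta, f2$beta, tolerance = 1e-10)
  # REML re-estimates tau2 on the doubled data, so only near-invariance
  g <- fit_meta(d, ~ x, random = "cluster")
  g2 <- fit_meta(d2, ~ x, random = "cluster")
  expect_equal(g$beta, g2$beta, tolerance = 1e-3)
})

test_that("likelihood-ratio deletion tests behave at their boundaries", {
  d <- parametric_effects(generator_truth(n_clusters = 40), seed = 6)
  f1 <- fit_meta(d, ~ x, random = "cluster", method = "ML")
  f0 <- fit_meta(d, ~ 1, random = "cluster", method = "ML")
  lrt <- lrt_moderator(f1, f0)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1)
  # identical models: statistic 0, p = 1
  same <- lrt_moderator(f1, f1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # non-nested designs rejected
  d$z <- rnorm(nrow(d))
  fz <- fit_meta(d, ~ z, random = "cluster", method = "ML")
  expect_error(lrt_moderator(f1, fz), "nested")
  # strong moderator detected with high power at modest replicate count
  rej <- vapply(1:60, function(i) {
    di <- parametric_effects(generator_truth(beta = c(0, -1), tau2 = 0.05,
                                             n_clusters = 100),
                             seed = 30000 + i)
    a <- fit_meta(di, ~ x, random = "cluster", method = "ML")
    b <- fit_meta(di, ~ 1, random = "cluster", method = "ML")
    lrt_moderator(a, b)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.9)
})

test_that("per-level summaries recombine the fitted coefficients", {
  d <- parametric_effects(generator_truth(n_clusters = 40), seed = 9)
  d$grp <- ifelse(d$x == 1, "B", "A")
  # intercept-only: the single pooled effect is the intercept
  f0 <- fit_meta(d, ~ 1, random = "cluster")
  lv0 <- summarize_by_level(f0, "grp")
  expect_equal(lv0$estimate, rep(unname(f0$beta), 2))
  # balanced two-level moderator: level estimates average to the grand
  # (OLS) estimate under equal variances
  deq <- transform(d, v = 0.15)
  f1 <- fit_meta(deq, ~ grp, random = NULL)
  lv1 <- summarize_by_level(f1, "grp")
  expect_equal(mean(lv1$estimate), mean(deq$g), tolerance = 1e-10)
  expect_equal(lv1$n, c(sum(d$grp == "A"), sum(d$grp == "B")))
  # robust covariance variant carries the t-based interval
  lv2 <- summarize_by_level(f1, "grp", cluster = "cluster")
  expect_true(all(lv2$ci.lb < lv2$estimate & lv2$estimate < lv2$ci.ub))
})

test_that("rank-deficient moderator designs are rejected with named columns", {
  d <- parametric_effects(generator_truth(n_clusters = 20), seed = 10)
  d$x2 <- d$x
  expect_error(fit_meta(d, ~ x + x2, random = "cluster"), "rank deficient")
})
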