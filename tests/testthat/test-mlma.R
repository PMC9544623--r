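test_that("GLS limiting cases reproduce inverse-variance weighting", {
  d <- data.frame(yi = c(0, 0), vi = c(1, 1))
  f <- mlma(yi ~ 1, data = d, vi = "vi", random = NULL)
  expect_equal(unname(coef(f)), 0)

  d <- data.frame(yi = c(1, 3), vi = c(1, 1))
  f <- mlma(yi ~ 1, data = d, vi = "vi", random = NULL)
  expect_equal(unname(coef(f)), 2)
  expect_equal(sqrt(diag(vcov(f)))[[1]], sqrt(0.5), tolerance = 1e-6)

  # unequal variances: weighted mean with w = 1/v
  d <- data.frame(yi = c(1, 3), vi = c(1, 4))
  f <- mlma(yi ~ 1, data = d, vi = "vi", random = NULL)
  expect_equal(unname(coef(f)), (1 / 1 * 1 + 1 / 4 * 3) / (1 + 1 / 4),
               tolerance = 1e-10)
})

test_that("REML solution matches a brute-force grid search of the likelihood", {
  set.seed(3)
  d <- data.frame(yi = c(0.2, -0.1, 0.5, 0.9, -0.3, 0.4),
                  vi = c(0.1, 0.2, 0.15, 0.3, 0.25, 0.1),
                  grp = c("a", "a", "b", "b", "c", "c"))
  d$row <- paste0("r", seq_len(6))
  for (method in c("REML", "ML")) {
    fit <- mlma(yi ~ 1, data = d, vi = "vi", random = "row",
                method = method)
    X <- matrix(1, 6, 1)
    grid <- seq(0, 1, by = 1e-4)
    ll <- vapply(grid, function(s2)
      oracle_loglik(d$yi, X, diag(d$vi + s2), method), numeric(1))
    s2_star <- grid[which.max(ll)]
    expect_equal(unname(fit$sigma2), s2_star, tolerance = 1.1e-4)
    expect_equal(fit$logLik, max(ll), tolerance = 1e-6)
  }
})

test_that("fits agree with an independent multilevel REML implementation", {
  skip_if_not_installed("metafor")
  ds <- generate_summary_dataset(generator_config(
    n_publications = 12, comparisons_per_publication = 3,
    effects_per_comparison = 2, seed = 5))
  es <- effect_sizes(ds, "lnCVR")
  V <- build_vcv(es)
  for (method in c("REML", "ML")) {
    fit <- mlma(yi ~ 1, data = es, V = V, method = method)
    ref <- metafor::rma.mv(yi, V, data = es, method = method,
                           random = ~ 1 | publication_id / comparison_id /
                             effect_id)
    expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-5)
    expect_equal(unname(fit$sigma2), ref$sigma2, tolerance = 1e-4)
    expect_equal(sqrt(diag(vcov(fit)))[[1]], ref$se, tolerance = 1e-5)
  }
  # moderator model too
  fitm <- mlma(yi ~ crop, data = es, V = V, method = "REML")
  refm <- metafor::rma.mv(yi, V, mods = ~ crop, data = es,
                          method = "REML",
                          random = ~ 1 | publication_id / comparison_id /
                            effect_id)
  expect_equal(unname(coef(fitm)), unname(coef(refm)), tolerance = 1e-4)
})

test_that("analytic gradient matches numerical differentiation", {
  ds <- generate_summary_dataset(generator_config(
    n_publications = 6, comparisons_per_publication = 2,
    effects_per_comparison = 2, seed = 9))
  es <- effect_sizes(ds, "lnCVR")
  V <- build_vcv(es)
  fit <- mlma(yi ~ 1, data = es, V = V)
  bd <- stabmeta:::precompute_blocks(
    fit$Vs, fit$X, fit$y - fit$offset, fit$groups,
    stabmeta:::independent_blocks(fit$Vs, fit$groups))
  for (method in c("REML", "ML")) {
    th <- log(c(0.03, 0.02, 0.01))
    g_an <- stabmeta:::neg2ll_grad(bd, th, method)
    h <- 1e-6
    g_num <- vapply(1:3, function(i) {
      e <- rep(0, 3); e[i] <- h
      (stabmeta:::neg2ll(bd, th + e, method) -
         stabmeta:::neg2ll(bd, th - e, method)) / (2 * h)
    }, numeric(1))
    expect_equal(g_an, g_num, tolerance = 1e-4)
  }
})

test_that("estimates are equivariant and invariant where they must be", {
  ds <- generate_summary_dataset(generator_config(
    n_publications = 8, comparisons_per_publication = 2,
    effects_per_comparison = 2, seed = 4))
  es <- effect_sizes(ds, "lnCVR")
  V <- build_vcv(es)
  fit <- mlma(yi ~ 1, data = es, V = V)
  # adding a constant shifts the intercept only
  es2 <- es; es2$yi <- es$yi + 1.5
  fit2 <- mlma(yi ~ 1, data = es2, V = V)
  expect_equal(unname(coef(fit2)), unname(coef(fit)) + 1.5,
               tolerance = 1e-6)
  expect_equal(fit2$sigma2, fit$sigma2, tolerance = 1e-6)
  # permuting rows leaves variance components unchanged
  perm <- sample(nrow(es))
  fit3 <- mlma(yi ~ 1, data = es[perm, ], V = V[perm, perm])
  expect_equal(fit3$sigma2, fit$sigma2, tolerance = 1e-6)
  expect_equal(coef(fit3), coef(fit), tolerance = 1e-8)
})

test_that("Wald summaries and degenerate confidence levels are exact", {
  d <- data.frame(yi = c(1, 3), vi = c(1, 1))
  f <- mlma(yi ~ 1, data = d, vi = "vi", random = NULL)
  sm <- summary(f, level = 0.95)$coefficients
  expect_equal(sm$ci.lb, 2 - qnorm(0.975) * sqrt(0.5), tolerance = 1e-8)
  # hand case: estimate 0, SE 1 -> (-1.96, 1.96)
  z <- qnorm(0.975)
  expect_equal(c(-z, z), c(-1.959964, 1.959964), tolerance = 1e-4)
  # estimate -0.386, SE 0.05 -> (-0.484, -0.288)
  expect_equal(-0.386 + c(-1, 1) * z * 0.05, c(-0.484, -0.288),
               tolerance = 1e-3)
  sm0 <- summary(f, level = 0)$coefficients
  expect_equal(sm0$ci.lb, sm0$estimate)
  expect_equal(sm0$ci.ub, sm0$estimate)
})

test_that("prediction intervals widen confidence intervals by the random variances", {
  ds <- generate_summary_dataset(generator_config(
    n_publications = 8, comparisons_per_publication = 2,
    effects_per_comparison = 2, seed = 12))
  es <- effect_sizes(ds, "lnCVR")
  fit <- mlma(yi ~ 1, data = es, V = build_vcv(es))
  pr <- predict(fit, level = 0.95)
  z <- qnorm(0.975)
  half_ci <- z * pr$se
  half_pi <- z * sqrt(pr$se^2 + sum(fit$sigma2))
  expect_equal(pr$ci.ub - pr$pred, half_ci, tolerance = 1e-10)
  expect_equal(pr$pi.ub - pr$pred, half_pi, tolerance = 1e-10)
  expect_true(all(pr$pi.lb <= pr$ci.lb & pr$ci.ub <= pr$pi.ub))
  # hand case: SE 0.1, summed sigma2 0.03 -> half-width 1.96 * 0.2
  expect_equal(z * sqrt(0.1^2 + 0.03), 0.392, tolerance = 1e-3)
})

test_that("likelihood-ratio tests behave as chi-square comparisons of ML fits", {
  ds <- generate_summary_dataset(generator_config(
    n_publications = 9, comparisons_per_publication = 2,
    effects_per_comparison = 2, seed = 21))
  es <- effect_sizes(ds, "lnCVR")
  V <- build_vcv(es)
  null_ml <- mlma(yi ~ 1, data = es, V = V, method = "ML")
  alt_ml <- mlma(yi ~ crop, data = es, V = V, method = "ML")
  tab <- anova(null_ml, alt_ml)
  expect_equal(tab$df, 2)
  expect_equal(tab$statistic, 2 * (alt_ml$logLik - null_ml$logLik),
               tolerance = 1e-10)
  expect_equal(tab$pval,
               pchisq(tab$statistic, 2, lower.tail = FALSE))
  # identical models: statistic 0, p 1
  same <- anova(null_ml, null_ml)
  expect_equal(same$statistic, 0)
  expect_equal(same$pval, 1)
  # hand case: loglik -10 vs -7 with df 2
  expect_equal(pchisq(6, 2, lower.tail = FALSE), 0.0498, tolerance = 1e-3)
  # REML fits and reversed nesting are refused
  null_reml <- mlma(yi ~ 1, data = es, V = V, method = "REML")
  expect_error(anova(null_reml, alt_ml), "require ML")
  expect_error(anova(alt_ml, null_ml), "fewer fixed coefficients")
})

test_that("cell-means and reference codings give the same likelihood", {
  ds <- generate_summary_dataset(generator_config(
    n_publications = 9, comparisons_per_publication = 2,
    effects_per_comparison = 2, seed = 31))
  es <- effect_sizes(ds, "lnCVR")
  V <- build_vcv(es)
  cm <- mlma(yi ~ 0 + crop, data = es, V = V, method = "ML")
  rf <- mlma(yi ~ crop, data = es, V = V, method = "ML")
  expect_equal(cm$logLik, rf$logLik, tolerance = 1e-6)
  expect_equal(cm$sigma2, rf$sigma2, tolerance = 1e-5)
})

test_that("rank-deficient designs fail naming the aliased columns", {
  d <- data.frame(yi = rnorm(6), vi = rep(0.1, 6), x1 = 1:6)
  d$x2 <- d$x1
  expect_error(mlma(yi ~ x1 + x2, data = d, vi = "vi", random = NULL),
               "aliased columns: x2")
})

test_that("REML and ML agree on the pooled mean under equal weights", {
  d <- data.frame(yi = c(0.1, 0.4, -0.2, 0.3), vi = rep(0.2, 4),
                  row = paste0("r", 1:4))
  fr <- mlma(yi ~ 1, data = d, vi = "vi", random = "row")
  fm <- mlma(yi ~ 1, data = d, vi = "vi", random = "row", method = "ML")
  expect_equal(coef(fr), coef(fm), tolerance = 1e-8)
  expect_equal(unname(coef(fr)), mean(d$yi), tolerance = 1e-8)
})

test_that("simulate draws from the fitted marginal distribution", {
  d <- data.frame(yi = c(0.1, 0.4, -0.2, 0.3), vi = rep(0.04, 4),
                  row = paste0("r", 1:4))
  fit <- mlma(yi ~ 1, data = d, vi = "vi", random = "row")
  s1 <- simulate(fit, nsim = 3, seed = 99)
  s2 <- simulate(fit, nsim = 3, seed = 99)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(4L, 3L))
})
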