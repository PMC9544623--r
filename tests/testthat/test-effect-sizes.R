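test_that("bias-corrected effect sizes match hand-computed values", {
  # lnRR: equal CVs and n, bias terms cancel
  es <- lnrr(20, 2, 10, 10, 1, 10)
  expect_equal(es$yi, log(2), tolerance = 1e-4)
  expect_equal(es$vi, 0.0020, tolerance = 1e-4)
  # identical arms: estimate 0, variance 2 * 9/(5*100)
  es <- lnrr(10, 3, 5, 10, 3, 5)
  expect_equal(es$yi, 0, tolerance = 1e-10)
  expect_equal(es$vi, 0.036, tolerance = 1e-4)

  # lnVR: equal SDs and n
  es <- lnvr(1, 2, 10, 1, 2, 10)
  expect_equal(es$yi, 0, tolerance = 1e-10)
  expect_equal(es$vi, 1 / 9, tolerance = 1e-4)
  es <- lnvr(1, 4, 10, 1, 2, 5)
  expect_equal(es$yi, log(2) + 1 / 18 - 1 / 8, tolerance = 1e-4)

  # lnCVR: equal n, n-based corrections cancel
  es <- lncvr(20, 2, 10, 10, 2, 10)
  expect_equal(es$yi, log(0.5) - 0.5 * (0.001 - 0.004), tolerance = 1e-4)
  expect_equal(es$vi, 0.001 + 1 / 18 + 0.004 + 1 / 18, tolerance = 1e-4)
  es <- lncvr(10, 2, 8, 10, 2, 8)
  expect_equal(es$yi, 0, tolerance = 1e-10)
})

test_that("corrected components satisfy lnCVR = lnVR - lnRR and swap antisymmetry", {
  set.seed(7)
  for (i in 1:25) {
    m <- runif(2, 1, 50); s <- runif(2, 0.1, 10)
    n <- sample(3:40, 2, replace = TRUE)
    cvr <- lncvr(m[1], s[1], n[1], m[2], s[2], n[2])
    vr <- lnvr(m[1], s[1], n[1], m[2], s[2], n[2])
    rr <- lnrr(m[1], s[1], n[1], m[2], s[2], n[2])
    expect_equal(cvr$yi, vr$yi - rr$yi, tolerance = 1e-12)
    # swapping treatment and control negates each estimate
    expect_equal(lncvr(m[2], s[2], n[2], m[1], s[1], n[1])$yi, -cvr$yi,
                 tolerance = 1e-12)
    expect_equal(lnvr(m[2], s[2], n[2], m[1], s[1], n[1])$yi, -vr$yi,
                 tolerance = 1e-12)
    expect_equal(lnrr(m[2], s[2], n[2], m[1], s[1], n[1])$yi, -rr$yi,
                 tolerance = 1e-12)
  }
})

test_that("domain violations are rejected", {
  expect_error(lnrr(-1, 1, 10, 10, 1, 10), "means must be > 0")
  expect_error(lnvr(1, 0, 10, 1, 1, 10), "SDs must be > 0")
  expect_error(lncvr(10, 1, 1, 10, 1, 10), "sample sizes")
})

test_that("arm rows are bias-corrected and controls deduplicated", {
  d <- rbind(
    schema_row("e1", comparison_id = "p1_c1", sd_t = 2, n_t = 11,
               shared_control_id = "ctlA"),
    schema_row("e2", comparison_id = "p1_c2", sd_t = 3, n_t = 6,
               shared_control_id = "ctlA"))
  d <- validate_yield_data(d)
  rows <- arm_rows(d)
  expect_equal(nrow(rows), 3L)  # two treatments, one shared control
  t1 <- rows[rows$arm_id == "t:e1", ]
  expect_equal(t1$ln_sd, log(2) + 0.05, tolerance = 1e-10)
  expect_equal(t1$vi, 0.05, tolerance = 1e-10)
  expect_equal(rows$vi[rows$arm_id == "t:e2"], 0.1, tolerance = 1e-10)

  d2 <- validate_yield_data(schema_row(sd_t = 1, n_t = 2))
  expect_equal(arm_rows(d2)$vi[1], 0.5)

  # inconsistent control summaries under one shared id are an error
  d$mean_c[2] <- 11
  expect_error(arm_rows(d), "inconsistent control")
})

test_that("shared-control covariance follows the control-arm contribution", {
  expect_equal(shared_control_cov("lnVR", 10, 1, 10), 1 / 18,
               tolerance = 1e-4)
  expect_equal(shared_control_cov("lnRR", 10, 1, 10), 0.001,
               tolerance = 1e-6)
  expect_equal(shared_control_cov("lnCVR", 10, 1, 10), 0.001 + 1 / 18,
               tolerance = 1e-4)
})

test_that("sampling VCV has block structure, matching diagonal, and is PSD", {
  d <- rbind(
    schema_row("e1", comparison_id = "p1_c1", sd_t = 2, n_t = 10,
               shared_control_id = "ctlA", sd_c = 2, n_c = 10,
               mean_c = 1, mean_t = 1),
    schema_row("e2", comparison_id = "p1_c2", sd_t = 2, n_t = 10,
               shared_control_id = "ctlA", sd_c = 2, n_c = 10,
               mean_c = 1, mean_t = 1),
    schema_row("e3", publication_id = "p2", sd_t = 2, n_t = 10,
               sd_c = 2, n_c = 10, mean_c = 1, mean_t = 1))
  d <- validate_yield_data(d)
  es <- effect_sizes(d, "lnVR")
  V <- build_vcv(es)
  expect_equal(diag(V), setNames(es$vi, es$effect_id))
  expect_equal(V["e1", "e2"], 1 / 18, tolerance = 1e-10)
  expect_equal(V["e1", "e3"], 0)
  expect_true(isSymmetric(V))
  expect_gte(min(eigen(V, symmetric = TRUE)$values), 0)

  # distinct controls give a diagonal matrix; empty input a 0 x 0 matrix
  d3 <- validate_yield_data(schema_rows(c(0.2, 0.3, 0.4)))
  V3 <- build_vcv(effect_sizes(d3, "lnCVR"))
  expect_equal(V3[lower.tri(V3)], rep(0, 3))
  expect_equal(dim(build_vcv(effect_sizes(d3[0, ], "lnCVR"))), c(0L, 0L))

  # mixing effect-size types is refused
  es_mix <- rbind(effect_sizes(d3[1, ], "lnCVR"),
                  effect_sizes(d3[2, ], "lnVR"))
  expect_error(build_vcv(es_mix), "different types")
})

test_that("within-block implied correlations lie in (0, 1)", {
  set.seed(11)
  for (i in 1:20) {
    mc <- runif(1, 1, 30); sc <- runif(1, 0.5, 6)
    nc <- sample(3:30, 1)
    d <- rbind(
      schema_row("a", mean_t = runif(1, 1, 30), sd_t = runif(1, .5, 6),
                 n_t = sample(3:30, 1), mean_c = mc, sd_c = sc, n_c = nc,
                 shared_control_id = "ctl"),
      schema_row("b", comparison_id = "p1_c2", mean_t = runif(1, 1, 30),
                 sd_t = runif(1, .5, 6), n_t = sample(3:30, 1),
                 mean_c = mc, sd_c = sc, n_c = nc,
                 shared_control_id = "ctl"))
    d <- validate_yield_data(d)
    for (type in c("lnRR", "lnVR", "lnCVR")) {
      es <- effect_sizes(d, type)
      V <- build_vcv(es)
      rho <- V[1, 2] / sqrt(V[1, 1] * V[2, 2])
      expect_gt(rho, 0); expect_lt(rho, 1)
    }
  }
})

test_that("Monte-Carlo means of lnVR/lnCVR land on the true log ratios", {
  # normal arms with known parameters; the corrections exist precisely
  # to remove the small-sample bias of the naive plug-in estimators
  set.seed(101)
  nrep <- 4000; n <- 10
  xt <- matrix(rnorm(nrep * n, 10, 2), nrep)
  xc <- matrix(rnorm(nrep * n, 10, 1), nrep)
  mt <- rowMeans(xt); mc_ <- rowMeans(xc)
  st <- sqrt((rowSums(xt^2) - n * mt^2) / (n - 1))
  sc <- sqrt((rowSums(xc^2) - n * mc_^2) / (n - 1))
  vr <- lnvr(mt, st, n, mc_, sc, n)
  cvr <- lncvr(mt, st, n, mc_, sc, n)
  for (es in list(list(v = vr$yi, true = log(2)),
                  list(v = cvr$yi, true = log(2)))) {
    mc_se <- sd(es$v) / sqrt(nrep)
    expect_lt(abs(mean(es$v) - es$true), 3 * mc_se)
  }
})
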