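test_that("exact signed-rank p-values match brute-force enumeration", {
  # worked examples at n = 8
  d_pos <- 1:8
  t1 <- wilcoxon_exact(d_pos)
  expect_equal(t1$W, 36)
  expect_equal(t1$p_exact, 2 / 256)
  expect_equal(hippolaminar:::wilcoxon_exact_p(1, 8), 4 / 256)

  # exhaustive agreement with the 2^n enumeration oracle for n <= 10
  for (n in 3:10) {
    for (W in 0:(n * (n + 1) / 2)) {
      expect_equal(hippolaminar:::wilcoxon_exact_p(W, n),
                   enum_signrank_p(W, n),
                   info = sprintf("n=%d W=%d", n, W))
    }
  }

  expect_warning(wilcoxon_exact(c(0, 1, -2, 3)), "zero difference")
  expect_error(wilcoxon_exact(c(1, 1, 2)), "tied")
  expect_error(wilcoxon_exact(rnorm(25)), "n > 20")
})

test_that("the exact test is conservative on its discrete support", {
  set.seed(17)
  p <- replicate(20000, {
    d <- rnorm(8)
    r <- rank(abs(d))
    hippolaminar:::wilcoxon_exact_p(sum(r[d > 0]), 8)
  })
  rej <- mean(p <= 0.05)
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.05)
})

test_that("Hochberg step-up reproduces the worked family and its formula", {
  fam <- c(0.0078125, 0.0078125, 0.015625, 0.0390625, 1.0)
  adj <- hochberg_stepup(fam)
  expect_equal(adj[1:2], rep(0.03125, 2))
  expect_equal(adj[3], 0.046875)
  expect_equal(adj[4], 0.078125)

  expect_equal(hochberg_stepup(0.2), 0.2)          # m = 1 unchanged
  expect_equal(hochberg_stepup(rep(0.3, 4)), rep(0.3, 4))

  # invariant: matches the direct min-over-j formula on random families,
  # monotone over sorted inputs, permutation-equivariant
  set.seed(23)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    a <- hochberg_stepup(p)
    expect_equal(a, hochberg_formula(p))
    expect_true(all(diff(a[order(p)]) >= -1e-12))
    perm <- sample(length(p))
    expect_equal(hochberg_stepup(p[perm]), a[perm])
  }
})

test_that("BH adjustment matches its worked example and controls FDR", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.7), 0.7)
  set.seed(29)
  hits <- replicate(10000, min(bh_fdr(runif(5))) <= 0.05)
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 10000) + 0.005)
})

test_that("marginal and conditional R2 behave at the deterministic limit", {
  # exact line, no random variance: both R2 -> 1 and equal
  d <- data.frame(z = rep(1 + 2 * seq(0, 1, length.out = 20), 4) +
                    rnorm(80, sd = 1e-8),
                  depth = rep(seq(0, 1, length.out = 20), 4),
                  subject = rep(1:4, each = 20))
  fits <- fit_depth_models(d)
  r2 <- fits$r2$linear
  expect_equal(unname(r2["marginal"]), 1, tolerance = 1e-4)
  expect_equal(unname(r2["conditional"]), 1, tolerance = 1e-4)
  expect_lt(abs(unname(lme4::fixef(fits$fits$linear)["d"]) - 2), 1e-4)
  # conditional >= marginal always
  set.seed(5)
  d$z <- d$z + rep(rnorm(4), each = 20) + rnorm(80, sd = 0.3)
  r2b <- fit_depth_models(d)$r2$linear
  expect_gte(r2b["conditional"], r2b["marginal"])
})

test_that("depth-model slope recovery is unbiased at the study layout", {
  set.seed(41)
  slopes <- replicate(200, {
    d <- data.frame(depth = rep(seq(0, 1, length.out = 20), 8),
                    subject = factor(rep(1:8, each = 20)))
    d$z <- 1 + 2 * d$depth + rep(rnorm(8, sd = 0.5), each = 20) +
      rnorm(160, sd = 0.2)
    unname(lme4::fixef(fit_depth_models(d)$fits$linear)["d"])
  })
  expect_lt(abs(mean(slopes) / 2 - 1), 0.05)
})

test_that("Kenward-Roger df match balanced-design closed forms", {
  set.seed(7)
  # between-subject factor: ddf = n_subjects - n_groups
  g <- rep(c("a", "b"), each = 30)
  subj <- factor(rep(1:10, each = 6))
  y <- rnorm(60) + rep(rnorm(10), each = 6) + (g == "b") * 0.5
  m0 <- lme4::lmer(y ~ (1 | subj), REML = TRUE)
  m1 <- lme4::lmer(y ~ g + (1 | subj), REML = TRUE)
  kr <- kr_f_test(m0, m1)
  expect_equal(kr$df2, 8, tolerance = 1e-6)

  # within-subject covariate: ddf = N - n_subjects - 1
  subj2 <- factor(rep(1:8, each = 20))
  d <- rep(seq(0, 1, length.out = 20), 8)
  y2 <- rnorm(160) + rep(rnorm(8), each = 20) + 2 * d
  m0b <- lme4::lmer(y2 ~ (1 | subj2), REML = TRUE)
  m1b <- lme4::lmer(y2 ~ d + (1 | subj2), REML = TRUE)
  kr2 <- kr_f_test(m0b, m1b)
  expect_equal(kr2$df2, 151, tolerance = 1e-6)
  expect_equal(kr2$df1, 1)

  # identical models: no added effect
  same <- kr_f_test(m0b, m0b)
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # non-nested models are refused
  m_other <- lme4::lmer(y2 ~ poly(d, 2) + (1 | subj2), REML = TRUE)
  expect_error(kr_f_test(m1b, m_other), "not nested")
})

test_that("slope ~ density-change model recovers the planted coefficient", {
  set.seed(51)
  est <- replicate(60, {
    d <- expand.grid(subject = factor(1:8), subfield = factor(1:5))
    d$delta_rho <- runif(nrow(d), -0.3, 0.5)
    d$slope <- 3 * d$delta_rho + rnorm(8, sd = 0.3)[d$subject] +
      rnorm(5, sd = 0.3)[d$subfield] + rnorm(nrow(d), sd = 0.2)
    slope_density_model(d)$coef["estimate"]
  })
  expect_lt(abs(mean(est) / 3 - 1), 0.1)

  d <- data.frame(subject = factor(rep(1, 12)), subfield = factor(rep(1, 12)),
                  delta_rho = runif(12), slope = rnorm(12))
  expect_error(slope_density_model(d), "2 subjects and 2 subfields")
})

test_that("interaction model is symmetric, calibrated and sensitive to slope differences", {
  set.seed(61)
  base <- expand.grid(depth = seq(0, 1, length.out = 20),
                      subject = factor(1:8), level = c("x", "y"))
  # identical profiles in both levels: level and interaction explain nothing
  d0 <- base
  zx <- 1 + d0$depth[d0$level == "x"] +
    rep(rnorm(8, sd = 0.3), each = 20) +
    rnorm(sum(d0$level == "x"), sd = 0.2)
  d0$z[d0$level == "x"] <- zx
  d0$z[d0$level == "y"] <- zx
  r0 <- contrast_interaction_model(d0)
  expect_lt(r0$F[r0$effect == "level"], 1e-6)
  expect_lt(r0$F[r0$effect == "interaction"], 1e-6)
  expect_gt(min(r0$p[r0$effect != "depth"]), 0.99)

  # swapping the factor labels leaves every F unchanged
  d1 <- d0
  d1$z <- d1$z + (d1$level == "y") * (d1$depth - 0.5) * 1.5
  r1 <- contrast_interaction_model(d1)
  d1s <- d1
  d1s$level <- ifelse(d1$level == "x", "y", "x")
  r1s <- contrast_interaction_model(d1s)
  expect_equal(r1$F, r1s$F, tolerance = 1e-6)

  # a pure slope difference is detected as an interaction
  expect_lt(r1$p[r1$effect == "interaction"], 0.05)

  d_bad <- d0[d0$level == "x" | d0$subject != "1", ]
  expect_error(contrast_interaction_model(d_bad), "both factor levels")
})
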