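am_events_one_trial <- function(press = 4.4, n_volumes = 60, tr = 2.21) {
  paradigm_events(c(0, press), c(press, 17.6 - press),
                  c("AM_construction", "AM_elaboration"),
                  tr_vol = tr, n_volumes = n_volumes)
}

test_that("design construction is linear in the boxcars and drops volumes", {
  ev <- am_events_one_trial()
  d <- build_design(ev, NULL, NULL, drop_initial = 0L)
  full <- paradigm_events(0, 17.6, "math", 2.21, 60)
  d_full <- build_design(full, NULL, NULL, drop_initial = 0L)
  # construction + elaboration convolved = full-trial boxcar convolved
  expect_lt(max(abs(d$X[, "AM_construction"] + d$X[, "AM_elaboration"] -
                      d_full$X[, "math"])), 1e-9)

  # the study run: 489 volumes, first three discarded -> 486 design rows
  ev489 <- paradigm_events(c(10, 40), c(17.6, 17.6),
                           c("AM_construction", "math"), 2.21, 489)
  expect_equal(nrow(build_design(ev489, NULL, NULL)$X), 486)

  # no task events: only intercept and drift columns remain
  ev_rest <- paradigm_events(0, 10, "rest", 2.21, 120)
  d0 <- build_design(ev_rest, NULL, NULL, drop_initial = 0L)
  expect_true(all(grepl("intercept|dct", colnames(d0$X))))

  # collinear nuisance columns are rejected by name
  nuis <- cbind(d$X[, "AM_construction"], 0)
  expect_error(build_design(ev, NULL, nuis, drop_initial = 0L),
               "rank deficient")
})

test_that("condition-volume selection applies the hemodynamic shift deterministically", {
  ev <- paradigm_events(c(0, 22.1), c(17.6, 17.6), c("math", "math"),
                        tr_vol = 2.21, n_volumes = 40)
  v0 <- condition_volumes(ev, "math", shift = 0L)
  v2 <- condition_volumes(ev, "math", shift = 2L)
  expect_identical(v2, v0 + 2L)
  # repeated evaluation is identical (purely deterministic rule)
  expect_identical(condition_volumes(ev, "math", 2L),
                   condition_volumes(ev, "math", 2L))
  # dropping initial volumes renumbers into the retained series
  v_drop <- condition_volumes(ev, "math", 2L, drop_initial = 3L)
  expect_identical(v_drop, v2[v2 > 3] - 3L)
})

test_that("rWLS approaches OLS in the homoscedastic limit and recovers beta exactly", {
  set.seed(9)
  n <- 120
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("intercept", "a", "b")
  beta <- c(2, 1, -0.5)
  # noiseless: exact interpolation (degenerate variances are flagged)
  Y0 <- matrix(X %*% beta, nrow = 1)
  expect_warning(f0 <- rwls_fit(Y0, X), "degenerate")
  expect_lt(max(abs(f0$coefficients[, 1] - beta)), 1e-9)

  # homoscedastic data: the per-volume variance estimates pool over the
  # response units, so the weights equalize and the fit converges to OLS as
  # the pooled dimension grows
  se <- sqrt(diag(solve(crossprod(X))))        # sigma = 1
  dev_at <- function(nd) {
    Y <- matrix(rep(as.numeric(X %*% beta), each = nd), nd, n) +
      matrix(rnorm(nd * n), nd, n)
    f <- rwls_fit(Y, X)
    c(dev = mean(abs(f$coefficients - qr.solve(X, t(Y))) / se),
      wsd = sd(f$weights))
  }
  small <- dev_at(50)
  big <- dev_at(20000)
  expect_lt(big["dev"], small["dev"])          # shrinks with pooling
  expect_lt(big["dev"], 0.03)                  # near-OLS at 2e4 units
  expect_lt(big["wsd"], 0.05)                  # weights equal within MC error
})

test_that("rWLS downweights corrupted volumes and beats OLS there", {
  set.seed(10)
  n <- 120; nd <- 30
  X <- cbind(1, rnorm(n)); colnames(X) <- c("intercept", "a")
  bad <- 1:5
  err <- replicate(50, {
    e <- matrix(rnorm(nd * n), nd, n)
    e[, bad] <- e[, bad] * 10                  # 100x variance
    Y <- matrix(rep(as.numeric(X %*% c(0, 1)), each = nd), nd, n) + e
    f <- rwls_fit(Y, X)
    ols <- qr.solve(X, t(Y))
    c(wratio = unname(max(f$weights[bad]) / median(f$weights)),
      rwls = sqrt(mean((f$coefficients["a", ] - 1)^2)),
      ols = sqrt(mean((ols["a", ] - 1)^2)))
  })
  expect_lt(mean(err["wratio", ]), 1 / 50)
  expect_lt(mean(err["rwls", ]), mean(err["ols", ]))
})

test_that("baseline z-transform standardizes against the math volumes", {
  set.seed(13)
  Y <- matrix(rnorm(5 * 100, mean = 50, sd = 4), 5, 100)
  mv <- 11:40
  Z <- baseline_z(Y, mv)
  expect_equal(rowMeans(Z[, mv]), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(Z[, mv], 1, sd), rep(1, 5), tolerance = 1e-12)
  # affine invariance of z
  Z2 <- baseline_z(3 * Y + 7, mv)
  expect_equal(Z2, Z, tolerance = 1e-10)
  # activation of +2 math-SD appears as z ~ 2
  Y3 <- Y
  Y3[, 60:100] <- Y3[, 60:100] + 2 * 4
  Z3 <- baseline_z(Y3, mv)
  expect_lt(abs(mean(Z3[, 60:100]) - 2), 0.2)
  expect_error(baseline_z(Y, 1:2), "at least 3")
  expect_error(baseline_z(matrix(1, 2, 10), 1:5), "zero SD")
})

test_that("laminar contrasts are the stated coefficient combinations", {
  B <- rbind(AM_construction = c(2, 1), AM_elaboration = c(1, 1),
             math = c(0, 1))
  ctr <- laminar_contrasts(B)
  expect_equal(ctr$memory_gt_math, c(1.5, 0))
  expect_equal(ctr$pre_gt_post, c(1, 0))
  expect_error(laminar_contrasts(B[1:2, , drop = FALSE]), "math")
})

test_that("contrast estimability holds for any complete event table", {
  ev <- paradigm_events(c(0, 22.1, 44.2), c(17.6, 17.6, 17.6),
                        c("AM_construction", "math", "AM_elaboration"),
                        2.21, 120)
  d <- build_design(ev, NULL, NULL, drop_initial = 0L)
  sub <- d$X[, c("AM_construction", "AM_elaboration", "math")]
  # both contrast vectors lie in the row space of the condition sub-design
  cmat <- rbind(memory = c(0.5, 0.5, -1), pre_post = c(1, -1, 0))
  fitted <- t(sub) %*% sub %*% solve(crossprod(sub), t(cmat))
  expect_lt(max(abs(t(fitted) - cmat)), 1e-6)
})
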