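test_that("standard index matches the direct sum and the covariance identity", {
  rk <- fractional_rank(1:4)
  expect_equal(concentration_index(c(0, 0, 1, 1), rk)$value, 0.5)

  # constant outcome carries no inequality
  expect_equal(concentration_index(rep(3.7, 10), fractional_rank(runif(10)))$value, 0)

  set.seed(101)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    s <- random_binary_sample(n)
    inc <- sample(seq_len(100), n) # distinct incomes, equal weights
    rk <- fractional_rank(inc)
    got <- concentration_index(s$h, rk)$value
    expect_equal(got, eq1_concentration(s$h, inc), tolerance = 1e-10)
    expect_equal(got, cov_identity_index(s$h, inc), tolerance = 1e-10)
  }
})

test_that("standard index rejects degenerate outcomes", {
  rk <- fractional_rank(1:4)
  expect_error(concentration_index(rep(0, 4), rk), "undefined")
  expect_error(concentration_index(c(-1, 0, 1, 1), rk), "non-negative")
  expect_error(concentration_index(c(0, 1, 1), rk), "length")
})

test_that("Erreygers index: maximal inequality, mirror and transfer properties", {
  rk <- fractional_rank(1:4)
  expect_identical(erreygers_index(c(0, 0, 1, 1), rk)$value, 1)

  # moving one use from a rich to a poor person is a pro-poor change
  expect_lt(erreygers_index(c(0, 1, 1, 0), rk)$value, 1)

  set.seed(202)
  for (rep in 1:20) {
    s <- random_binary_sample(sample(5:40, 1))
    rk <- fractional_rank(s$income, s$w)
    e <- erreygers_index(s$h, rk, s$w)$value
    expect_equal(erreygers_index(1 - s$h, rk, s$w)$value, -e, tolerance = 1e-12)
    expect_gte(e, -1)
    expect_lte(e, 1)
  }
})

test_that("Erreygers index is invariant to increments and linear rescaling", {
  set.seed(303)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    h <- runif(n) # bounded continuous outcome in (0,1)
    inc <- rlnorm(n)
    w <- runif(n, 0.5, 2)
    rk <- fractional_rank(inc, w)
    e <- erreygers_index(h, rk, w, bounds = c(0, 1))$value
    cst <- runif(1, -2, 2)
    expect_equal(erreygers_index(h + cst, rk, w, bounds = c(0, 1) + cst)$value,
                 e, tolerance = 1e-12)
    a <- runif(1, -1, 1); b <- runif(1, 0.5, 3)
    expect_equal(erreygers_index(a + b * h, rk, w,
                                 bounds = a + b * c(0, 1))$value,
                 e, tolerance = 1e-12)
  }
})

test_that("Wagstaff index and the Erreygers-Wagstaff identity", {
  rk <- fractional_rank(1:4)
  expect_equal(wagstaff_index(c(0, 0, 1, 1), rk)$value, 1)
  expect_error(wagstaff_index(rep(1, 4), rk), "bound")

  set.seed(404)
  for (rep in 1:20) {
    s <- random_binary_sample(sample(5:40, 1))
    rk <- fractional_rank(s$income, s$w)
    W <- wagstaff_index(s$h, rk, s$w)$value
    E <- erreygers_index(s$h, rk, s$w)$value
    hbar <- sum(s$w * s$h) / sum(s$w)
    expect_equal(E, 4 * hbar * (1 - hbar) * W, tolerance = 1e-12)
  }
})

test_that("indices are invariant to row permutation and to record duplication with halved weights", {
  set.seed(505)
  s <- random_binary_sample(25)
  rk <- fractional_rank(s$income, s$w)
  base <- c(concentration_index(s$h, rk, s$w)$value,
            erreygers_index(s$h, rk, s$w)$value,
            wagstaff_index(s$h, rk, s$w)$value)

  perm <- sample(25)
  rkp <- fractional_rank(s$income[perm], s$w[perm])
  expect_equal(concentration_index(s$h[perm], rkp, s$w[perm])$value, base[1])
  expect_equal(erreygers_index(s$h[perm], rkp, s$w[perm])$value, base[2])

  h2 <- rep(s$h, each = 2); inc2 <- rep(s$income, each = 2)
  w2 <- rep(s$w / 2, each = 2)
  rk2 <- fractional_rank(inc2, w2)
  expect_equal(concentration_index(h2, rk2, w2)$value, base[1], tolerance = 1e-12)
  expect_equal(erreygers_index(h2, rk2, w2)$value, base[2], tolerance = 1e-12)
  expect_equal(wagstaff_index(h2, rk2, w2)$value, base[3], tolerance = 1e-12)
})

test_that("concentration curve endpoints, shape, and area identity", {
  rk <- fractional_rank(1:10)
  cc <- concentration_curve(rep(2, 10), rk)
  expect_equal(cc$points[, 1], cc$points[, 2]) # equality line

  rk4 <- fractional_rank(1:4)
  cc2 <- concentration_curve(c(0, 0, 1, 1), rk4)
  expect_true(any(cc2$points[, 1] == 0.5 & cc2$points[, 2] == 0))

  set.seed(606)
  for (rep in 1:20) {
    s <- random_binary_sample(sample(5:60, 1))
    rk <- fractional_rank(s$income, s$w)
    cc <- concentration_curve(s$h, rk, s$w)
    pts <- cc$points
    expect_equal(pts[1, ], c(pop_share = 0, outcome_share = 0))
    expect_equal(pts[nrow(pts), ], c(pop_share = 1, outcome_share = 1))
    expect_true(all(diff(pts[, 1]) >= 0) && all(diff(pts[, 2]) >= 0))
    expect_equal(curve_index(cc), concentration_index(s$h, rk, s$w)$value,
                 tolerance = 1e-6)
  }
  expect_error(concentration_curve(rep(0, 4), rk4), "zero")
})

test_that("robust-regression CI reproduces the direct point estimate", {
  set.seed(707)
  s <- random_binary_sample(200)
  rk <- fractional_rank(s$income, s$w)
  for (v in c("standard", "erreygers", "wagstaff")) {
    direct <- switch(v,
      standard = concentration_index(s$h, rk, s$w)$value,
      erreygers = erreygers_index(s$h, rk, s$w)$value,
      wagstaff = wagstaff_index(s$h, rk, s$w)$value)
    est <- index_ci(s$h, rk, s$w, variant = v, method = "robust_regression")
    expect_equal(est$value, direct, tolerance = 1e-10)
    expect_true(est$ci_low <= est$value && est$value <= est$ci_high)
  }
})

test_that("a constant outcome has zero index and zero standard error", {
  rk <- fractional_rank(1:8)
  est <- index_ci(rep(1, 8), rk, variant = "erreygers")
  expect_equal(est$value, 0)
  expect_equal(est$se, 0)
  expect_equal(c(est$ci_low, est$ci_high), c(0, 0))
})

test_that("bootstrap CIs are seed-deterministic and agree with the regression method", {
  set.seed(808)
  g <- generate_survey(generator_config(
    n_persons = 1500, seed = 21, covariates = list(),
    outcomes = list(outcome_def("u", model = "linear_rank", a = 0.4, b = 0.3))
  ))
  d <- g$data
  rk <- fractional_rank(d$income_pc, d$weight)
  b1 <- index_ci(d$u, rk, d$weight, variant = "erreygers", method = "bootstrap",
                 n_boot = 200, seed = 5, cluster_id = d$psu_id)
  b2 <- index_ci(d$u, rk, d$weight, variant = "erreygers", method = "bootstrap",
                 n_boot = 200, seed = 5, cluster_id = d$psu_id)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$ci_high, b2$ci_high)

  rr <- index_ci(d$u, rk, d$weight, variant = "erreygers",
                 method = "robust_regression")
  expect_equal(b1$value, rr$value, tolerance = 1e-10)
  # intervals from the two methods overlap
  expect_true(b1$ci_low <= rr$ci_high && rr$ci_low <= b1$ci_high)
  expect_error(index_ci(d$u, rk, d$weight, method = "bootstrap"), "seed")
})

test_that("inequality classification follows the confidence interval", {
  expect_identical(classify_inequality(make_estimate(0.265, 0.235, 0.294)),
                   "pro-rich")
  expect_identical(classify_inequality(make_estimate(0.010, 0.004, 0.016)),
                   "pro-rich")
  expect_identical(classify_inequality(make_estimate(-0.02, -0.05, -0.001)),
                   "pro-poor")
  expect_identical(classify_inequality(make_estimate(0, -0.1, 0.1)),
                   "indeterminate")
  expect_error(classify_inequality(make_estimate(0.1, NA, NA)), "interval")
})
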