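test_that("intercept-only probit recovers the probit-inverse of the mean", {
  set.seed(1)
  n <- 1000
  y <- rep(c(1, 0), times = c(700, 300))
  df <- data.frame(dummy = rnorm(n))
  des <- covariate_design(df)
  fit <- fit_probit(y, des)
  expect_equal(unname(fit$coefficients), qnorm(0.7), tolerance = 1e-6)
  expect_equal(unique(round(fit$fitted, 10)), 0.7)
  expect_true(fit$converged)
})

test_that("probit parameter recovery on generator output with known coefficients", {
  g <- generate_survey(generator_config(n_persons = 50000, seed = 77))
  d <- g$data
  # reconstruct the exact latent regressors of the generating model
  d$income_rank <- fractional_rank(d$income_pc, d$weight)$ranks
  d$female <- as.numeric(d$sex == "female")
  d$age_decades <- d$age / 10
  des <- covariate_design(d, c("insurance", "education_secondary",
                               "chronic_condition", "income_rank",
                               "female", "age_decades"))
  fit <- fit_probit(d$doctor_visit, des, d$weight)
  truth <- unlist(g$truth$outcomes$doctor_visit$coefficients)
  for (nm in names(truth)) {
    idx <- if (nm == "(Intercept)") "(Intercept)" else nm
    expect_lt(abs(fit$coefficients[[idx]] - truth[[nm]]),
              3.5 * fit$se[[idx]] + 0.01)
  }
})

test_that("probit rejects non-binary outcomes and perfect separation", {
  df <- data.frame(x = c(rep(0, 20), rep(1, 20)))
  des <- covariate_design(df, "x")
  expect_error(fit_probit(rep(0.5, 40), des), "binary")
  y_sep <- df$x # outcome identical to the covariate
  expect_error(fit_probit(y_sep, des), "separation")
})

test_that("design construction enforces rank and constant-column rules", {
  df <- data.frame(a = c(1, 0, 1, 0), b = c(2, 2, 2, 2), c = c(2, 0, 2, 0))
  expect_error(covariate_design(df, c("a", "b")), "constant")
  expect_error(covariate_design(df, c("a", "c")), "rank deficient")
  expect_error(covariate_design(df, c("a", "z")), "not found")

  df2 <- data.frame(g = c("lo", "mid", "hi", "mid", "hi", "lo"),
                    x = rnorm(6))
  des <- covariate_design(df2, c("g", "x"), reference = list(g = "lo"))
  expect_setequal(des$columns, c("ghi", "gmid", "x"))
  expect_true(all(des$binary[c("ghi", "gmid")]))
  expect_false(des$binary[["x"]])
})

test_that("continuous partial effects equal the analytic derivative average", {
  z <- c(-1.2, -0.3, 0.1, 0.8, 2.0)
  b <- 0.7
  df <- data.frame(z = z)
  des <- covariate_design(df, "z")
  fit <- structure(list(
    coefficients = c("(Intercept)" = 0, z = b),
    eta = b * z, weights = rep(1, 5), n = 5
  ), class = "probit_fit")
  pe <- partial_effects(fit, des)
  expect_equal(unname(pe$effects[["z"]]), mean(b * dnorm(b * z)),
               tolerance = 1e-12)
  expect_identical(unname(pe$averaging_rule[["z"]]), "overall_mean")
})

test_that("binary partial effects use the subgroup rule and report the overall mean too", {
  # heterogeneous effects: the discrete change depends on the other covariate
  df <- data.frame(x = c(1, 1, 0, 0, 0, 1), z = c(-2, 0, 1, -1, 2, 1.5))
  des <- covariate_design(df, c("x", "z"))
  beta <- c("(Intercept)" = -0.2, x = 0.9, z = 0.5)
  eta <- drop(des$X %*% beta)
  fit <- structure(list(coefficients = beta, eta = eta,
                        weights = rep(1, 6), n = 6), class = "probit_fit")
  pe <- partial_effects(fit, des)

  eta1 <- drop(cbind(1, 1, df$z) %*% beta)
  eta0 <- drop(cbind(1, 0, df$z) %*% beta)
  per_obs <- pnorm(eta1) - pnorm(eta0)
  expect_equal(unname(pe$effects[["x"]]), mean(per_obs[df$x == 1]),
               tolerance = 1e-12)
  expect_equal(unname(pe$effects_overall[["x"]]), mean(per_obs),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pe$effects[["x"]], pe$effects_overall[["x"]])))
  expect_identical(unname(pe$averaging_rule[["x"]]), "subgroup_mean")
})

test_that("zero-coefficient covariates have exactly zero partial effect", {
  df <- data.frame(x = c(0, 1, 0, 1), z = c(0.3, -1, 2, 0.5))
  des <- covariate_design(df, c("x", "z"))
  beta <- c("(Intercept)" = 0.1, x = 0, z = 0)
  fit <- structure(list(coefficients = beta, eta = rep(0.1, 4),
                        weights = rep(1, 4), n = 4), class = "probit_fit")
  pe <- partial_effects(fit, des)
  expect_identical(unname(pe$effects[["x"]]), 0)
  expect_identical(unname(pe$effects[["z"]]), 0)
})

test_that("generalized concentration index follows the covariance form", {
  rk <- fractional_rank(1:4)
  expect_equal(generalized_concentration(rep(5, 4), rk), 0)
  expect_equal(generalized_concentration(c(0, 0, 1, 1), rk), 0.25)

  n <- 10000
  rkn <- fractional_rank(seq_len(n))
  expect_equal(generalized_concentration(rkn$ranks, rkn), 1 / 6,
               tolerance = 1e-3)
})

test_that("intercept-only decomposition puts all inequality in the residual", {
  set.seed(2)
  s <- random_binary_sample(200)
  rk <- fractional_rank(s$income, s$w)
  des <- covariate_design(data.frame(row = seq_along(s$h)))
  dec <- decompose_index(s$h, des, rk, s$w)
  expect_equal(nrow(dec$table), 0)
  expect_equal(dec$residual_contribution, dec$total_index)
})

test_that("decomposition is exactly additive and closure matches the direct residual GC", {
  set.seed(3)
  for (rep in 1:8) {
    n <- sample(150:400, 1)
    df <- data.frame(
      x1 = rbinom(n, 1, 0.4),
      x2 = rnorm(n),
      x3 = rbinom(n, 1, 0.6)
    )
    inc <- rlnorm(n)
    w <- runif(n, 0.5, 2)
    eta <- -0.3 + 0.8 * df$x1 + 0.4 * df$x2 + 2 * (rank(inc) / n - 0.5)
    h <- rbinom(n, 1, pnorm(eta))
    if (length(unique(h)) == 1) h[1] <- 1 - h[1]
    rk <- fractional_rank(inc, w)
    des <- covariate_design(df, c("x1", "x2", "x3"))
    dec <- decompose_index(h, des, rk, w, share_floor = 0)
    expect_equal(sum(dec$table$contribution) + dec$residual_contribution,
                 dec$total_index, tolerance = 1e-10)
    expect_equal(dec$residual_contribution, dec$residual_gc_direct,
                 tolerance = 1e-10)
  }
})

test_that("a covariate uncorrelated with income rank contributes exactly zero", {
  h <- c(1, 0, 1, 0)
  x <- c(1, 0, 0, 1) # symmetric around the rank midpoint: GC(x) = 0
  rk <- fractional_rank(1:4)
  des <- covariate_design(data.frame(x = x), "x")
  dec <- decompose_index(h, des, rk, share_floor = 0)
  expect_identical(dec$table$gc, 0)
  expect_identical(dec$table$contribution, 0)
})

test_that("re-decomposing the linear approximation reproduces the contributions", {
  set.seed(4)
  n <- 500
  df <- data.frame(x1 = rbinom(n, 1, 0.3), x2 = rnorm(n))
  inc <- rlnorm(n)
  h <- rbinom(n, 1, pnorm(-0.4 + 0.9 * df$x1 + 0.3 * df$x2))
  rk <- fractional_rank(inc)
  des <- covariate_design(df, c("x1", "x2"))
  dec <- decompose_index(h, des, rk, share_floor = 0)
  # contributions recomputed from the linearized coefficients and GCs alone
  redone <- 4 * dec$partials$effects *
    vapply(des$columns, function(cn)
      generalized_concentration(des$X[, cn], rk), numeric(1))
  expect_equal(unname(dec$table$contribution), unname(redone), tolerance = 1e-12)
})

test_that("contribution shares are plain arithmetic and support role grouping", {
  fake <- structure(list(
    table = data.frame(term = c("A", "B"), role = c("enabling", "need"),
                       beta_m = c(NA, NA), beta_m_overall = c(NA, NA),
                       averaging_rule = c("", ""), gc = c(NA, NA),
                       contribution = c(0.08, -0.02), share = c(0.8, -0.2),
                       stringsAsFactors = FALSE),
    residual_contribution = 0.04,
    total_index = 0.10,
    role_subtotals = data.frame(role = c("enabling", "need"),
                                contribution = c(0.08, -0.02),
                                share = c(0.8, -0.2)),
    shares_suppressed = FALSE, share_floor = 0.01
  ), class = "decomposition")
  sh <- contribution_shares(fake)
  expect_equal(sh$share_pct, c(80, -20, 40))
  expect_equal(sum(sh$share_pct), 100)
  by_role <- contribution_shares(fake, "role")
  expect_setequal(by_role$term, c("enabling", "need", "residual"))

  fake$shares_suppressed <- TRUE
  expect_error(contribution_shares(fake), "suppressed")
})

test_that("small-index decompositions suppress shares but keep contributions", {
  set.seed(5)
  n <- 400
  df <- data.frame(x = rbinom(n, 1, 0.5))
  h <- rbinom(n, 1, 0.5) # outcome independent of income
  if (length(unique(h)) == 1) h[1] <- 1 - h[1]
  rk <- fractional_rank(runif(n))
  dec <- decompose_index(h, covariate_design(df, "x"), rk, share_floor = 0.5)
  expect_true(dec$shares_suppressed)
  expect_true(all(is.na(dec$table$share)))
  expect_false(anyNA(dec$table$contribution))
})
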