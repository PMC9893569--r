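# Independent oracles and small fixture builders used across the suite.

# Literal equal-weight concentration-index sum: order by income, assign
# fractional ranks (i - 0.5)/n, and evaluate 2/(n hbar) * sum(h_i R_i) - 1
# term by term. Deliberately independent of the package's covariance path.
eq1_concentration <- function(h, income) {
  n <- length(h)
  ord <- order(income)
  hs <- h[ord]
  R <- (seq_len(n) - 0.5) / n
  s <- 0
  for (i in seq_len(n)) s <- s + hs[i] * R[i]
  2 * s / (n * mean(h)) - 1
}

# Weighted covariance oracle (population denominator), written independently.
cov_identity_index <- function(h, income, w = rep(1, length(h))) {
  r <- fractional_rank(income, w)$ranks
  W <- sum(w)
  hbar <- sum(w * h) / W
  2 * sum(w * (h - hbar) * (r - sum(w * r) / W)) / W / hbar
}

random_binary_sample <- function(n, force_variation = TRUE) {
  h <- rbinom(n, 1, runif(1, 0.2, 0.8))
  if (force_variation && length(unique(h)) == 1) h[sample(n, 1)] <- 1 - h[1]
  list(h = h, income = runif(n), w = runif(n, 0.5, 2))
}

make_estimate <- function(value, ci_low, ci_high) {
  est <- hcineq:::.new_index_estimate("erreygers", value, 0.5, 100,
                                      ci_low = ci_low, ci_high = ci_high,
                                      ci_method = "robust_regression")
  est
}

# Handcrafted six-person table exercising the screening eligibility rules:
# two eligible women (25-59), one woman aged 70, two men, one woman aged 20.
eligibility_fixture <- function() {
  df <- data.frame(
    person_id = 1:6,
    household_id = 1:6,
    region = rep("South", 6),
    age = c(30, 45, 70, 40, 55, 20),
    sex = c("female", "female", "female", "male", "male", "female"),
    income_pc = c(100, 900, 400, 250, 600, 120),
    weight = rep(1, 6),
    pap = c(1L, 0L, 1L, NA, NA, 1L),
    stringsAsFactors = FALSE
  )
  df$pap[df$sex != "female" | df$age < 25 | df$age > 59] <- NA
  mapping <- list(
    person_id = "person_id", household_id = "household_id",
    region = "region", age = "age", sex = "sex",
    income = "income_pc", weight = "weight",
    covariates = character(0), covariate_roles = list(),
    outcomes = list(pap = list(
      column = "pap",
      eligibility = list(sex = "female", age_min = 25, age_max = 59),
      recode_zero_col = NULL
    )),
    column_types = lapply(df, function(x) class(x)[1])
  )
  validate_microdata(df, mapping)
}
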