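#' @title Concentration indices for health variables
#' @description Standard, Erreygers-corrected and Wagstaff-corrected
#'   concentration indices over a weighted income ranking, with uncertainty.
#' @name concentration
NULL

.new_index_estimate <- function(variant, value, mean_outcome, n_effective,
                                bounds = c(0, 1), se = NA_real_,
                                ci_low = NA_real_, ci_high = NA_real_,
                                ci_method = "none", ci_level = 0.95,
                                n = NA_integer_) {
  structure(
    list(
      variant = variant,
      value = value,
      mean_outcome = mean_outcome,
      n = n,
      n_effective = n_effective,
      bounds = bounds,
      se = se,
      ci_low = ci_low,
      ci_high = ci_high,
      ci_method = ci_method,
      ci_level = ci_level
    ),
    class = "index_estimate"
  )
}

#' @export
print.index_estimate <- function(x, ...) {
  cat(sprintf("<index_estimate> %s concentration index\n", x$variant))
  cat(sprintf("  value = %.4f  (mean outcome = %.4f, effective n = %.1f)\n",
              x$value, x$mean_outcome, x$n_effective))
  if (!is.na(x$se)) {
    cat(sprintf("  se = %.4f, %d%% CI [%.4f, %.4f] (%s)\n",
                x$se, round(100 * x$ci_level), x$ci_low, x$ci_high, x$ci_method))
  }
  invisible(x)
}

#' Standard concentration index
#'
#' Twice the area between the concentration curve and the line of equality,
#' computed as the weighted sum
#' \deqn{C(h) = \frac{1}{\bar h} \sum_i \frac{w_i}{W} h_i (2 R_i - 1)}
#' which, because the weighted mean rank is exactly 0.5, equals the covariance
#' form \eqn{2\,\mathrm{cov}_w(h, R)/\bar h}. With equal weights and distinct
#' incomes this reduces to the textbook unweighted formula with ranks
#' \eqn{(i-0.5)/n}. Positive values indicate concentration among the rich
#' (pro-rich), negative among the poor (pro-poor).
#'
#' @param h non-negative outcome vector with positive weighted mean (binary
#'   utilisation indicators are the common case).
#' @param ranked a [fractional_rank()] result aligned index-for-index with `h`.
#' @param weights positive weights; `NULL` uses the weights stored in `ranked`.
#' @return An `index_estimate` with `variant = "standard"`.
#' @examples
#' r <- fractional_rank(1:4)
#' concentration_index(c(0, 0, 1, 1), r)$value  # 0.5
#' @export
concentration_index <- function(h, ranked, weights = NULL) {
  weights <- .check_alignment(h, ranked, weights)
  if (any(h < 0)) {
    stop("the standard concentration index requires a non-negative outcome",
         call. = FALSE)
  }
  hbar <- .wmean(h, weights)
  if (hbar <= 0) {
    stop("the concentration index is undefined: weighted mean of the outcome is zero",
         call. = FALSE)
  }
  value <- sum((weights / sum(weights)) * h * (2 * ranked$ranks - 1)) / hbar
  .new_index_estimate("standard", value, hbar, .effective_n(weights),
                      bounds = range(h), n = length(h))
}

#' Erreygers-corrected concentration index
#'
#' Correction of the standard index for bounded (especially binary) health
#' variables: \eqn{E(h) = \frac{4\bar h}{h_{max} - h_{min}} C(h)}, implemented
#' through the equivalent covariance form
#' \eqn{E(h) = 8\,\mathrm{cov}_w(h, R)/(h_{max}-h_{min})}. The corrected index
#' satisfies mirror symmetry (\eqn{E(1-h) = -E(h)} for binary outcomes),
#' transfer sensitivity, and invariance to equal increments and to positive
#' linear rescalings of the outcome (with bounds transformed identically).
#'
#' @inheritParams concentration_index
#' @param bounds numeric pair `c(h_min, h_max)` of the outcome's feasible
#'   bounds; the default `c(0, 1)` fits binary indicators.
#' @return An `index_estimate` with `variant = "erreygers"`, value in
#'   \eqn{[-1, 1]}.
#' @examples
#' r <- fractional_rank(1:4)
#' erreygers_index(c(0, 0, 1, 1), r)$value  # 1: richest half uses, poorest does not
#' @export
erreygers_index <- function(h, ranked, weights = NULL, bounds = c(0, 1)) {
  weights <- .check_alignment(h, ranked, weights)
  .check_bounds(bounds)
  if (any(h < bounds[1]) || any(h > bounds[2])) {
    stop("outcome values fall outside the stated bounds", call. = FALSE)
  }
  value <- 8 * .wcov(h, ranked$ranks, weights) / (bounds[2] - bounds[1])
  .new_index_estimate("erreygers", value, .wmean(h, weights),
                      .effective_n(weights), bounds = bounds, n = length(h))
}

#' Wagstaff-corrected concentration index
#'
#' Alternative normalization for bounded outcomes,
#' \eqn{W(h) = \frac{\bar h (h_{max} - h_{min})}{(h_{max} - \bar h)(\bar h - h_{min})} C(h)},
#' which for binary 0/1 outcomes simplifies to \eqn{C(h)/(1 - \bar h)}. It is
#' linked to the Erreygers index by the exact identity
#' \eqn{E(h) = 4 \bar h (1 - \bar h) W(h)} (binary bounds). Undefined when the
#' mean sits at either bound.
#'
#' @inheritParams erreygers_index
#' @return An `index_estimate` with `variant = "wagstaff"`.
#' @export
wagstaff_index <- function(h, ranked, weights = NULL, bounds = c(0, 1)) {
  weights <- .check_alignment(h, ranked, weights)
  .check_bounds(bounds)
  if (any(h < bounds[1]) || any(h > bounds[2])) {
    stop("outcome values fall outside the stated bounds", call. = FALSE)
  }
  hbar <- .wmean(h, weights)
  if (hbar <= bounds[1] || hbar >= bounds[2]) {
    stop("the Wagstaff index is undefined when the mean outcome sits at a bound",
         call. = FALSE)
  }
  # hbar * range / ((hmax - hbar)(hbar - hmin)) * C, with C = 2 cov / hbar
  value <- 2 * .wcov(h, ranked$ranks, weights) * (bounds[2] - bounds[1]) /
    ((bounds[2] - hbar) * (hbar - bounds[1]))
  .new_index_estimate("wagstaff", value, hbar, .effective_n(weights),
                      bounds = bounds, n = length(h))
}

.check_bounds <- function(bounds) {
  if (length(bounds) != 2 || !is.numeric(bounds) || bounds[2] <= bounds[1]) {
    stop("`bounds` must be a numeric pair c(h_min, h_max) with h_max > h_min",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Fast scalar index used inside bootstrap loops: no object construction.
# Ranks are recomputed from scratch so resampling uncertainty includes the
# rank estimation step.
.index_value <- function(h, income, weights, variant, bounds = c(0, 1)) {
  ord <- order(income)
  w_s <- weights[ord]
  inc_s <- income[ord]
  W <- sum(w_s)
  block <- cumsum(!duplicated(inc_s))
  block_w <- as.numeric(rowsum(w_s, block))
  block_rank <- (cumsum(block_w) - block_w + block_w / 2) / W
  R <- block_rank[block]
  hs <- h[ord]
  hbar <- sum(w_s * hs) / W
  cv <- sum(w_s * (hs - hbar) * (R - 0.5)) / W
  switch(variant,
    standard = if (hbar <= 0) NA_real_ else 2 * cv / hbar,
    erreygers = 8 * cv / (bounds[2] - bounds[1]),
    wagstaff = if (hbar <= bounds[1] || hbar >= bounds[2]) NA_real_ else
      2 * cv * (bounds[2] - bounds[1]) / ((bounds[2] - hbar) * (hbar - bounds[1])),
    stop("unknown variant: ", variant, call. = FALSE)
  )
}

#' Concentration curve
#'
#' Cumulative weighted share of the outcome against the cumulative weighted
#' population share, persons ordered from poorest to richest. Persons tied on
#' income are merged into a single segment so the curve does not depend on
#' within-tie ordering. Twice the signed area between the 45-degree equality
#' line and the curve equals the standard concentration index.
#'
#' @inheritParams concentration_index
#' @return An object of class `concentration_curve` with a two-column matrix
#'   `points` (`pop_share`, `outcome_share`) starting at (0,0) and ending at
#'   (1,1).
#' @export
concentration_curve <- function(h, ranked, weights = NULL) {
  weights <- .check_alignment(h, ranked, weights)
  if (any(h < 0)) stop("the concentration curve requires a non-negative outcome",
                       call. = FALSE)
  total_h <- sum(weights * h)
  if (total_h <= 0) {
    stop("the concentration curve is undefined: total weighted outcome is zero",
         call. = FALSE)
  }
  ord <- ranked$order_permutation
  w_s <- weights[ord]
  h_s <- h[ord]
  # merge tie blocks (equal ranks along the sorted order)
  block <- cumsum(!duplicated(ranked$ranks[ord]))
  bw <- as.numeric(rowsum(w_s, block))
  bh <- as.numeric(rowsum(w_s * h_s, block))
  pop <- c(0, cumsum(bw) / sum(bw))
  out <- c(0, cumsum(bh) / total_h)
  pop[length(pop)] <- 1
  out[length(out)] <- 1
  structure(list(points = cbind(pop_share = pop, outcome_share = out)),
            class = "concentration_curve")
}

#' Standard index recovered from a concentration curve
#'
#' Evaluates twice the signed area between the diagonal and the (piecewise
#' linear) curve by exact trapezoidal integration.
#'
#' @param curve a [concentration_curve()] result.
#' @return scalar index value.
#' @export
curve_index <- function(curve) {
  stopifnot(inherits(curve, "concentration_curve"))
  p <- curve$points[, 1]
  l <- curve$points[, 2]
  area_under <- sum(diff(p) * (l[-1] + l[-length(l)]) / 2)
  1 - 2 * area_under
}

#' @export
plot.concentration_curve <- function(x, ...,
                                     xlab = "cumulative population share (poorest to richest)",
                                     ylab = "cumulative outcome share") {
  graphics::plot(x$points[, 1], x$points[, 2], type = "l",
                 xlab = xlab, ylab = ylab, xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Confidence intervals for a concentration index
#'
#' Two estimators of the sampling uncertainty of the standard, Erreygers or
#' Wagstaff index:
#'
#' * `"robust_regression"` — the "convenient regression": weighted least
#'   squares of a transformed outcome on the fractional rank whose slope is
#'   exactly the index, with heteroskedasticity-robust (HC1) standard errors
#'   and a normal-approximation interval.
#' * `"bootstrap"` — percentile interval over `n_boot` resamples; when
#'   `cluster_id` is supplied whole clusters (e.g. PSUs) are resampled with
#'   replacement. Ranks are recomputed within every resample. Resamples on
#'   which the index is undefined (e.g. an all-zero outcome for the standard
#'   variant) are redrawn, up to a cap, and the redraw count is recorded.
#'
#' A two-sided p-value for index = 0 and its significance stars
#' (* p < 0.1, ** p < 0.05, *** p < 0.01) are attached.
#'
#' @inheritParams erreygers_index
#' @param variant one of `"standard"`, `"erreygers"`, `"wagstaff"`.
#' @param method `"robust_regression"` (default) or `"bootstrap"`.
#' @param ci_level confidence level, default 0.95.
#' @param n_boot number of bootstrap resamples (>= 50).
#' @param seed integer seed, required for the bootstrap.
#' @param cluster_id optional cluster labels for a clustered bootstrap.
#' @return An `index_estimate` with `se`, `ci_low`, `ci_high`, `p_value` and
#'   `stars` filled in.
#' @export
index_ci <- function(h, ranked, weights = NULL,
                     variant = c("erreygers", "standard", "wagstaff"),
                     method = c("robust_regression", "bootstrap"),
                     ci_level = 0.95, n_boot = 500, seed = NULL,
                     cluster_id = NULL, bounds = c(0, 1)) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  weights <- .check_alignment(h, ranked, weights)
  est <- switch(variant,
    standard = concentration_index(h, ranked, weights),
    erreygers = erreygers_index(h, ranked, weights, bounds),
    wagstaff = wagstaff_index(h, ranked, weights, bounds)
  )

  if (.wvar(h, weights) == 0) {
    # a constant outcome has no sampling variability in the index
    est$se <- 0
    est$ci_low <- est$ci_high <- est$value
    est$ci_method <- method
    est$ci_level <- ci_level
    est$p_value <- 1
    est$stars <- ""
    return(est)
  }

  if (method == "robust_regression") {
    R <- ranked$ranks
    vr <- .wvar(R, weights)
    hbar <- est$mean_outcome
    scale_f <- switch(variant,
      standard = 2 * vr / hbar,
      erreygers = 8 * vr / (bounds[2] - bounds[1]),
      wagstaff = 2 * vr * (bounds[2] - bounds[1]) /
        ((bounds[2] - hbar) * (hbar - bounds[1]))
    )
    y <- scale_f * h
    fit <- stats::lm(y ~ R, weights = weights)
    slope <- unname(stats::coef(fit)[2])
    se <- sqrt(sandwich::vcovHC(fit, type = "HC1")[2, 2])
    z <- stats::qnorm(1 - (1 - ci_level) / 2)
    est$value <- slope
    est$se <- se
    est$ci_low <- slope - z * se
    est$ci_high <- slope + z * se
    est$ci_method <- "robust_regression"
  } else {
    if (is.null(seed)) stop("the bootstrap requires a `seed`", call. = FALSE)
    if (n_boot < 50) stop("`n_boot` must be at least 50", call. = FALSE)
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)

    income <- ranked$income
    n <- length(h)
    if (is.null(cluster_id)) cluster_id <- seq_len(n)
    cl <- split(seq_len(n), cluster_id)
    k <- length(cl)
    vals <- numeric(n_boot)
    redraws <- 0L
    for (b in seq_len(n_boot)) {
      v <- NA_real_
      tries <- 0L
      while (is.na(v)) {
        if (tries >= 100L) {
          stop("bootstrap resamples repeatedly degenerate (undefined index); ",
               "check the outcome distribution", call. = FALSE)
        }
        idx <- unlist(cl[sample.int(k, k, replace = TRUE)], use.names = FALSE)
        v <- .index_value(h[idx], income[idx], weights[idx], variant, bounds)
        if (is.na(v)) redraws <- redraws + 1L
        tries <- tries + 1L
      }
      vals[b] <- v
    }
    alpha <- 1 - ci_level
    q <- unname(stats::quantile(vals, c(alpha / 2, 1 - alpha / 2), type = 6))
    est$se <- stats::sd(vals)
    est$ci_low <- q[1]
    est$ci_high <- q[2]
    est$ci_method <- "bootstrap"
    est$n_boot <- n_boot
    est$n_redraws <- redraws
  }
  est$ci_level <- ci_level
  if (!is.na(est$se) && est$se > 0) {
    est$p_value <- 2 * stats::pnorm(-abs(est$value / est$se))
  } else {
    est$p_value <- if (est$value == 0) 1 else 0
  }
  est$stars <- .stars(est$p_value)
  est
}

#' Classify the direction of inequality from a confidence interval
#'
#' Pro-rich when the whole interval lies above zero, pro-poor when it lies
#' below, indeterminate otherwise — the reading rule used for tables of
#' corrected concentration indices.
#'
#' @param estimate an `index_estimate` with `ci_low`/`ci_high` present.
#' @return one of `"pro-rich"`, `"pro-poor"`, `"indeterminate"`.
#' @export
classify_inequality <- function(estimate) {
  if (!inherits(estimate, "index_estimate")) {
    stop("`estimate` must be an index_estimate", call. = FALSE)
  }
  if (is.na(estimate$ci_low) || is.na(estimate$ci_high)) {
    stop("classification requires a confidence interval; run index_ci() first",
         call. = FALSE)
  }
  if (estimate$ci_low > 0) "pro-rich"
  else if (estimate$ci_high < 0) "pro-poor"
  else "indeterminate"
}
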