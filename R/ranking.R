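#' Weighted fractional income ranks
#'
#' Computes the fractional rank of each person in the weighted ordering by
#' household income per capita, the ranking variable underlying every
#' concentration index. With equal weights and distinct incomes the rank of
#' the i-th poorest person is \eqn{(i - 0.5)/n}; with survey weights it is
#' the weighted midpoint \eqn{(W_{<i} + w_i/2)/W}, where \eqn{W_{<i}} is the
#' weight accumulated by strictly poorer persons and \eqn{W} the total
#' weight. Tied incomes share the weighted midpoint rank of their tie block,
#' so the result never depends on an arbitrary within-tie ordering.
#'
#' The weighted mean of the returned ranks is exactly 0.5 (up to floating
#' point), a conservation property that downstream index formulas rely on.
#'
#' @param income numeric vector of non-negative household income per capita,
#'   one entry per person (each person carries their household's value).
#' @param weights positive survey weights, same length as `income`; `NULL`
#'   means equal weights.
#' @return An object of class `ranked_sample`: a list with `ranks` (fractional
#'   ranks in (0,1), aligned with the input), `order_permutation` (the
#'   income-sorted order), `total_weight`, `tie_groups` (index sets sharing an
#'   income value), plus the `income` and `weights` used (kept for curve
#'   construction and resampling).
#' @examples
#' fractional_rank(c(10, 20, 30))$ranks           # 1/6, 3/6, 5/6
#' fractional_rank(c(5, 10), weights = c(1, 3))$ranks  # 0.125, 0.625
#' @export
fractional_rank <- function(income, weights = NULL) {
  n <- length(income)
  if (n < 1) stop("`income` must have length >= 1", call. = FALSE)
  if (anyNA(income) || any(!is.finite(income))) {
    stop("`income` contains missing or non-finite values; resolve missingness before ranking",
         call. = FALSE)
  }
  if (any(income < 0)) {
    stop("`income` must be non-negative", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, n)
  .check_weights(weights, n)

  ord <- order(income)
  w_s <- weights[ord]
  inc_s <- income[ord]
  W <- sum(w_s)

  # Tie blocks along the sorted order: each block gets the rank of its
  # weighted midpoint, (weight below block + block weight / 2) / W.
  block <- cumsum(!duplicated(inc_s))
  block_w <- as.numeric(rowsum(w_s, block))
  cum_before <- cumsum(block_w) - block_w
  block_rank <- (cum_before + block_w / 2) / W

  ranks <- numeric(n)
  ranks[ord] <- block_rank[block]

  groups <- split(ord, block)
  tie_groups <- unname(groups[vapply(groups, length, 1L) > 1L])

  structure(
    list(
      ranks = ranks,
      order_permutation = ord,
      total_weight = W,
      tie_groups = tie_groups,
      income = income,
      weights = weights,
      n = n
    ),
    class = "ranked_sample"
  )
}

#' @export
print.ranked_sample <- function(x, ...) {
  cat(sprintf(
    "<ranked_sample> n = %d, total weight = %.4g, %d tie group(s)\n",
    x$n, x$total_weight, length(x$tie_groups)
  ))
  cat(sprintf("  weighted mean rank = %.12f\n", .wmean(x$ranks, x$weights)))
  invisible(x)
}

.check_alignment <- function(h, ranked, weights) {
  if (!inherits(ranked, "ranked_sample")) {
    stop("`ranked` must be a ranked_sample from fractional_rank()", call. = FALSE)
  }
  if (length(h) != ranked$n) {
    stop(sprintf("outcome has length %d but the ranked sample has %d persons",
                 length(h), ranked$n), call. = FALSE)
  }
  if (anyNA(h)) {
    stop("outcome contains missing values; apply eligibility filtering first",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- ranked$weights
  .check_weights(weights, ranked$n)
  weights
}
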