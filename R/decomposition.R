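#' Covariate design for decomposition
#'
#' Builds the design matrix used by the probit decomposition from named
#' columns of a person-level table, tagging every expanded column with its
#' Andersen role (predisposing, enabling or need). Categorical covariates are
#' expanded to indicator columns against a reference level (by default the
#' first level); the intercept is always included in the fit but never
#' receives a contribution.
#'
#' @param data data.frame of person-level records.
#' @param covariates character vector of column names to include.
#' @param roles named character vector mapping covariate names to
#'   `"predisposing"`, `"enabling"` or `"need"`; unnamed covariates default to
#'   `"enabling"`.
#' @param reference named list of reference levels for categorical covariates.
#' @return A `covariate_design`: the expanded model matrix, per-column roles,
#'   source covariate of each column, and a flag marking binary columns
#'   (values in \{0, 1\}), which determines the partial-effect rule.
#' @export
covariate_design <- function(data, covariates = character(0), roles = NULL,
                             reference = NULL) {
  if (length(covariates) == 0) {
    X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
    return(structure(
      list(X = X, columns = character(0),
           roles = character(0), source = character(0),
           binary = logical(0), covariates = character(0)),
      class = "covariate_design"
    ))
  }
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols)) {
    stop("covariates not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(covariates)) {
    stop("duplicated covariate names", call. = FALSE)
  }
  df <- data[covariates]
  for (nm in covariates) {
    v <- df[[nm]]
    if (is.character(v) || is.logical(v)) v <- factor(v)
    if (is.factor(v) && !is.null(reference[[nm]])) {
      v <- stats::relevel(v, ref = reference[[nm]])
    }
    df[[nm]] <- v
    if (anyNA(v)) stop("covariate '", nm, "' has missing values", call. = FALSE)
  }
  X <- stats::model.matrix(~ ., data = df)
  cols <- setdiff(colnames(X), "(Intercept)")
  src <- vapply(cols, function(cn) {
    hit <- covariates[startsWith(cn, covariates)]
    hit[which.max(nchar(hit))]
  }, character(1))
  role_of <- function(nm) {
    r <- if (!is.null(roles) && nm %in% names(roles)) roles[[nm]] else "enabling"
    match.arg(r, c("predisposing", "enabling", "need"))
  }
  col_roles <- vapply(src, role_of, character(1))

  non_int <- X[, cols, drop = FALSE]
  const <- apply(non_int, 2, function(x) max(x) == min(x))
  if (any(const)) {
    stop("constant covariate column(s): ", paste(cols[const], collapse = ", "),
         call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  binary <- apply(non_int, 2, function(x) all(x %in% c(0, 1)))

  structure(
    list(X = X, columns = cols, roles = col_roles, source = src,
         binary = binary, covariates = covariates),
    class = "covariate_design"
  )
}

#' @export
print.covariate_design <- function(x, ...) {
  cat(sprintf("<covariate_design> %d column(s) + intercept, n = %d\n",
              length(x$columns), nrow(x$X)))
  for (i in seq_along(x$columns)) {
    cat(sprintf("  %-24s %-12s %s\n", x$columns[i], x$roles[i],
                if (x$binary[i]) "binary" else "continuous"))
  }
  invisible(x)
}

#' Weighted probit fit
#'
#' Maximum-likelihood probit regression of a binary outcome on a covariate
#' design, with survey weights entering the likelihood. This is the nonlinear
#' model \eqn{E(y_i | x_i) = \Phi(\sum_j \beta_j x_i^j)} that the
#' decomposition linearizes through partial effects.
#'
#' @param y binary 0/1 outcome vector.
#' @param design a [covariate_design()].
#' @param weights positive weights (`NULL` for equal weights).
#' @return A `probit_fit` with latent-scale `coefficients`, their standard
#'   errors (expected information), weighted `loglik`, per-observation
#'   `fitted` probabilities and a `converged` flag.
#' @export
fit_probit <- function(y, design, weights = NULL) {
  stopifnot(inherits(design, "covariate_design"))
  X <- design$X
  n <- nrow(X)
  if (length(y) != n) stop("`y` and design have different lengths", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  .check_weights(weights, n)

  fit <- suppressWarnings(
    stats::glm.fit(x = X, y = y, weights = weights,
                   family = stats::quasibinomial("probit"),
                   control = stats::glm.control(maxit = 100))
  )
  beta <- fit$coefficients
  if (!fit$converged) {
    stop("probit did not converge after ", fit$iter, " iterations",
         call. = FALSE)
  }
  p <- fit$fitted.values
  # complete separation: the fit classifies every observation perfectly
  separated <- max(c(-Inf, p[y == 0])) < 1e-6 && min(c(Inf, p[y == 1])) > 1 - 1e-6
  if (separated && length(beta) > 1) {
    slope <- beta[names(beta) != "(Intercept)"]
    worst <- names(slope)[which.max(abs(slope))]
    stop("perfect separation on covariate '", worst,
         "': the probit likelihood has no interior maximum", call. = FALSE)
  }
  eta <- drop(X %*% beta)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- sum(weights * (y * log(pc) + (1 - y) * log(1 - pc)))
  # expected information for the probit: sum w * phi(eta)^2 / (p (1-p)) x x'
  info_w <- weights * stats::dnorm(eta)^2 / (pc * (1 - pc))
  vcov <- tryCatch(solve(crossprod(X * sqrt(info_w))), error = function(e) NULL)
  se <- if (is.null(vcov)) rep(NA_real_, length(beta)) else sqrt(diag(vcov))

  structure(
    list(coefficients = beta, se = se, vcov = vcov, loglik = ll,
         fitted = p, eta = eta, converged = fit$converged,
         iterations = fit$iter, n = n, weights = weights, y = y),
    class = "probit_fit"
  )
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("<probit_fit> n = %d, logLik = %.2f, converged in %d iteration(s)\n",
              x$n, x$loglik, x$iterations))
  print(data.frame(coef = x$coefficients, se = x$se))
  invisible(x)
}

#' Averaged partial effects of a probit fit
#'
#' Linearizes the probit so the decomposition mechanics apply: for each
#' covariate a per-observation effect is computed and averaged (with the
#' survey weights) into a single coefficient \eqn{\beta_j^m}.
#'
#' * Continuous columns: the derivative \eqn{\beta_j \phi(x_i'\beta)} of the
#'   fitted probability, averaged over all observations.
#' * Binary columns: the discrete change
#'   \eqn{\Phi(\eta_i|x_j{=}1) - \Phi(\eta_i|x_j{=}0)} holding the other
#'   covariates at their observed values, averaged over the subgroup with
#'   \eqn{x_j = 1} (e.g. the effect of female sex is the mean effect among
#'   female respondents). The conventional overall average (AME) is also
#'   computed and stored so the two rules can be compared.
#'
#' @param fit a [fit_probit()] result.
#' @param design the [covariate_design()] used in the fit.
#' @return A `partial_effects` object: `per_observation` matrix, subgroup/all
#'   averaged `effects` (the \eqn{\beta_j^m} used downstream), the overall
#'   `effects_overall`, and the `averaging_rule` per column.
#' @export
partial_effects <- function(fit, design) {
  stopifnot(inherits(fit, "probit_fit"), inherits(design, "covariate_design"))
  X <- design$X
  beta <- fit$coefficients
  if (!identical(names(beta), colnames(X))) {
    stop("fit and design are misaligned", call. = FALSE)
  }
  w <- fit$weights
  eta <- fit$eta
  cols <- design$columns
  k <- length(cols)
  pe <- matrix(NA_real_, nrow(X), k, dimnames = list(NULL, cols))
  effects <- effects_overall <- stats::setNames(numeric(k), cols)
  rule <- stats::setNames(character(k), cols)

  for (j in seq_len(k)) {
    cn <- cols[j]
    bj <- beta[[cn]]
    xj <- X[, cn]
    if (design$binary[j]) {
      eta1 <- eta + (1 - xj) * bj
      eta0 <- eta - xj * bj
      pe[, j] <- stats::pnorm(eta1) - stats::pnorm(eta0)
      effects_overall[j] <- .wmean(pe[, j], w)
      in_group <- xj == 1
      if (any(in_group)) {
        effects[j] <- .wmean(pe[in_group, j], w[in_group])
        rule[j] <- "subgroup_mean"
      } else {
        effects[j] <- effects_overall[j]
        rule[j] <- "overall_mean"
      }
    } else {
      pe[, j] <- bj * stats::dnorm(eta)
      effects[j] <- effects_overall[j] <- .wmean(pe[, j], w)
      rule[j] <- "overall_mean"
    }
  }
  structure(
    list(per_observation = pe, effects = effects,
         effects_overall = effects_overall, averaging_rule = rule),
    class = "partial_effects"
  )
}

#' Generalized concentration index
#'
#' \eqn{GC(x) = \bar x \, C(x) = 2\,\mathrm{cov}_w(x, R)}: the covariance form
#' is used so covariates of any sign are handled.
#'
#' @param x numeric covariate vector aligned with `ranked`.
#' @inheritParams concentration_index
#' @return scalar generalized concentration index.
#' @export
generalized_concentration <- function(x, ranked, weights = NULL) {
  weights <- .check_alignment(x, ranked, weights)
  2 * .wcov(x, ranked$ranks, weights)
}

#' Decompose the Erreygers-corrected index into covariate contributions
#'
#' Fits a weighted probit of the binary outcome on the design, averages its
#' partial effects into linearized coefficients \eqn{\beta_j^m}, and splits
#' the Erreygers-corrected index as
#' \deqn{E(h) = 4\Big[\sum_j \beta_j^m\, GC(x_j) + GC(e)\Big]}
#' where each covariate's contribution is \eqn{4 \beta_j^m GC(x_j)} — the
#' product of the outcome's sensitivity to the covariate and the covariate's
#' own income-related concentration — and the residual \eqn{4\,GC(e)} is the
#' generalized concentration of the linear-approximation error. Because GC is
#' a covariance, the directly computed residual closes the identity to
#' machine precision.
#'
#' @param h binary 0/1 outcome.
#' @param design a [covariate_design()].
#' @inheritParams concentration_index
#' @param share_floor when `|E(h)|` falls below this floor, contribution
#'   shares are suppressed (contributions are still reported) to avoid
#'   division blow-up; default 0.01.
#' @return A `decomposition` object: a per-covariate `table`
#'   (\eqn{\beta_j^m}, GC, contribution, share), `residual_contribution`,
#'   `total_index`, role-aggregated `role_subtotals`, the underlying `fit`
#'   and `partials`, and a `shares_suppressed` flag.
#' @export
decompose_index <- function(h, design, ranked, weights = NULL,
                            share_floor = 0.01) {
  weights <- .check_alignment(h, ranked, weights)
  if (!all(h %in% c(0, 1))) {
    stop("decomposition requires a binary 0/1 outcome", call. = FALSE)
  }
  fit <- fit_probit(h, design, weights)
  pm <- partial_effects(fit, design)
  cols <- design$columns
  gc <- vapply(cols, function(cn)
    generalized_concentration(design$X[, cn], ranked, weights), numeric(1))
  contribution <- 4 * pm$effects * gc
  E <- erreygers_index(h, ranked, weights)$value

  # direct residual: GC of the linear-approximation error; equals the
  # closure value E - sum(contributions) identically because GC is linear
  lin_pred <- drop(design$X[, cols, drop = FALSE] %*% pm$effects)
  gc_resid <- generalized_concentration(h - lin_pred, ranked, weights)
  residual <- E - sum(contribution)

  suppressed <- abs(E) < share_floor
  share <- if (suppressed) rep(NA_real_, length(cols)) else contribution / E

  tab <- data.frame(
    term = cols,
    role = unname(design$roles),
    beta_m = unname(pm$effects),
    beta_m_overall = unname(pm$effects_overall),
    averaging_rule = unname(pm$averaging_rule),
    gc = unname(gc),
    contribution = unname(contribution),
    share = unname(share),
    stringsAsFactors = FALSE
  )
  role_subtotals <- if (length(cols)) {
    agg <- stats::aggregate(contribution ~ role, data = tab, FUN = sum)
    agg$share <- if (suppressed) NA_real_ else agg$contribution / E
    agg
  } else {
    data.frame(role = character(), contribution = numeric(), share = numeric())
  }

  structure(
    list(table = tab,
         residual_contribution = residual,
         residual_gc_direct = 4 * gc_resid,
         total_index = E,
         role_subtotals = role_subtotals,
         shares_suppressed = suppressed,
         share_floor = share_floor,
         fit = fit, partials = pm),
    class = "decomposition"
  )
}

#' @export
print.decomposition <- function(x, digits = 4, ...) {
  cat(sprintf("<decomposition> Erreygers index E(h) = %.4f\n", x$total_index))
  tab <- x$table
  tab$beta_m <- round(tab$beta_m, digits)
  tab$gc <- round(tab$gc, digits)
  tab$contribution <- round(tab$contribution, digits)
  tab$share <- round(tab$share, digits)
  print(tab[c("term", "role", "beta_m", "gc", "contribution", "share")],
        row.names = FALSE)
  cat(sprintf("  residual contribution 4*GC(e) = %.4f\n",
              x$residual_contribution))
  if (x$shares_suppressed) {
    cat(sprintf("  shares suppressed: |E(h)| < %.3g\n", x$share_floor))
  }
  invisible(x)
}

#' Contribution shares of a decomposition
#'
#' Shares of the total corrected index attributable to each covariate (or to
#' each Andersen role), as contribution / E(h) expressed in percent. Shares
#' can exceed 100% or be negative: a covariate may push inequality beyond the
#' observed total while others offset it.
#'
#' @param decomp a [decompose_index()] result.
#' @param grouping `"covariate"` (default) or `"role"`.
#' @return data.frame of terms, contributions and shares in percent, with the
#'   residual as the final row.
#' @export
contribution_shares <- function(decomp, grouping = c("covariate", "role")) {
  stopifnot(inherits(decomp, "decomposition"))
  grouping <- match.arg(grouping)
  if (decomp$shares_suppressed) {
    stop("shares are suppressed because |E(h)| < ", decomp$share_floor,
         "; use the raw contributions in `decomp$table` instead", call. = FALSE)
  }
  E <- decomp$total_index
  base <- if (grouping == "covariate") {
    data.frame(term = decomp$table$term,
               contribution = decomp$table$contribution,
               stringsAsFactors = FALSE)
  } else {
    data.frame(term = decomp$role_subtotals$role,
               contribution = decomp$role_subtotals$contribution,
               stringsAsFactors = FALSE)
  }
  out <- rbind(base,
               data.frame(term = "residual",
                          contribution = decomp$residual_contribution,
                          stringsAsFactors = FALSE))
  out$share_pct <- 100 * out$contribution / E
  out
}
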