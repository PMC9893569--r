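#' @title Synthetic household-survey generator
#' @description Person-level microdata emulating large national household
#'   health surveys (skewed per-capita household income, heterogeneous
#'   weights, five-region stratification, binary utilisation outcomes from a
#'   known latent probit model with income-rank-dependent covariates), with
#'   the full generating model returned as ground truth.
#' @name synthetic_survey
NULL

#' Dependence of a covariate on the income rank
#'
#' Declares how a generated covariate depends on the weighted fractional
#' income rank R in (0,1). For binary covariates the prevalence is
#' `plogis(intercept + slope * R)`; for continuous covariates the mean is
#' `intercept + slope * R` with unit-variance Gaussian noise (scaled by `sd`).
#' Dependence is specified on the rank scale so closed-form index
#' expectations stay tractable.
#'
#' @param slope,intercept parameters of the dependence.
#' @return a `rank_dependence` list.
#' @export
rank_dependence <- function(slope, intercept) {
  structure(list(kind = "logistic", slope = slope, intercept = intercept),
            class = "rank_dependence")
}

#' Covariate definition for the generator
#'
#' @param name column name.
#' @param role Andersen role: `"predisposing"`, `"enabling"` or `"need"`.
#' @param type `"binary"` or `"continuous"`.
#' @param dependence a [rank_dependence()] or `NULL` for no income-rank
#'   dependence (binary covariates then need `prevalence`).
#' @param prevalence marginal prevalence for a rank-independent binary
#'   covariate.
#' @param sd residual standard deviation for continuous covariates.
#' @return a `covariate_def` list.
#' @export
covariate_def <- function(name, role = c("enabling", "predisposing", "need"),
                          type = c("binary", "continuous"),
                          dependence = NULL, prevalence = 0.5, sd = 1) {
  role <- match.arg(role)
  type <- match.arg(type)
  if (is.null(dependence)) {
    dependence <- if (type == "binary") {
      rank_dependence(0, stats::qlogis(prevalence))
    } else {
      rank_dependence(0, 0)
    }
  }
  if (!inherits(dependence, "rank_dependence")) {
    stop("covariate '", name, "': `dependence` must be a rank_dependence()",
         call. = FALSE)
  }
  structure(list(name = name, role = role, type = type,
                 dependence = dependence, sd = sd),
            class = "covariate_def")
}

#' Outcome definition for the generator
#'
#' Two latent models are supported:
#'
#' * `model = "probit"`: utilisation probability `pnorm(eta)` with
#'   `eta = sum(coefficients * regressors)`. Regressor names must be declared
#'   covariates or one of the special regressors `"(Intercept)"`,
#'   `"income_rank"` (the weighted fractional rank), `"female"`
#'   (indicator of female sex) and `"age_decades"` (age / 10).
#' * `model = "linear_rank"`: probability `a + b * R`, linear in the income
#'   rank; this model has the closed-form expected Erreygers index `2 b / 3`
#'   (since `E = 8 cov(h, R)` and `cov = b * Var(R) = b / 12` for near-uniform
#'   ranks).
#'
#' @param name outcome column name.
#' @param model `"probit"` or `"linear_rank"`.
#' @param coefficients named numeric vector (probit model).
#' @param a,b intercept and rank slope (linear_rank model).
#' @param eligibility optional list with any of `sex`, `age_min`, `age_max`;
#'   persons outside the stratum get a not-applicable (`NA`) outcome rather
#'   than being dropped, so downstream eligibility filtering is exercised.
#' @param delivery_exclusion if `TRUE`, a labour-and-delivery admission
#'   process (probability `p_delivery` for women aged 18-45) is superimposed:
#'   the recorded outcome is 1 if either the need-based event or a delivery
#'   admission occurred, and a companion column `<name>_delivery_only` flags
#'   records whose only admission was for delivery, so the study pipeline can
#'   recode them to 0.
#' @param p_delivery annual delivery-admission probability.
#' @return an `outcome_def` list.
#' @export
outcome_def <- function(name, model = c("probit", "linear_rank"),
                        coefficients = NULL, a = NULL, b = NULL,
                        eligibility = NULL, delivery_exclusion = FALSE,
                        p_delivery = 0.04) {
  model <- match.arg(model)
  structure(list(name = name, model = model, coefficients = coefficients,
                 a = a, b = b, eligibility = eligibility,
                 delivery_exclusion = delivery_exclusion,
                 p_delivery = p_delivery),
            class = "outcome_def")
}

.special_regressors <- c("(Intercept)", "income_rank", "female", "age_decades")

#' Default covariate set
#'
#' Four Andersen-framework covariates: private health insurance and secondary
#' education (enabling, concentrated among the rich), a chronic condition
#' (need, mildly concentrated among the poor) and urban residence
#' (predisposing, more common among the rich).
#' @return list of [covariate_def()]s.
#' @export
default_covariates <- function() {
  list(
    covariate_def("insurance", "enabling", "binary",
                  rank_dependence(slope = 3.5, intercept = -2.6)),
    covariate_def("education_secondary", "enabling", "binary",
                  rank_dependence(slope = 2.2, intercept = -1.1)),
    covariate_def("chronic_condition", "need", "binary",
                  rank_dependence(slope = -0.8, intercept = -0.4)),
    covariate_def("urban", "predisposing", "binary",
                  rank_dependence(slope = 1.5, intercept = 0.3))
  )
}

#' Default outcome set
#'
#' Five binary utilisation outcomes mirroring the standard survey battery:
#' physician visit (past year), hospitalisation (past year, with the
#' labour-and-delivery exclusion process), surgery (past year), Pap smear
#' (women 25-59, 3-year recall) and mammogram (women 50-69, 2-year recall).
#' @return list of [outcome_def()]s.
#' @export
default_outcomes <- function() {
  list(
    outcome_def("doctor_visit", "probit", c(
      "(Intercept)" = 0.15, insurance = 0.55, education_secondary = 0.25,
      chronic_condition = 0.45, income_rank = 0.30, female = 0.20,
      age_decades = 0.02)),
    outcome_def("hospitalisation", "probit", c(
      "(Intercept)" = -1.75, chronic_condition = 0.50, insurance = 0.08,
      income_rank = 0.08, age_decades = 0.02),
      delivery_exclusion = TRUE),
    outcome_def("surgery", "probit", c(
      "(Intercept)" = -2.15, chronic_condition = 0.30, insurance = 0.22,
      income_rank = 0.10, age_decades = 0.02)),
    outcome_def("pap_smear", "probit", c(
      "(Intercept)" = 0.35, insurance = 0.45, education_secondary = 0.35,
      income_rank = 0.30),
      eligibility = list(sex = "female", age_min = 25, age_max = 59)),
    outcome_def("mammogram", "probit", c(
      "(Intercept)" = -0.55, insurance = 0.70, education_secondary = 0.40,
      income_rank = 0.50),
      eligibility = list(sex = "female", age_min = 50, age_max = 69))
  )
}

#' Generator configuration
#'
#' Defines the full synthetic-survey model. Defaults emulate a national
#' household health survey: five regions with unequal population shares and
#' log-normal per-capita household income with region-specific locations,
#' gamma survey weights with mean 1, households of 1-6 persons sharing an
#' income, and the covariates/outcomes of [default_covariates()] and
#' [default_outcomes()].
#'
#' @param n_persons number of persons (>= 2).
#' @param seed integer seed; one RNG stream per generate call, with component
#'   sub-streams (households/income, weights, covariates, outcomes) derived
#'   deterministically so adding a covariate does not perturb incomes.
#' @param regions region labels (unique).
#' @param region_prob sampling probability of each region.
#' @param income_meanlog,income_sdlog log-normal income parameters per region
#'   (`income_sdlog` may be scalar).
#' @param weight_model `list(kind = "gamma", shape = 2)` or
#'   `list(kind = "uniform")` (all weights 1).
#' @param household_size_range integer pair.
#' @param age_range integer pair of ages to draw from (exponentially tilted
#'   toward younger adults).
#' @param covariates list of [covariate_def()]s.
#' @param outcomes list of [outcome_def()]s.
#' @param psu_households households per primary sampling unit block.
#' @return a validated `generator_config`.
#' @export
generator_config <- function(n_persons = 20000, seed = 1,
                             regions = c("North", "North-East", "South-East",
                                         "South", "Midwest"),
                             region_prob = c(0.08, 0.27, 0.42, 0.14, 0.09),
                             income_meanlog = c(6.4, 6.2, 7.0, 6.9, 6.8),
                             income_sdlog = 0.85,
                             weight_model = list(kind = "gamma", shape = 2),
                             household_size_range = c(1, 6),
                             age_range = c(16, 95),
                             covariates = default_covariates(),
                             outcomes = default_outcomes(),
                             psu_households = 10) {
  cfg <- structure(
    list(n_persons = n_persons, seed = seed, regions = regions,
         region_prob = region_prob, income_meanlog = income_meanlog,
         income_sdlog = rep_len(income_sdlog, length(regions)),
         weight_model = weight_model,
         household_size_range = household_size_range,
         age_range = age_range, covariates = covariates, outcomes = outcomes,
         psu_households = psu_households),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks every structural invariant and errors naming the offending field;
#' in particular, a `linear_rank` outcome whose probability can escape
#' \eqn{[0, 1]} is rejected rather than silently clipped.
#'
#' @param cfg a `generator_config`.
#' @return `cfg`, invisibly.
#' @export
validate_generator_config <- function(cfg) {
  err <- function(field, msg) {
    stop(sprintf("invalid generator config: `%s` %s", field, msg), call. = FALSE)
  }
  if (!is.numeric(cfg$n_persons) || cfg$n_persons < 2) {
    err("n_persons", "must be >= 2")
  }
  if (anyDuplicated(cfg$regions)) err("regions", "labels must be unique")
  if (length(cfg$region_prob) != length(cfg$regions) ||
      any(cfg$region_prob <= 0)) {
    err("region_prob", "must be positive, one per region")
  }
  if (length(cfg$income_meanlog) != length(cfg$regions)) {
    err("income_meanlog", "must have one entry per region")
  }
  if (!cfg$weight_model$kind %in% c("gamma", "uniform")) {
    err("weight_model", "kind must be 'gamma' or 'uniform'")
  }
  hs <- cfg$household_size_range
  if (length(hs) != 2 || hs[1] < 1 || hs[2] < hs[1]) {
    err("household_size_range", "must be an increasing positive pair")
  }
  cov_names <- vapply(cfg$covariates, function(x) x$name, character(1))
  if (anyDuplicated(cov_names)) err("covariate_spec", "names must be unique")
  for (oc in cfg$outcomes) {
    if (oc$model == "probit") {
      if (is.null(oc$coefficients) || is.null(names(oc$coefficients))) {
        err("outcome_spec", sprintf("('%s') probit model needs named coefficients",
                                    oc$name))
      }
      unknown <- setdiff(names(oc$coefficients),
                         c(cov_names, .special_regressors))
      if (length(unknown)) {
        err("outcome_spec",
            sprintf("('%s') coefficient refers to undeclared covariate(s): %s",
                    oc$name, paste(unknown, collapse = ", ")))
      }
    } else {
      if (is.null(oc$a) || is.null(oc$b)) {
        err("outcome_spec", sprintf("('%s') linear_rank model needs `a` and `b`",
                                    oc$name))
      }
      p_ends <- c(oc$a, oc$a + oc$b)
      if (any(p_ends < 0) || any(p_ends > 1)) {
        err("outcome_spec",
            sprintf("('%s') linear-in-rank probability escapes [0,1] (range %.3f to %.3f)",
                    oc$name, min(p_ends), max(p_ends)))
      }
    }
  }
  oc_names <- vapply(cfg$outcomes, function(x) x$name, character(1))
  if (anyDuplicated(oc_names)) err("outcome_spec", "names must be unique")
  invisible(cfg)
}

#' Generate synthetic survey microdata
#'
#' Draws a person-level table from the configured latent model and returns it
#' together with a `generator_truth` object describing exactly the model that
#' produced the outcomes (true latent coefficients, the marginal dependence of
#' each outcome probability on the income rank, and the closed-form expected
#' Erreygers index where derivable). Deterministic for a fixed seed.
#'
#' @param config a [generator_config()].
#' @return list with `data` (a `survey_microdata` data.frame carrying its
#'   column-role mapping as an attribute) and `truth` (a `generator_truth`).
#' @export
generate_survey <- function(config) {
  validate_generator_config(config)
  n <- as.integer(config$n_persons)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  sub_seeds <- sample.int(2147483646L, 4L)

  ## -- households, regions, income, demographics ------------------------
  set.seed(sub_seeds[1])
  hs <- config$household_size_range
  n_hh_guess <- ceiling(n / mean(hs)) + 64L
  sizes <- sample(hs[1]:hs[2], n_hh_guess, replace = TRUE)
  while (sum(sizes) < n) sizes <- c(sizes, sample(hs[1]:hs[2], 64L, replace = TRUE))
  csum <- cumsum(sizes)
  n_hh <- which(csum >= n)[1]
  sizes <- sizes[seq_len(n_hh)]
  sizes[n_hh] <- sizes[n_hh] - (csum[n_hh] - n)
  household_id <- rep(seq_len(n_hh), times = sizes)

  region_idx_hh <- sample.int(length(config$regions), n_hh, replace = TRUE,
                              prob = config$region_prob)
  income_hh <- stats::rlnorm(n_hh,
                             meanlog = config$income_meanlog[region_idx_hh],
                             sdlog = config$income_sdlog[region_idx_hh])
  region <- config$regions[region_idx_hh][household_id]
  income_pc <- income_hh[household_id]

  ages <- config$age_range[1]:config$age_range[2]
  age <- sample(ages, n, replace = TRUE, prob = exp(-0.02 * (ages - ages[1])))
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.52, 0.48))

  ## -- weights ----------------------------------------------------------
  set.seed(sub_seeds[2])
  weight <- if (config$weight_model$kind == "gamma") {
    shp <- config$weight_model$shape %||% 2
    stats::rgamma(n, shape = shp, rate = shp)
  } else {
    rep(1, n)
  }

  ranked <- fractional_rank(income_pc, weight)
  R <- ranked$ranks

  ## -- stratum / PSU: region x income tercile, blocks of households -----
  terc <- cut(income_pc, breaks = stats::quantile(income_pc, c(0, 1/3, 2/3, 1)),
              labels = c("T1", "T2", "T3"), include.lowest = TRUE)
  stratum_id <- paste(region, terc, sep = ":")
  psu_id <- paste(stratum_id,
                  ((match(household_id, unique(household_id)) - 1L) %/%
                     config$psu_households) + 1L,
                  sep = ":")

  ## -- covariates -------------------------------------------------------
  set.seed(sub_seeds[3])
  cov_cols <- list()
  for (cv in config$covariates) {
    dep <- cv$dependence
    if (cv$type == "binary") {
      p <- stats::plogis(dep$intercept + dep$slope * R)
      cov_cols[[cv$name]] <- stats::rbinom(n, 1, p)
    } else {
      cov_cols[[cv$name]] <- dep$intercept + dep$slope * R +
        stats::rnorm(n, 0, cv$sd)
    }
  }

  ## -- outcomes ---------------------------------------------------------
  set.seed(sub_seeds[4])
  female <- as.numeric(sex == "female")
  out_cols <- list()
  truth_outcomes <- list()
  for (oc in config$outcomes) {
    eligible <- rep(TRUE, n)
    if (!is.null(oc$eligibility)) {
      el <- oc$eligibility
      if (!is.null(el$sex)) eligible <- eligible & sex == el$sex
      if (!is.null(el$age_min)) eligible <- eligible & age >= el$age_min
      if (!is.null(el$age_max)) eligible <- eligible & age <= el$age_max
    }
    if (oc$model == "probit") {
      regs <- names(oc$coefficients)
      eta <- rep(0, n)
      for (rg in regs) {
        x <- switch(rg,
          "(Intercept)" = 1,
          income_rank = R,
          female = female,
          age_decades = age / 10,
          cov_cols[[rg]]
        )
        eta <- eta + oc$coefficients[[rg]] * x
      }
      p <- stats::pnorm(eta)
      rank_grad <- if ("income_rank" %in% regs) {
        .wmean((oc$coefficients[["income_rank"]] * stats::dnorm(eta))[eligible],
               weight[eligible])
      } else 0
      expected_e <- NA_real_
    } else {
      p <- oc$a + oc$b * R
      if (any(p < 0 | p > 1)) {
        stop("outcome '", oc$name, "': probability escapes [0,1]", call. = FALSE)
      }
      rank_grad <- oc$b
      expected_e <- 2 * oc$b / 3
    }
    h <- rep(NA_integer_, n)
    h[eligible] <- stats::rbinom(sum(eligible), 1, p[eligible])

    if (isTRUE(oc$delivery_exclusion)) {
      can_deliver <- eligible & sex == "female" & age >= 18 & age <= 45
      d <- rep(0L, n)
      d[can_deliver] <- stats::rbinom(sum(can_deliver), 1, oc$p_delivery)
      delivery_only <- as.integer(d == 1L & h == 0L)
      delivery_only[!eligible] <- NA_integer_
      h[eligible] <- pmax(h[eligible], d[eligible])
      out_cols[[paste0(oc$name, "_delivery_only")]] <- delivery_only
    }
    out_cols[[oc$name]] <- h
    truth_outcomes[[oc$name]] <- list(
      model = oc$model,
      coefficients = as.list(oc$coefficients),
      a = oc$a, b = oc$b,
      rank_gradient = rank_grad,
      expected_erreygers = expected_e,
      eligibility = oc$eligibility,
      delivery_exclusion = isTRUE(oc$delivery_exclusion),
      p_delivery = if (isTRUE(oc$delivery_exclusion)) oc$p_delivery else NULL
    )
  }

  data <- data.frame(
    person_id = seq_len(n),
    household_id = household_id,
    stratum_id = stratum_id,
    psu_id = psu_id,
    region = region,
    age = age,
    sex = sex,
    income_pc = income_pc,
    weight = weight,
    stringsAsFactors = FALSE
  )
  for (nm in names(cov_cols)) data[[nm]] <- cov_cols[[nm]]
  for (nm in names(out_cols)) data[[nm]] <- out_cols[[nm]]

  outcome_map <- lapply(config$outcomes, function(oc) {
    list(column = oc$name,
         eligibility = oc$eligibility,
         recode_zero_col = if (isTRUE(oc$delivery_exclusion))
           paste0(oc$name, "_delivery_only") else NULL)
  })
  names(outcome_map) <- vapply(config$outcomes, function(x) x$name, character(1))

  mapping <- list(
    person_id = "person_id", household_id = "household_id",
    stratum = "stratum_id", psu = "psu_id", region = "region",
    age = "age", sex = "sex", income = "income_pc", weight = "weight",
    covariates = names(cov_cols),
    covariate_roles = as.list(stats::setNames(
      vapply(config$covariates, function(x) x$role, character(1)),
      vapply(config$covariates, function(x) x$name, character(1))
    )),
    outcomes = outcome_map,
    column_types = lapply(data, function(col) class(col)[1])
  )
  attr(data, "mapping") <- mapping
  class(data) <- c("survey_microdata", "data.frame")

  truth <- structure(
    list(outcomes = truth_outcomes,
         covariates = lapply(config$covariates, function(cv)
           list(name = cv$name, role = cv$role, type = cv$type,
                dependence = unclass(cv$dependence))),
         seed = config$seed,
         component_seeds = sub_seeds),
    class = "generator_truth"
  )
  list(data = data, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write survey microdata to disk
#'
#' Writes the table (CSV with full double precision, or Parquet via the arrow
#' package) plus a sidecar YAML file `<path>.mapping.yaml` declaring column
#' roles, and optionally the generator truth as JSON next to the data. The
#' result round-trips losslessly through [read_microdata()].
#'
#' @param data a `survey_microdata` (or plain data.frame with a mapping).
#' @param path output file path.
#' @param format `"csv"` or `"parquet"`.
#' @param truth optional `generator_truth` to serialize as
#'   `<path>.truth.json`.
#' @param mapping column-role mapping; defaults to the one attached to `data`.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(data, path, format = c("csv", "parquet"),
                            truth = NULL, mapping = attr(data, "mapping")) {
  format <- match.arg(format)
  if (is.null(mapping)) {
    stop("no column-role mapping: pass `mapping` or use generator output",
         call. = FALSE)
  }
  df <- as.data.frame(data)
  if (format == "csv") {
    out <- df
    for (nm in names(out)) {
      if (is.double(out[[nm]])) {
        out[[nm]] <- formatC(out[[nm]], digits = 17, format = "g")
      }
    }
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("parquet output requires the 'arrow' package", call. = FALSE)
    }
    arrow::write_parquet(df, path)
  }
  yaml::write_yaml(mapping, paste0(path, ".mapping.yaml"))
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read survey microdata from disk
#'
#' Reads a CSV or Parquet table written by [write_microdata()] (or any
#' compatible table plus mapping), restores declared column types, and
#' validates the structural invariants: mapped roles present, strictly
#' positive weights, finite non-negative income, and binary (0/1/NA) outcome
#' columns. Violations raise errors naming the offending rows.
#'
#' @param path data file path.
#' @param mapping a mapping list or path to a mapping YAML; defaults to the
#'   sidecar `<path>.mapping.yaml`.
#' @param format `"csv"`, `"parquet"`, or `NULL` to infer from the extension.
#' @return a validated `survey_microdata`.
#' @export
read_microdata <- function(path, mapping = NULL, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.parquet$", path)) "parquet" else "csv"
  }
  if (is.null(mapping)) {
    side <- paste0(path, ".mapping.yaml")
    if (!file.exists(side)) {
      stop("no mapping supplied and no sidecar found at ", side, call. = FALSE)
    }
    mapping <- side
  }
  if (is.character(mapping)) mapping <- yaml::read_yaml(mapping)

  df <- if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("parquet input requires the 'arrow' package", call. = FALSE)
    }
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(mapping$column_types)) {
    for (nm in intersect(names(df), names(mapping$column_types))) {
      target <- mapping$column_types[[nm]]
      df[[nm]] <- switch(target,
        numeric = as.numeric(df[[nm]]),
        integer = as.integer(df[[nm]]),
        character = as.character(df[[nm]]),
        df[[nm]]
      )
    }
  }
  validate_microdata(df, mapping)
}

#' Validate survey microdata against its mapping
#'
#' @param df data.frame of person-level records.
#' @param mapping column-role mapping list.
#' @return the validated `survey_microdata` with the mapping attached.
#' @export
validate_microdata <- function(df, mapping) {
  required <- c(mapping$income, mapping$weight, mapping$age, mapping$sex)
  outcome_cols <- vapply(mapping$outcomes, function(x) x$column, character(1))
  missing_cols <- setdiff(c(required, outcome_cols), names(df))
  if (length(missing_cols)) {
    stop("mapped column(s) absent from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  w <- df[[mapping$weight]]
  bad_w <- which(is.na(w) | w <= 0)
  if (length(bad_w)) {
    stop("non-positive or missing weight in row(s): ",
         paste(utils::head(bad_w, 5), collapse = ", "), call. = FALSE)
  }
  inc <- df[[mapping$income]]
  bad_i <- which(!is.finite(inc) | inc < 0)
  if (length(bad_i)) {
    stop("income must be finite and non-negative; offending row(s): ",
         paste(utils::head(bad_i, 5), collapse = ", "), call. = FALSE)
  }
  for (oc in outcome_cols) {
    v <- df[[oc]]
    bad <- which(!(is.na(v) | v %in% c(0, 1)))
    if (length(bad)) {
      stop("outcome '", oc, "' is not binary 0/1 in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  attr(df, "mapping") <- mapping
  class(df) <- unique(c("survey_microdata", class(df)))
  df
}
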