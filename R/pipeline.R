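#' @title End-to-end study pipeline
#' @description Applies eligibility filters, computes weighted prevalences,
#'   concentration indices with uncertainty and classification, and
#'   decompositions, across outcomes, waves and regions, emitting the standard
#'   study tables (prevalence; indices by year; indices by region and year;
#'   decomposition contributions).
#' @name study_pipeline
NULL

#' Restrict a sample to adults
#'
#' @param data a `survey_microdata`.
#' @param min_age minimum age kept (default 18).
#' @return list with `data` and a one-row `log` (rows in/retained/excluded).
#' @export
filter_adults <- function(data, min_age = 18) {
  mp <- attr(data, "mapping")
  age <- data[[mp$age]]
  keep <- !is.na(age) & age >= min_age
  out <- data[keep, , drop = FALSE]
  attr(out, "mapping") <- mp
  class(out) <- class(data)
  list(
    data = out,
    log = data.frame(filter = sprintf("age >= %d", min_age),
                     rows_in = nrow(data), rows_retained = sum(keep),
                     rows_excluded = sum(!keep), n_recoded = 0L,
                     stringsAsFactors = FALSE)
  )
}

#' Apply an outcome's eligibility rule
#'
#' Restricts the denominator to the eligible stratum (e.g. women aged 50-69
#' for mammography screening) by dropping ineligible rows, and applies any
#' recode rule: records flagged as admitted only for labour and delivery have
#' the outcome recoded to 0 but remain in the denominator. Rows whose outcome
#' is missing after restriction are excluded and counted. Counts are
#' conserved: `rows_in = rows_retained + rows_excluded`.
#'
#' @param data a `survey_microdata`.
#' @param outcome_name name of the outcome column.
#' @param rule eligibility rule list (`sex`, `age_min`, `age_max`,
#'   `recode_zero_col`); defaults to the rule recorded in the data's mapping.
#' @return list with filtered `data` and a one-row `log` including the number
#'   of recoded outcomes.
#' @export
eligibility_filter <- function(data, outcome_name, rule = NULL) {
  mp <- attr(data, "mapping")
  if (is.null(rule)) {
    oc <- mp$outcomes[[outcome_name]]
    rule <- c(oc$eligibility, list(recode_zero_col = oc$recode_zero_col))
  }
  if (!outcome_name %in% names(data)) {
    stop("outcome '", outcome_name, "' not present in data", call. = FALSE)
  }
  for (fld in intersect(c("sex", "age_min", "age_max"), names(rule))) {
    need <- if (fld == "sex") mp$sex else mp$age
    if (!need %in% names(data)) {
      stop("eligibility rule needs missing field '", need, "'", call. = FALSE)
    }
  }
  n_in <- nrow(data)
  keep <- rep(TRUE, n_in)
  if (!is.null(rule$sex)) keep <- keep & data[[mp$sex]] == rule$sex
  if (!is.null(rule$age_min)) keep <- keep & data[[mp$age]] >= rule$age_min
  if (!is.null(rule$age_max)) keep <- keep & data[[mp$age]] <= rule$age_max
  keep <- keep & !is.na(data[[outcome_name]])

  out <- data[keep, , drop = FALSE]
  n_recoded <- 0L
  rc <- rule$recode_zero_col
  if (!is.null(rc)) {
    if (!rc %in% names(out)) {
      stop("recode rule references missing field '", rc, "'", call. = FALSE)
    }
    flag <- !is.na(out[[rc]]) & out[[rc]] == 1
    n_recoded <- sum(flag & out[[outcome_name]] == 1)
    out[[outcome_name]][flag] <- 0L
  }
  attr(out, "mapping") <- mp
  class(out) <- class(data)
  list(
    data = out,
    log = data.frame(filter = paste0("eligibility:", outcome_name),
                     rows_in = n_in, rows_retained = nrow(out),
                     rows_excluded = n_in - nrow(out),
                     n_recoded = n_recoded, stringsAsFactors = FALSE)
  )
}

#' Weighted prevalence with a confidence interval
#'
#' Weighted mean of a binary indicator with a design-based normal
#' approximation interval (linearized standard error), the standard summary
#' for survey prevalence tables.
#'
#' @param h binary vector (no missing values).
#' @param weights positive weights.
#' @param ci_level confidence level.
#' @return one-row data.frame: `n_users` (unweighted count of users), `n`
#'   (denominator), weighted `pct` and its CI, all in percent.
#' @export
prevalence_estimate <- function(h, weights = NULL, ci_level = 0.95) {
  n <- length(h)
  if (is.null(weights)) weights <- rep(1, n)
  .check_weights(weights, n)
  p <- .wmean(h, weights)
  se <- sqrt(sum(weights^2 * (h - p)^2)) / sum(weights)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  data.frame(n_users = sum(h == 1), n = n,
             pct = 100 * p,
             ci_low = 100 * max(0, p - z * se),
             ci_high = 100 * min(1, p + z * se))
}

#' Study configuration
#'
#' @param waves named list (names are wave/year labels); each element is
#'   either a [generator_config()] or `list(path = , mapping = )` pointing at
#'   microdata on disk.
#' @param design_covariates covariate column names for the decomposition
#'   (`NULL` disables decomposition).
#' @param roles named role vector passed to [covariate_design()].
#' @param variant index variant for the main tables.
#' @param ci_method `"robust_regression"` or `"bootstrap"`.
#' @param ci_level confidence level.
#' @param n_boot bootstrap replicates (when bootstrapping).
#' @param seed integer seed governing every random step (bootstrap resampling;
#'   generation uses each generator config's own seed).
#' @param by_region compute region-stratified indices (individuals are
#'   re-ranked within each region, so each regional index measures
#'   within-region inequality).
#' @param outcomes outcome names to analyse; `NULL` means all mapped outcomes.
#' @param exclude_rows declarative row filters: list of
#'   `list(column =, equals =)` — rows matching all conditions of an entry are
#'   dropped (e.g. excluding rural households of one region).
#' @param min_age adult age cutoff.
#' @param share_floor decomposition share suppression floor.
#' @return a `study_config`.
#' @export
study_config <- function(waves, design_covariates = NULL, roles = NULL,
                         variant = c("erreygers", "standard", "wagstaff"),
                         ci_method = c("robust_regression", "bootstrap"),
                         ci_level = 0.95, n_boot = 500, seed = 1,
                         by_region = TRUE, outcomes = NULL,
                         exclude_rows = NULL, min_age = 18,
                         share_floor = 0.01) {
  variant <- match.arg(variant)
  ci_method <- match.arg(ci_method)
  if (is.null(names(waves)) || any(names(waves) == "") ||
      anyDuplicated(names(waves))) {
    stop("`waves` must be a named list with unique wave labels", call. = FALSE)
  }
  if (ci_method == "bootstrap" && is.null(seed)) {
    stop("a `seed` is required when the bootstrap CI method is chosen",
         call. = FALSE)
  }
  structure(
    list(waves = waves, design_covariates = design_covariates, roles = roles,
         variant = variant, ci_method = ci_method, ci_level = ci_level,
         n_boot = n_boot, seed = seed, by_region = by_region,
         outcomes = outcomes, exclude_rows = exclude_rows, min_age = min_age,
         share_floor = share_floor),
    class = "study_config"
  )
}

.load_wave <- function(wave) {
  if (inherits(wave, "generator_config")) {
    generate_survey(wave)$data
  } else if (is.list(wave) && !is.null(wave$path)) {
    read_microdata(wave$path, mapping = wave$mapping)
  } else {
    stop("each wave must be a generator_config or list(path=, mapping=)",
         call. = FALSE)
  }
}

.apply_row_exclusions <- function(data, exclude_rows) {
  if (is.null(exclude_rows)) return(data)
  mp <- attr(data, "mapping")
  drop <- rep(FALSE, nrow(data))
  for (rule in exclude_rows) {
    if (!rule$column %in% names(data)) {
      stop("row-exclusion rule references missing column '", rule$column, "'",
           call. = FALSE)
    }
    drop <- drop | (data[[rule$column]] == rule$equals)
  }
  out <- data[!drop, , drop = FALSE]
  attr(out, "mapping") <- mp
  class(out) <- class(data)
  out
}

.index_row <- function(est, wave, outcome, region = "(national)") {
  data.frame(
    wave = wave, outcome = outcome, region = region,
    variant = est$variant, value = est$value, se = est$se,
    ci_low = est$ci_low, ci_high = est$ci_high,
    p_value = est$p_value, stars = est$stars,
    classification = classify_inequality(est),
    n = est$n, stringsAsFactors = FALSE
  )
}

#' Run a full utilisation-inequality study
#'
#' For every wave and outcome: applies the adult and outcome-specific
#' eligibility filters, computes the weighted prevalence with CI, the chosen
#' concentration index with CI, significance stars and pro-rich/pro-poor
#' classification (nationally and, optionally, within each region after
#' re-ranking), and the probit decomposition of the Erreygers index. Fully
#' deterministic given the config's seeds. A stratum with no eligible rows is
#' reported as an empty cell, never a crash.
#'
#' @param config a [study_config()].
#' @return a `study_report` with data.frames `prevalence`, `indices`,
#'   `indices_by_region`, a named list `decompositions`, a `filter_log`, and
#'   run `meta` (seed, config hash, package version).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  prevalence <- list()
  indices <- list()
  by_region <- list()
  decomps <- list()
  logs <- list()
  oc_counter <- 0L

  for (wv in names(config$waves)) {
    data <- .load_wave(config$waves[[wv]])
    data <- .apply_row_exclusions(data, config$exclude_rows)
    ad <- filter_adults(data, config$min_age)
    ad$log$wave <- wv
    logs[[length(logs) + 1L]] <- ad$log
    data <- ad$data
    mp <- attr(data, "mapping")
    outcome_names <- config$outcomes %||% names(mp$outcomes)

    for (oc in outcome_names) {
      oc_counter <- oc_counter + 1L
      ef <- eligibility_filter(data, oc)
      ef$log$wave <- wv
      logs[[length(logs) + 1L]] <- ef$log
      d <- ef$data
      if (nrow(d) == 0) {
        prevalence[[length(prevalence) + 1L]] <-
          data.frame(wave = wv, outcome = oc, n_users = 0L, n = 0L,
                     pct = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
        next
      }
      h <- d[[oc]]
      w <- d[[mp$weight]]
      prev <- prevalence_estimate(h, w, config$ci_level)
      prevalence[[length(prevalence) + 1L]] <-
        cbind(data.frame(wave = wv, outcome = oc), prev)

      ranked <- fractional_rank(d[[mp$income]], w)
      est <- index_ci(
        h, ranked, w, variant = config$variant, method = config$ci_method,
        ci_level = config$ci_level, n_boot = config$n_boot,
        seed = if (!is.null(config$seed)) config$seed + oc_counter else NULL,
        cluster_id = if (!is.null(mp$psu)) d[[mp$psu]] else NULL
      )
      indices[[length(indices) + 1L]] <- .index_row(est, wv, oc)

      if (isTRUE(config$by_region) && !is.null(mp$region)) {
        for (rg in sort(unique(d[[mp$region]]))) {
          sel <- d[[mp$region]] == rg
          if (!any(sel)) next
          hr <- h[sel]
          wr <- w[sel]
          row <- tryCatch({
            rr <- fractional_rank(d[[mp$income]][sel], wr)
            er <- index_ci(
              hr, rr, wr, variant = config$variant,
              method = config$ci_method, ci_level = config$ci_level,
              n_boot = config$n_boot,
              seed = if (!is.null(config$seed)) config$seed + oc_counter else NULL,
              cluster_id = if (!is.null(mp$psu)) d[[mp$psu]][sel] else NULL
            )
            .index_row(er, wv, oc, rg)
          }, error = function(e) {
            data.frame(wave = wv, outcome = oc, region = rg,
                       variant = config$variant, value = NA_real_,
                       se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       p_value = NA_real_, stars = "",
                       classification = NA_character_, n = sum(sel),
                       stringsAsFactors = FALSE)
          })
          by_region[[length(by_region) + 1L]] <- row
        }
      }

      if (!is.null(config$design_covariates)) {
        dc <- tryCatch({
          des <- covariate_design(d, config$design_covariates,
                                  roles = config$roles)
          decompose_index(h, des, ranked, w,
                          share_floor = config$share_floor)
        }, error = function(e) e)
        decomps[[paste(wv, oc, sep = ":")]] <- dc
      }
    }
  }

  structure(
    list(
      prevalence = do.call(rbind, prevalence),
      indices = do.call(rbind, indices),
      indices_by_region = if (length(by_region)) do.call(rbind, by_region) else NULL,
      decompositions = decomps,
      filter_log = do.call(rbind, logs),
      meta = list(seed = config$seed,
                  variant = config$variant,
                  ci_method = config$ci_method,
                  config_hash = .config_hash(config),
                  package_version = as.character(utils::packageVersion("hcineq")))
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  waves x outcomes: %d prevalence cell(s), %d national index cell(s)\n",
              nrow(x$prevalence), nrow(x$indices)))
  if (!is.null(x$indices_by_region)) {
    cat(sprintf("  regional index cells: %d\n", nrow(x$indices_by_region)))
  }
  cat(sprintf("  decompositions: %d; seed %s; config %s\n",
              length(x$decompositions), x$meta$seed, x$meta$config_hash))
  invisible(x)
}

.fmt_md_num <- function(x, digits = 3) {
  ifelse(is.na(x), "", formatC(x, digits = digits, format = "f"))
}

.md_table <- function(df, digits = 3) {
  cols <- names(df)
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(cols, function(cn) {
      v <- df[[cn]][i]
      if (is.numeric(v)) .fmt_md_num(v, digits) else as.character(v)
    }, character(1))
    paste0("| ", paste(cells, collapse = " | "), " |")
  }, character(1))
  c(paste0("| ", paste(cols, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
    body)
}

#' Render a study report to files
#'
#' Writes the report tables as a CSV bundle, a single JSON document, and/or a
#' markdown summary with the conventional significance-star footnote
#' (* p < 0.1, ** p < 0.05, *** p < 0.01). Column order is stable and the run
#' metadata contains no wall-clock values, so identical reports render to
#' byte-identical files.
#'
#' @param report a [run_study()] report.
#' @param dir output directory (created if needed).
#' @param formats subset of `"csv"`, `"json"`, `"markdown"`.
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(report, dir, formats = c("csv", "json", "markdown")) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  }
  written <- character()

  decomp_tables <- lapply(report$decompositions, function(d) {
    if (inherits(d, "decomposition")) {
      tab <- d$table
      tab <- rbind(tab, data.frame(
        term = "residual", role = "(residual)", beta_m = NA_real_,
        beta_m_overall = NA_real_, averaging_rule = "",
        gc = NA_real_, contribution = d$residual_contribution,
        share = if (d$shares_suppressed) NA_real_ else
          d$residual_contribution / d$total_index,
        stringsAsFactors = FALSE
      ))
      attr(tab, "suppressed") <- d$shares_suppressed
      attr(tab, "total_index") <- d$total_index
      tab
    } else NULL
  })

  if ("csv" %in% formats) {
    for (nm in c("prevalence", "indices", "indices_by_region", "filter_log")) {
      obj <- report[[nm]]
      if (is.null(obj)) next
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(obj, f, row.names = FALSE)
      written <- c(written, f)
    }
    for (nm in names(decomp_tables)) {
      tab <- decomp_tables[[nm]]
      if (is.null(tab)) next
      f <- file.path(dir, paste0("decomposition_", gsub("[:/]", "_", nm), ".csv"))
      utils::write.csv(tab, f, row.names = FALSE)
      written <- c(written, f)
    }
  }

  if ("json" %in% formats) {
    payload <- list(
      meta = report$meta,
      prevalence = report$prevalence,
      indices = report$indices,
      indices_by_region = report$indices_by_region,
      decompositions = lapply(decomp_tables, function(tab) {
        if (is.null(tab)) return(NULL)
        list(total_index = attr(tab, "total_index"),
             shares_suppressed = attr(tab, "suppressed"),
             table = tab)
      }),
      filter_log = report$filter_log
    )
    f <- file.path(dir, "report.json")
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null", na = "null")
    written <- c(written, f)
  }

  if ("markdown" %in% formats) {
    lines <- c("# Utilisation-inequality study report", "")
    lines <- c(lines, "## Prevalence", "", .md_table(report$prevalence), "")
    lines <- c(lines, "## Concentration indices (national)", "",
               .md_table(report$indices), "")
    if (!is.null(report$indices_by_region)) {
      lines <- c(lines, "## Concentration indices by region", "",
                 .md_table(report$indices_by_region), "")
    }
    for (nm in names(decomp_tables)) {
      tab <- decomp_tables[[nm]]
      if (is.null(tab)) next
      lines <- c(lines, paste0("## Decomposition: ", nm), "",
                 .md_table(tab), "")
      if (isTRUE(attr(tab, "suppressed"))) {
        lines <- c(lines,
                   "Shares suppressed: |E(h)| below the share floor; raw contributions reported.",
                   "")
      }
    }
    lines <- c(lines, "\\* p < 0.1; \\*\\* p < 0.05; \\*\\*\\* p < 0.01", "")
    f <- file.path(dir, "report.md")
    writeLines(lines, f)
    written <- c(written, f)
  }

  log_f <- file.path(dir, "run_log.txt")
  writeLines(c(
    sprintf("hcineq %s", report$meta$package_version),
    sprintf("seed: %s", report$meta$seed),
    sprintf("config hash: %s", report$meta$config_hash),
    sprintf("variant: %s; ci method: %s", report$meta$variant,
            report$meta$ci_method),
    "filter counts:",
    utils::capture.output(print(report$filter_log, row.names = FALSE))
  ), log_f)
  written <- c(written, log_f)
  invisible(written)
}

#' Validate a rendered JSON report against the bundled schema
#'
#' Light structural validation of `report.json` against the JSON-Schema
#' document shipped in `extdata/study_report_schema.json`: required top-level
#' fields, required per-row fields of the tabular sections, and container
#' types. Raises an error describing the first violation.
#'
#' @param path path to a `report.json` written by [render_report()].
#' @param schema_path path to the schema document.
#' @return `TRUE`, invisibly, on success.
#' @export
validate_report_json <- function(path,
                                 schema_path = system.file(
                                   "extdata", "study_report_schema.json",
                                   package = "hcineq")) {
  doc <- jsonlite::read_json(path)
  schema <- jsonlite::read_json(schema_path)
  req <- unlist(schema$required)
  missing_top <- setdiff(req, names(doc))
  if (length(missing_top)) {
    stop("report JSON missing required field(s): ",
         paste(missing_top, collapse = ", "), call. = FALSE)
  }
  for (nm in names(schema$properties)) {
    prop <- schema$properties[[nm]]
    if (!nm %in% names(doc) || is.null(doc[[nm]])) next
    if (identical(prop$type, "object") && !is.list(doc[[nm]])) {
      stop("report JSON field '", nm, "' must be an object", call. = FALSE)
    }
    if (identical(prop$type, "array")) {
      if (!is.list(doc[[nm]])) {
        stop("report JSON field '", nm, "' must be an array", call. = FALSE)
      }
      row_req <- unlist(prop$items$required)
      for (row in doc[[nm]]) {
        miss <- setdiff(row_req, names(row))
        if (length(miss)) {
          stop("report JSON rows of '", nm, "' missing field(s): ",
               paste(miss, collapse = ", "), call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}
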