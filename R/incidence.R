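#' Select incident hip-fracture cases from an admission line list
#'
#' Applies the case definition: ICD-10 codes S72.0, S72.1 or S72.2 (any
#' further subdigits), age 40 or older at admission, admission inside the
#' study window, with no exclusion by injury severity. Within each patient,
#' admissions falling within `window_days` of an earlier retained admission
#' are dropped as repeat admissions for the same fracture; the earliest
#' admission defines the case's age and calendar year. Records with an
#' unparseable date or missing sex are skipped with a warning giving the
#' count.
#'
#' @param records Data frame of admissions with columns `patient_id`,
#'   `admission_date` (Date or ISO-8601 string), `sex`, `icd10`, and either
#'   `age` (completed years at admission) or `birth_date`; `nationality` is
#'   carried through when present.
#' @param window_days Deduplication window in days (default 365): two hip
#'   admissions of one patient closer than this are treated as the same
#'   fracture, regardless of subcode.
#' @param study_years Optional integer vector; admissions outside these
#'   calendar years are excluded.
#' @return Tibble of cases (class `fracture_cases`) with one row per patient
#'   per fracture episode, including `age_band` and `year`.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   patient_id = c("a", "a", "b"),
#'   admission_date = as.Date(c("2017-02-01", "2017-03-03", "2017-06-01")),
#'   age = c(72, 72, 39), sex = "female", icd10 = c("S72.0", "S72.1", "S72.2")
#' )
#' select_index_admissions(recs) # one case: patient a; b fails the age floor
select_index_admissions <- function(records, window_days = 365,
                                    study_years = NULL) {
  stopifnot(window_days > 0)
  records <- tibble::as_tibble(records)
  req <- c("patient_id", "admission_date", "sex", "icd10")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("line list lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"age" %in% names(records) && !"birth_date" %in% names(records)) {
    abort("line list needs an `age` or `birth_date` column")
  }

  records$admission_date <- as.Date(records$admission_date)
  if (!"age" %in% names(records)) records$age <- NA_real_
  if ("birth_date" %in% names(records)) {
    bd <- as.Date(records$birth_date)
    derived <- floor(as.numeric(records$admission_date - bd) / 365.25)
    records$age <- dplyr::coalesce(records$age, derived)
  }

  bad <- is.na(records$admission_date) | is.na(records$sex) |
    records$sex == "" | is.na(records$age)
  if (any(bad)) {
    warn(sprintf("skipping %d record(s) with missing date, sex or age",
                 sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }
  n_skipped <- sum(bad)

  cases <- records |>
    dplyr::filter(
      grepl("^S72\\.?[012]", .data$icd10),
      .data$age >= 40
    )
  if (!is.null(study_years)) {
    cases <- dplyr::filter(
      cases, as.integer(format(.data$admission_date, "%Y")) %in% study_years
    )
  }

  cases <- cases |>
    dplyr::arrange(.data$patient_id, .data$admission_date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter(keep_index(.data$admission_date, window_days)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      age_band = assign_age_band(.data$age),
      year = as.integer(format(.data$admission_date, "%Y"))
    )

  attr(cases, "n_skipped") <- n_skipped
  class(cases) <- c("fracture_cases", class(cases))
  cases
}

# greedy dedup: keep a sorted date only if > window days after the last kept
keep_index <- function(dates, window) {
  keep <- logical(length(dates))
  last <- as.Date(NA)
  for (i in seq_along(dates)) {
    if (is.na(last) || as.numeric(dates[i] - last) > window) {
      keep[i] <- TRUE
      last <- dates[i]
    }
  }
  keep
}

#' Person-years of observation by sex and age band
#'
#' Each person contributes one person-year per calendar year, so person-years
#' are the sum of mid-year head counts over the study years (the convention
#' used with annually projected denominators).
#'
#' @param population Population table: `year`, `sex`, `nationality`,
#'   `age_band`, `count`.
#' @param years Calendar years to include (default: all years present).
#' @param scope `"all"`, `"national"` or `"expatriate"`: which nationality
#'   stratum forms the denominator.
#' @return Tibble with columns `sex`, `age_band`, `py`.
#' @export
person_years <- function(population,
                         years = NULL,
                         scope = c("all", "national", "expatriate")) {
  scope <- match.arg(scope)
  population <- tibble::as_tibble(population)
  years <- years %||% sort(unique(population$year))
  pop <- dplyr::filter(population, .data$year %in% years)
  if (scope != "all") {
    pop <- dplyr::filter(pop, .data$nationality == scope)
  }
  full <- tidyr::crossing(
    year = years, sex = unique(pop$sex), age_band = unique(pop$age_band)
  )
  have <- dplyr::distinct(pop, .data$year, .data$sex, .data$age_band)
  gaps <- dplyr::anti_join(full, have, by = c("year", "sex", "age_band"))
  if (nrow(gaps) > 0) {
    g <- gaps[1, ]
    abort(sprintf(
      "population table is missing stratum %s / %s / %s (and %d more)",
      g$year, g$sex, g$age_band, nrow(gaps) - 1
    ))
  }
  pop |>
    dplyr::group_by(.data$sex, .data$age_band) |>
    dplyr::summarise(py = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$sex, band_lower(.data$age_band))
}

#' Exact (Garwood) Poisson confidence limits for an incidence rate
#'
#' Two-sided interval for a Poisson count `n` observed over `py`
#' person-years, from chi-square quantiles: the lower limit is
#' `qchisq(alpha/2, 2n) / 2 / py` (zero when `n = 0`) and the upper limit is
#' `qchisq(1 - alpha/2, 2n + 2) / 2 / py`. Valid at small counts, where the
#' interval is markedly asymmetric around the point estimate.
#'
#' @param n Event counts (vectorised).
#' @param py Person-years at risk.
#' @param conf_level Coverage (default 0.95).
#' @param per Reporting scale (default per 100,000 person-years).
#' @return Tibble with columns `rate`, `ci_low`, `ci_high` on the `per` scale.
#' @export
#' @examples
#' exact_poisson_ci(7, 16627) # 42.1 (16.9 - 86.7) per 100,000
exact_poisson_ci <- function(n, py, conf_level = 0.95, per = 1e5) {
  stopifnot(all(n >= 0), all(py > 0))
  alpha <- 1 - conf_level
  low <- ifelse(n == 0, 0, qchisq(alpha / 2, 2 * n) / 2)
  high <- qchisq(1 - alpha / 2, 2 * n + 2) / 2
  tibble::tibble(
    rate = n / py * per, ci_low = low / py * per, ci_high = high / py * per
  )
}

#' Incidence rates with exact Poisson confidence intervals by stratum
#'
#' Tallies cases by sex and age band, joins the person-year denominators and
#' returns rates per 100,000 person-years with exact (Garwood) 95%
#' confidence intervals. Strata present in the denominator but without cases
#' are reported with `n = 0`, rate 0 and the exact upper bound. Values are
#' kept at full precision; use [format_incidence()] for one-decimal
#' presentation.
#'
#' @param cases Output of [select_index_admissions()] (or any data frame with
#'   `sex` and `age_band`).
#' @param py Person-year table from [person_years()].
#' @param conf_level Coverage of the interval (default 0.95).
#' @param per Reporting scale (default per 100,000).
#' @return Tibble (class `incidence_table`): `sex`, `age_band`, `n`, `py`,
#'   `rate`, `ci_low`, `ci_high`.
#' @export
estimate_rates <- function(cases, py, conf_level = 0.95, per = 1e5) {
  if (any(py$py <= 0)) abort("person-years must be positive in every stratum")
  counts <- tibble::as_tibble(cases) |>
    dplyr::count(.data$sex, .data$age_band, name = "n") |>
    dplyr::mutate(age_band = as.character(.data$age_band))
  out <- py |>
    dplyr::mutate(age_band = as.character(.data$age_band)) |>
    dplyr::left_join(counts, by = c("sex", "age_band")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  ci <- exact_poisson_ci(out$n, out$py, conf_level = conf_level, per = per)
  out <- dplyr::bind_cols(
    dplyr::select(out, "sex", "age_band", "n", "py"), ci
  ) |>
    dplyr::arrange(.data$sex, band_lower(.data$age_band))
  class(out) <- c("incidence_table", class(out))
  attr(out, "per") <- per
  out
}

#' Format an incidence table for presentation
#'
#' Renders each stratum as `"rate (low-high)"` with one decimal, the layout
#' conventional for registry incidence tables.
#'
#' @param table An `incidence_table` from [estimate_rates()].
#' @return Tibble with `sex`, `age_band`, `n`, `py` and a `formatted` string.
#' @export
format_incidence <- function(table) {
  tibble::as_tibble(table) |>
    dplyr::mutate(formatted = sprintf(
      "%.1f (%.1f-%.1f)", .data$rate, .data$ci_low, .data$ci_high
    )) |>
    dplyr::select("sex", "age_band", "n", "py", "formatted")
}

#' Directly age-standardized rate with Fay-Feuer gamma interval
#'
#' Weighted average of the age-specific rates using a fixed standard
#' population's age distribution (weights computed within sex and summing to
#' one), with the gamma-distribution confidence interval of Fay and Feuer,
#' which retains validity for sparse counts.
#'
#' @param table An `incidence_table` from [estimate_rates()].
#' @param standard Standard population: data frame with `sex`, `age_band`,
#'   `count` (a `year` column, if present, is summed over).
#' @param conf_level Coverage (default 0.95).
#' @return Tibble (class `standardized_rate`) with one row per sex: `rate`,
#'   `se`, `ci_low`, `ci_high` on the table's reporting scale, plus the
#'   weights as a list column.
#' @export
age_standardize <- function(table, standard, conf_level = 0.95) {
  per <- attr(table, "per") %||% 1e5
  std <- tibble::as_tibble(standard) |>
    dplyr::group_by(.data$sex, age_band = as.character(.data$age_band)) |>
    dplyr::summarise(std_count = sum(.data$count), .groups = "drop")
  tab <- tibble::as_tibble(table) |>
    dplyr::mutate(age_band = as.character(.data$age_band))
  gaps <- dplyr::anti_join(tab, std, by = c("sex", "age_band"))
  if (nrow(gaps) > 0) {
    abort(sprintf("standard population lacks band(s): %s",
                  paste(unique(gaps$age_band), collapse = ", ")))
  }
  alpha <- 1 - conf_level
  out <- tab |>
    dplyr::inner_join(std, by = c("sex", "age_band")) |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(
      rate = {
        w <- .data$std_count / sum(.data$std_count)
        sum(w * .data$n / .data$py) * per
      },
      se = {
        w <- .data$std_count / sum(.data$std_count)
        sqrt(sum((w / .data$py)^2 * .data$n)) * per
      },
      ci_low = {
        w <- .data$std_count / sum(.data$std_count) * per / .data$py
        fay_feuer_limits(sum(w * .data$n), sum(w^2 * .data$n), max(w),
                         alpha)[1]
      },
      ci_high = {
        w <- .data$std_count / sum(.data$std_count) * per / .data$py
        fay_feuer_limits(sum(w * .data$n), sum(w^2 * .data$n), max(w),
                         alpha)[2]
      },
      weights = {
        w <- .data$std_count / sum(.data$std_count)
        list(stats::setNames(w, .data$age_band))
      },
      .groups = "drop"
    )
  class(out) <- c("standardized_rate", class(out))
  attr(out, "per") <- per
  out
}

# Fay-Feuer gamma limits for a weighted Poisson sum:
# R = sum w_i x_i, v = sum w_i^2 x_i, wm = max weight
fay_feuer_limits <- function(R, v, wm, alpha) {
  low <- if (R <= 0) 0 else qgamma(alpha / 2, shape = R^2 / v) * v / R
  up <- qgamma(1 - alpha / 2, shape = (R + wm)^2 / (v + wm^2)) *
    (v + wm^2) / (R + wm)
  c(low, up)
}

#' Compare two age-standardized rates
#'
#' Two-sided z-test on the log scale: with delta-method standard errors
#' `SE_ln = SE / rate`, the statistic is
#' `z = (ln b - ln a) / sqrt(SE_ln_a^2 + SE_ln_b^2)` and
#' `p = 2 (1 - Phi(|z|))`. Rows are matched by sex when both inputs carry a
#' `sex` column.
#'
#' @param a,b `standardized_rate` tibbles from [age_standardize()] (or data
#'   frames with `rate` and `se`, optionally `sex`).
#' @return Tibble with `rate_a`, `rate_b`, `ratio` (b/a), `z`, `p_value`
#'   (per sex when applicable).
#' @export
compare_standardized <- function(a, b) {
  a <- tibble::as_tibble(a)
  b <- tibble::as_tibble(b)
  if ("sex" %in% names(a) && "sex" %in% names(b)) {
    m <- dplyr::inner_join(
      dplyr::select(a, "sex", rate_a = "rate", se_a = "se"),
      dplyr::select(b, "sex", rate_b = "rate", se_b = "se"),
      by = "sex"
    )
  } else {
    m <- tibble::tibble(rate_a = a$rate, se_a = a$se,
                        rate_b = b$rate, se_b = b$se)
  }
  if (any(m$rate_a <= 0 | m$rate_b <= 0)) {
    abort(paste(
      "a standardized rate is zero; the log-scale z-test is undefined -",
      "use an exact conditional Poisson comparison on the raw counts"
    ))
  }
  m |>
    dplyr::mutate(
      ratio = .data$rate_b / .data$rate_a,
      z = (log(.data$rate_b) - log(.data$rate_a)) /
        sqrt((.data$se_a / .data$rate_a)^2 + (.data$se_b / .data$rate_b)^2),
      p_value = 2 * (1 - pnorm(abs(.data$z)))
    ) |>
    dplyr::select(-"se_a", -"se_b")
}

#' Crude female:male incidence ratio
#'
#' Ratio of the crude (all-ages) female rate to the crude male rate.
#'
#' @param cases Case table with a `sex` column.
#' @param py Person-year table from [person_years()].
#' @return A single number, (female events / female PY) / (male events /
#'   male PY).
#' @export
crude_sex_ratio <- function(cases, py) {
  n <- tibble::as_tibble(cases) |> dplyr::count(.data$sex)
  d <- py |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(py = sum(.data$py)) |>
    dplyr::left_join(n, by = "sex") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  male <- d[d$sex == "male", ]
  female <- d[d$sex == "female", ]
  if (male$n == 0) abort("male crude rate is zero; ratio undefined")
  (female$n / female$py) / (male$n / male$py)
}
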