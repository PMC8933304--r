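#' Assemble a pipeline run configuration
#'
#' Collects the inputs and settings for a full model-construction run. Each
#' data input may be given as a file path (read with the package's readers)
#' or as an in-memory data frame.
#'
#' @param line_list Admission line list (path or data frame).
#' @param population Population denominators (path or data frame).
#' @param life_table Life table (path or data frame).
#' @param ratio_table MOF:hip ratio table (path or data frame); `NULL` skips
#'   the MOF stage.
#' @param study_years Calendar years of the study window.
#' @param dedup_window Days within which repeat admissions of one patient
#'   count as the same fracture (default 365).
#' @param scope Nationality stratum whose incidence feeds the model
#'   (default `"national"` — a country model is built on its nationals).
#' @param smoothing `"quadratic"` or `"spline"`.
#' @param spline_df Degrees of freedom when `smoothing = "spline"`.
#' @param terminal_age Closed end of the hazard tables (default 105).
#' @param curve_ages Starting ages for the 10-year probability curve.
#' @param horizon Probability horizon in years (default 10).
#' @param lifetime_from Age from which the remaining lifetime probability is
#'   reported (default 50).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @param out_dir Directory for output files, or `NULL` to return results
#'   in memory only.
#' @return A `run_config` list.
#' @export
run_config <- function(line_list, population, life_table,
                       ratio_table = NULL,
                       study_years = 2017:2019,
                       dedup_window = 365,
                       scope = c("national", "expatriate", "all"),
                       smoothing = c("quadratic", "spline"),
                       spline_df = 3,
                       terminal_age = 105,
                       curve_ages = seq(50, 90, by = 5),
                       horizon = 10,
                       lifetime_from = 50,
                       seed = 1L,
                       out_dir = NULL) {
  structure(
    list(
      line_list = line_list, population = population,
      life_table = life_table, ratio_table = ratio_table,
      study_years = as.integer(study_years),
      dedup_window = dedup_window,
      scope = match.arg(scope),
      smoothing = match.arg(smoothing), spline_df = spline_df,
      terminal_age = terminal_age,
      curve_ages = curve_ages, horizon = horizon,
      lifetime_from = lifetime_from,
      seed = as.integer(seed), out_dir = out_dir
    ),
    class = "run_config"
  )
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(sprintf("input file not found: %s", x))
    reader(x)
  } else {
    tibble::as_tibble(x)
  }
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full model-construction pipeline
#'
#' Executes, in order: case selection, person-years, incidence rates with
#' exact Poisson intervals, direct age standardization of nationals vs
#' expatriates (with the national population as the standard), hazard
#' smoothing, MOF imputation (when a ratio table is supplied), mortality
#' hazard construction, 10-year probability curves per sex and outcome, and
#' the remaining lifetime probability. A manifest records the configuration
#' hash, seed, package version and record-drop counts; when `out_dir` is
#' set, every table is written as CSV carrying the configuration hash and
#' the manifest as JSON.
#'
#' @param config A [run_config()].
#' @return Named list (class `frax_run`): `cases`, `incidence`,
#'   `standardized`, `comparison`, `hazards`, `probabilities`, `lifetime`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  line_list <- resolve_input(config$line_list, read_line_list)
  population <- resolve_input(config$population, read_population)
  life_table <- resolve_input(config$life_table, read_life_table)
  ratios <- if (!is.null(config$ratio_table)) {
    resolve_input(config$ratio_table, read_ratio_table)
  }

  settings <- config[setdiff(names(config), "out_dir")]
  settings$line_list <- NULL
  settings$population <- NULL
  settings$life_table <- NULL
  settings$ratio_table <- NULL
  config_hash <- rlang::hash(list(
    settings = settings, line_list = line_list, population = population,
    life_table = life_table, ratios = ratios
  ))

  n_skipped <- 0
  cases <- run_stage("select_index_admissions", {
    withCallingHandlers(
      select_index_admissions(line_list, window_days = config$dedup_window,
                              study_years = config$study_years),
      warning = function(w) invokeRestart("muffleWarning")
    )
  })
  n_skipped <- attr(cases, "n_skipped") %||% 0

  model_cases <- if (config$scope == "all") {
    cases
  } else {
    dplyr::filter(cases, .data$nationality == config$scope)
  }

  py <- run_stage("person_years", {
    person_years(population, years = config$study_years,
                 scope = config$scope)
  })
  incidence <- run_stage("estimate_rates", estimate_rates(model_cases, py))

  # stratum comparison: nationals vs expatriates, national age structure
  # as the standard (only possible when both strata are present)
  standardized <- NULL
  comparison <- NULL
  if (all(c("national", "expatriate") %in% population$nationality) &&
      "nationality" %in% names(cases)) {
    standardized <- run_stage("age_standardize", {
      std_pop <- dplyr::filter(population,
                               .data$nationality == "national",
                               .data$year %in% config$study_years)
      nat <- estimate_rates(
        dplyr::filter(cases, .data$nationality == "national"),
        person_years(population, config$study_years, "national")
      )
      exp <- estimate_rates(
        dplyr::filter(cases, .data$nationality == "expatriate"),
        person_years(population, config$study_years, "expatriate")
      )
      list(
        national = age_standardize(nat, std_pop),
        expatriate = age_standardize(exp, std_pop)
      )
    })
    comparison <- tryCatch(
      compare_standardized(standardized$national, standardized$expatriate),
      error = function(e) NULL
    )
  }

  hip <- run_stage("smooth_incidence", {
    smooth_incidence(incidence, method = config$smoothing,
                     df = config$spline_df,
                     terminal_age = config$terminal_age)
  })
  death <- run_stage("mortality_hazard", {
    mortality_hazard(life_table, terminal_age = config$terminal_age)
  })
  mof <- if (!is.null(ratios)) {
    run_stage("mof_from_hip", mof_from_hip(hip, ratios))
  }
  hazards <- dplyr::bind_rows(hip, mof, death)
  class(hazards) <- c("hazard_curve", class(tibble::tibble()))

  fracture_curves <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(hip), outcome = "hip"),
    if (!is.null(mof)) dplyr::mutate(tibble::as_tibble(mof), outcome = "mof")
  )
  probabilities <- run_stage("probability_curve", {
    fracture_curves |>
      dplyr::group_by(.data$sex, .data$outcome) |>
      dplyr::group_modify(function(d, key) {
        ch <- competing_hazards(d, death[death$sex == key$sex, ])
        probability_curve(ch, ages = config$curve_ages,
                          horizon = config$horizon)
      }) |>
      dplyr::ungroup()
  })
  class(probabilities) <- c("probability_curve_table",
                            class(tibble::tibble()))

  lifetime <- run_stage("lifetime_probability", {
    fracture_curves |>
      dplyr::group_by(.data$sex, .data$outcome) |>
      dplyr::group_modify(function(d, key) {
        ch <- competing_hazards(d, death[death$sex == key$sex, ])
        tibble::as_tibble(
          lifetime_probability(ch, config$lifetime_from,
                               terminal_age = config$terminal_age)
        )
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(percent = 100 * .data$probability)
  })

  manifest <- list(
    config_hash = config_hash,
    seed = config$seed,
    package = "fraxbuildr",
    version = as.character(utils::packageVersion("fraxbuildr")),
    settings = settings,
    n_records_in = nrow(line_list),
    n_records_skipped = n_skipped,
    n_cases = nrow(cases),
    n_model_cases = nrow(model_cases)
  )

  result <- structure(
    list(cases = cases, incidence = incidence, standardized = standardized,
         comparison = comparison, hazards = hazards,
         probabilities = probabilities, lifetime = lifetime,
         manifest = manifest),
    class = "frax_run"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_output(incidence, p("incidence.csv"), config_hash)
    if (!is.null(standardized)) {
      std_tab <- dplyr::bind_rows(
        dplyr::mutate(dplyr::select(standardized$national, -"weights"),
                      stratum = "national"),
        dplyr::mutate(dplyr::select(standardized$expatriate, -"weights"),
                      stratum = "expatriate")
      )
      write_output(std_tab, p("standardized.csv"), config_hash)
    }
    if (!is.null(comparison)) {
      write_output(comparison, p("comparison.csv"), config_hash)
    }
    write_output(hazards, p("hazard_curves.csv"), config_hash)
    write_output(probabilities, p("probabilities.csv"), config_hash)
    write_output(lifetime, p("lifetime.csv"), config_hash)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  result
}

#' @export
print.frax_run <- function(x, ...) {
  cat("<frax_run>\n")
  cat(sprintf("  cases: %d (of %d records)\n", x$manifest$n_cases,
              x$manifest$n_records_in))
  cat(sprintf("  incidence strata: %d\n", nrow(x$incidence)))
  cat(sprintf("  hazard curves: %s\n",
              paste(unique(x$hazards$kind), collapse = ", ")))
  cat(sprintf("  config hash: %s\n", x$manifest$config_hash))
  invisible(x)
}
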