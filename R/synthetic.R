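#' Configuration for the synthetic fracture registry
#'
#' Bundles every parameter of the synthetic data generator: the study years,
#' the population structure by sex and nationality stratum, a Gompertz
#' fracture hazard `h_f(age) = a * exp(b * age)` with stratum multipliers,
#' a Gompertz-Makeham death hazard `h_d(age) = alpha + beta * exp(c * age)`
#' per sex, and the duplicate-admission and decoy-record rates that exercise
#' the case-selection rules downstream.
#'
#' Defaults emulate a three-year national hip-fracture admission extract from
#' a Gulf-state population: a small national stratum (~12% of residents) with
#' an older age structure, a large expatriate stratum concentrated at working
#' ages, fracture incidence rising log-linearly with age at roughly the level
#' seen in Gulf registries (tens per 100,000 at 55-59 rising to several
#' hundred per 100,000 at 80+), a female:male hazard ratio of 1.25 and a
#' moderately higher expatriate rate.
#'
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @param years Calendar years covered (default 2017-2019).
#' @param pop_size Data frame with columns `sex`, `nationality`, `age_band`,
#'   `count`: mid-year head counts for the first year. Defaults to
#'   [default_population_structure()].
#' @param growth Per-year multiplicative population growth applied to later
#'   years (default 1, i.e. the first-year structure carried forward).
#' @param frac_hazard_scale Baseline fracture hazard `a` at age 0, per
#'   person-year.
#' @param frac_hazard_slope Log-hazard increase `b` per year of age.
#' @param sex_multiplier Female:male fracture hazard ratio.
#' @param expat_rate_multiplier Expatriate:national fracture hazard ratio.
#' @param dup_prob Probability that a fracture generates a second admission
#'   1-90 days after the first.
#' @param decoy_fraction Non-hip admissions (e.g. ICD-10 S82.x) appended per
#'   index fracture, as a fraction.
#' @param mort_makeham Named list with elements `male` and `female`, each
#'   `c(alpha, beta, c)` for the Gompertz-Makeham death hazard.
#' @return A `synthetic_config` list.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' pop <- generate_population(cfg)
#' head(pop)
synthetic_config <- function(seed = 1L,
                             years = 2017:2019,
                             pop_size = default_population_structure(),
                             growth = 1,
                             frac_hazard_scale = 7.5e-7,
                             frac_hazard_slope = 0.11,
                             sex_multiplier = 1.25,
                             expat_rate_multiplier = 1.4,
                             dup_prob = 0.1,
                             decoy_fraction = 0.05,
                             mort_makeham = list(
                               male = c(alpha = 6e-4, beta = 5e-5, c = 0.09),
                               female = c(alpha = 5e-4, beta = 3e-5, c = 0.09)
                             )) {
  if (length(years) < 1) abort("`years` must contain at least one year")
  pop_size <- tibble::as_tibble(pop_size)
  req <- c("sex", "nationality", "age_band", "count")
  missing_cols <- setdiff(req, names(pop_size))
  if (length(missing_cols) > 0) {
    abort(sprintf("`pop_size` lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(pop_size) == 0 || length(unique(pop_size$age_band)) == 0) {
    abort("`pop_size` must contain at least one age band")
  }
  if (any(pop_size$count < 0)) abort("`pop_size` counts must be >= 0")
  stopifnot(
    frac_hazard_scale >= 0, frac_hazard_slope >= 0,
    sex_multiplier >= 0, expat_rate_multiplier >= 0,
    growth > 0, decoy_fraction >= 0
  )
  if (dup_prob < 0 || dup_prob > 1) abort("`dup_prob` must be in [0, 1]")
  for (s in c("male", "female")) {
    if (any(mort_makeham[[s]] < 0)) {
      abort("Gompertz-Makeham parameters must be >= 0")
    }
  }
  structure(
    list(
      seed = as.integer(seed), years = as.integer(years),
      pop_size = pop_size, growth = growth,
      frac_hazard_scale = frac_hazard_scale,
      frac_hazard_slope = frac_hazard_slope,
      sex_multiplier = sex_multiplier,
      expat_rate_multiplier = expat_rate_multiplier,
      dup_prob = dup_prob, decoy_fraction = decoy_fraction,
      mort_makeham = mort_makeham
    ),
    class = "synthetic_config"
  )
}

#' Default first-year population structure for the synthetic registry
#'
#' Head counts by sex, nationality and five-year band emulating a small
#' national stratum with a conventional age pyramid and a much larger,
#' younger, male-skewed expatriate stratum.
#'
#' @return Tibble with columns `sex`, `nationality`, `age_band`, `count`.
#' @export
default_population_structure <- function() {
  bands <- age_band_labels()
  national <- c(9000, 8000, 7000, 5500, 4000, 2500, 1500, 900, 700)
  expat_m <- c(60000, 48000, 36000, 24000, 14000, 7000, 3000, 1200, 800)
  expat_f <- c(30000, 24000, 18000, 12000, 7000, 3500, 1500, 700, 500)
  dplyr::bind_rows(
    tibble::tibble(sex = "male", nationality = "national",
                   age_band = bands, count = national),
    tibble::tibble(sex = "female", nationality = "national",
                   age_band = bands, count = round(national * 1.05)),
    tibble::tibble(sex = "male", nationality = "expatriate",
                   age_band = bands, count = expat_m),
    tibble::tibble(sex = "female", nationality = "expatriate",
                   age_band = bands, count = expat_f)
  )
}

# Gompertz fracture hazard at a given age with stratum multipliers applied
fracture_hazard_at <- function(config, age, sex, nationality) {
  h <- config$frac_hazard_scale * exp(config$frac_hazard_slope * age)
  h <- h * ifelse(sex == "female", config$sex_multiplier, 1)
  h * ifelse(nationality == "expatriate", config$expat_rate_multiplier, 1)
}

# Gompertz-Makeham death hazard per sex
makeham_hazard_at <- function(config, age, sex) {
  p <- config$mort_makeham[[match.arg(sex, c("male", "female"))]]
  unname(p[1] + p[2] * exp(p[3] * age))
}

#' Generate a population table from a synthetic configuration
#'
#' Produces one row per calendar year, sex, nationality and age band with a
#' mid-year head count. Years after the first are the first-year counts grown
#' by a fixed per-year factor, mirroring denominators projected forward from
#' a single census year.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with columns `year`, `sex`, `nationality`, `age_band`,
#'   `count`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  tidyr::crossing(year = config$years, config$pop_size) |>
    dplyr::mutate(
      count = .data$count * config$growth^(.data$year - min(config$years))
    ) |>
    dplyr::arrange(.data$year, .data$sex, .data$nationality,
                   band_lower(.data$age_band))
}

#' Simulate a hip-fracture admission line list
#'
#' For every stratum-year cell of the population the number of incident
#' fractures is drawn as Poisson with mean `head count x h_f(band midpoint)`,
#' where `h_f` is the configured Gompertz hazard with sex and nationality
#' multipliers. Each fracture produces one index admission with a uniform
#' in-year date and an ICD-10 hip code (S72.0/S72.1/S72.2); with probability
#' `dup_prob` a duplicate admission of the same patient follows 1-90 days
#' later (possibly under a different hip subcode, as readmissions are often
#' recoded). A configurable fraction of decoy records with non-hip codes is
#' appended so the code filter downstream is exercised.
#'
#' Within closed bands the age at fracture is uniform over the band's five
#' single years; in the open 80+ band ages 80-100 are drawn with weights
#' proportional to the survival implied by the config's own death hazard.
#'
#' @param config A [synthetic_config()].
#' @param population Output of [generate_population()] (or compatible tibble).
#' @return Tibble of admission records: `patient_id`, `admission_date`,
#'   `birth_date`, `age`, `sex`, `nationality`, `icd10`.
#' @export
generate_line_list <- function(config, population) {
  stopifnot(inherits(config, "synthetic_config"))
  if (nrow(population) == 0) abort("`population` is empty")
  set.seed(config$seed)
  hip_codes <- c("S72.0", "S72.1", "S72.2")
  decoy_codes <- c("S82.1", "S52.5", "S42.2", "M80.0")

  cells <- population |>
    dplyr::mutate(
      mid = band_midpoint(.data$age_band),
      mean_n = .data$count *
        fracture_hazard_at(config, .data$mid, .data$sex, .data$nationality)
    )
  cells$n <- rpois(nrow(cells), cells$mean_n)

  draw_age <- function(band, n) {
    lo <- band_lower(band)
    if (is.finite(band_upper(band))) {
      sample(lo:(lo + 4L), n, replace = TRUE)
    } else {
      ages <- lo:(lo + 20L)
      # within-band ages thinned by the configured death hazard
      haz <- makeham_hazard_at(config, ages, "female")
      w <- exp(-cumsum(c(0, haz[-length(haz)])))
      sample(ages, n, replace = TRUE, prob = w / sum(w))
    }
  }

  rows <- purrr::pmap(cells, function(year, sex, nationality, age_band,
                                      count, mid, n, ...) {
    if (n == 0) return(NULL)
    age <- draw_age(age_band, n)
    day <- sample.int(365L, n, replace = TRUE) - 1L
    adm <- as.Date(sprintf("%d-01-01", year)) + day
    tibble::tibble(
      admission_date = adm, age = age, sex = sex, nationality = nationality,
      icd10 = sample(hip_codes, n, replace = TRUE)
    )
  })
  index <- dplyr::bind_rows(rows)
  if (nrow(index) == 0) {
    return(tibble::tibble(
      patient_id = character(), admission_date = as.Date(character()),
      birth_date = as.Date(character()), age = integer(),
      sex = character(), nationality = character(), icd10 = character()
    ))
  }
  index$patient_id <- sprintf("P%06d", seq_len(nrow(index)))
  # birth date consistent with completed age at the index admission
  index$birth_date <- index$admission_date -
    round((index$age + runif(nrow(index))) * 365.25)

  dup <- index[runif(nrow(index)) < config$dup_prob, , drop = FALSE]
  if (nrow(dup) > 0) {
    gap <- sample.int(90L, nrow(dup), replace = TRUE)
    dup$admission_date <- dup$admission_date + gap
    dup$age <- floor(as.numeric(dup$admission_date - dup$birth_date) / 365.25)
    dup$icd10 <- sample(hip_codes, nrow(dup), replace = TRUE)
  }

  n_decoy <- round(config$decoy_fraction * nrow(index))
  decoy <- NULL
  if (n_decoy > 0) {
    pick <- sample.int(nrow(index), n_decoy, replace = TRUE)
    decoy <- index[pick, , drop = FALSE]
    decoy$patient_id <- sprintf("D%06d", seq_len(n_decoy))
    decoy$admission_date <- decoy$admission_date +
      sample.int(200L, n_decoy, replace = TRUE) - 100L
    decoy$icd10 <- sample(decoy_codes, n_decoy, replace = TRUE)
  }

  dplyr::bind_rows(index, dup, decoy) |>
    dplyr::select("patient_id", "admission_date", "birth_date", "age",
                  "sex", "nationality", "icd10") |>
    dplyr::arrange(.data$admission_date, .data$patient_id)
}

#' Generate a single-year-of-age life table from Gompertz-Makeham mortality
#'
#' For each sex and single year of age 40-105 the central death rate is
#' `m(age) = alpha + beta * exp(c * age)` and the annual death probability is
#' `q = 1 - exp(-m)`.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with columns `sex`, `age`, `m`, `q`.
#' @export
generate_life_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  tidyr::crossing(sex = c("male", "female"), age = 40:105) |>
    dplyr::rowwise() |>
    dplyr::mutate(m = makeham_hazard_at(config, .data$age, .data$sex)) |>
    dplyr::ungroup() |>
    dplyr::mutate(q = 1 - exp(-.data$m))
}

#' True analytic hazards implied by a synthetic configuration
#'
#' Returns the generator's exact fracture and death hazards on the single-year
#' age grid, for validating what the estimation pipeline recovers.
#'
#' @param config A [synthetic_config()].
#' @param sex `"male"` or `"female"`.
#' @param nationality Stratum whose fracture hazard is wanted.
#' @param ages Age grid (default 40:105).
#' @return Tibble with columns `age`, `h_f`, `h_d`.
#' @export
true_hazards <- function(config, sex, nationality = "national",
                         ages = 40:105) {
  tibble::tibble(
    age = ages,
    h_f = fracture_hazard_at(config, ages, sex, nationality),
    h_d = makeham_hazard_at(config, ages, sex)
  )
}
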