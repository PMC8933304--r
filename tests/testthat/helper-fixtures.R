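# shared fixtures built in code; sizes kept modest so the default run stays
# fast while the statistical checks retain power

scaled_population <- function(scale = 1) {
  dplyr::mutate(default_population_structure(),
                count = round(count * scale))
}

# registry with the default study conditions, optionally scaled
make_registry <- function(seed = 7, scale = 1, ...) {
  cfg <- synthetic_config(seed = seed, pop_size = scaled_population(scale),
                          ...)
  pop <- generate_population(cfg)
  list(
    config = cfg, population = pop,
    line_list = generate_line_list(cfg, pop),
    life_table = generate_life_table(cfg)
  )
}

# a one-cell population: single sex / nationality / band / year
one_cell_config <- function(seed, count, band = "60-64", years = 2017L,
                            ...) {
  synthetic_config(
    seed = seed, years = years,
    pop_size = tibble::tibble(sex = "female", nationality = "national",
                              age_band = band, count = count),
    ...
  )
}

# admission rows with sensible defaults, for hand-built dedup cases
admission <- function(patient_id, admission_date, age = 70, sex = "female",
                      nationality = "national", icd10 = "S72.0") {
  tibble::tibble(
    patient_id = patient_id,
    admission_date = as.Date(admission_date),
    age = age, sex = sex, nationality = nationality, icd10 = icd10
  )
}

# incidence table straight from counts and person-years
incidence_from_counts <- function(n, py, sex = "female",
                                  bands = age_band_labels()[seq_along(n)]) {
  cases <- tibble::tibble(
    sex = rep(sex, sum(n)),
    age_band = rep(bands, times = n)
  )
  pyt <- tibble::tibble(sex = sex, age_band = bands, py = py)
  estimate_rates(cases, pyt)
}

ratio_fixture <- function() {
  read_ratio_table(
    system.file("extdata", "synthetic_mof_hip_ratios.csv",
                package = "fraxbuildr")
  )
}
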