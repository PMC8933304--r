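test_that("repeat admissions within the window collapse to one case", {
  recs <- dplyr::bind_rows(
    admission("a", "2017-02-01", icd10 = "S72.0"),
    admission("a", "2017-03-03", icd10 = "S72.1") # +30 days, recoded
  )
  expect_equal(nrow(select_index_admissions(recs)), 1)

  far <- dplyr::bind_rows(
    admission("b", "2017-02-01"),
    admission("b", "2018-03-08") # 400 days later: a new fracture
  )
  expect_equal(nrow(select_index_admissions(far)), 2)
})

test_that("age floor, code filter and study window apply", {
  recs <- dplyr::bind_rows(
    admission("a", "2017-02-01", age = 39),
    admission("b", "2017-02-01", icd10 = "S82.1"),
    admission("c", "2016-12-31"),
    admission("d", "2017-01-01", icd10 = "S72.2")
  )
  cases <- select_index_admissions(recs, study_years = 2017:2019)
  expect_equal(cases$patient_id, "d")
  expect_equal(as.character(cases$age_band), "70-74")
})

test_that("earliest admission defines the case; dedup is idempotent", {
  recs <- dplyr::bind_rows(
    admission("a", "2017-06-15", age = 74),
    admission("a", "2017-07-01", age = 75), # same episode, band boundary
    admission("b", "2018-01-10", age = 81),
    admission("b", "2019-06-10", age = 82) # > 365 days: second episode
  )
  once <- select_index_admissions(recs)
  expect_equal(once$age[once$patient_id == "a"], 74)
  twice <- select_index_admissions(once)
  expect_equal(nrow(twice), nrow(once))
  expect_equal(twice$admission_date, once$admission_date)
})

test_that("records with missing sex or unparseable dates are counted and
           skipped", {
  recs <- dplyr::bind_rows(
    admission("a", "2017-02-01"),
    admission("b", "2017-03-01", sex = NA)
  )
  recs$admission_date[1] <- NA
  expect_warning(cases <- select_index_admissions(recs), "2 record")
  expect_equal(nrow(cases), 0)
})

test_that("ages derive from birth_date when no age column is present", {
  recs <- tibble::tibble(
    patient_id = "a", admission_date = as.Date("2017-06-01"),
    birth_date = as.Date("1947-06-15"), # 69 completed years
    sex = "female", icd10 = "S72.0"
  )
  cases <- select_index_admissions(recs)
  expect_equal(cases$age, 69)
  expect_equal(as.character(cases$age_band), "65-69")
})

test_that("person-years sum mid-year head counts over the study years", {
  cfg <- one_cell_config(seed = 1, count = 10000, years = 2017:2019)
  pop <- generate_population(cfg)
  expect_equal(person_years(pop)$py, 30000)
  expect_equal(person_years(pop, years = 2018)$py, 10000)

  cfg2 <- one_cell_config(seed = 1, count = 10000, years = 2017:2019,
                          growth = 1.02)
  expect_equal(person_years(generate_population(cfg2))$py, 30604)
})

test_that("a missing stratum-year is a hard error naming the stratum", {
  cfg <- one_cell_config(seed = 1, count = 10000, years = 2017:2019)
  pop <- generate_population(cfg)
  expect_error(person_years(pop[pop$year != 2018, ], years = 2017:2019),
               "2018")
})

test_that("exact Poisson limits match their chi-square closed form", {
  # 7 events over 16,627 PY: the asymmetric small-count case
  ci <- exact_poisson_ci(7, 16627)
  expect_equal(round(ci$rate, 1), 42.1)
  expect_equal(round(ci$ci_low, 1), 16.9)
  expect_equal(round(ci$ci_high, 1), 86.7)

  # no events: lower limit exactly zero, upper from chi-square with 2 df
  ci0 <- exact_poisson_ci(0, 10000)
  expect_equal(ci0$rate, 0)
  expect_equal(ci0$ci_low, 0)
  expect_equal(round(ci0$ci_high, 1), 36.9)

  ci1 <- exact_poisson_ci(1, 5000)
  expect_true(ci1$ci_low < ci1$rate && ci1$rate < ci1$ci_high)
})

test_that("estimate_rates reports zero-case strata and rejects bad PY", {
  tab <- incidence_from_counts(c(0, 7), c(10000, 16627),
                               bands = c("40-44", "55-59"))
  expect_s3_class(tab, "incidence_table")
  expect_equal(tab$n, c(0L, 7L))
  expect_equal(tab$rate[1], 0)
  expect_gt(tab$ci_high[1], 0)
  expect_true(all(tab$ci_low <= tab$rate & tab$rate <= tab$ci_high))
  expect_match(format_incidence(tab)$formatted[2], "42.1 \\(16.9-86.7\\)")

  bad_py <- tibble::tibble(sex = "female", age_band = "40-44", py = 0)
  expect_error(estimate_rates(tibble::tibble(sex = "female",
                                             age_band = "40-44"), bad_py),
               "positive")
})

test_that("exact interval is conservative: coverage at least nominal at
           small counts", {
  # exact enumeration over the Poisson mass, no simulation noise
  coverage <- function(mu) {
    x <- 0:(mu + 15 * sqrt(mu) + 20)
    ci <- exact_poisson_ci(x, py = 1, per = 1)
    sum(dpois(x, mu) * (ci$ci_low <= mu & mu <= ci$ci_high))
  }
  for (mu in c(1, 3, 7, 20)) {
    cov <- coverage(mu)
    expect_gte(cov, 0.94)
    expect_lte(cov, 1)
  }
})

test_that("stratum intervals cover the generating hazard in at least 90%
           of strata", {
  # two registries x 2 sexes x 2 nationalities x 9 bands = 72 strata
  hits <- 0; total <- 0
  for (s in c(31, 32)) {
    reg <- make_registry(seed = s, scale = 1.5, dup_prob = 0,
                         decoy_fraction = 0)
    cases <- select_index_admissions(reg$line_list,
                                     study_years = reg$config$years)
    for (scope in c("national", "expatriate")) {
      py <- person_years(reg$population, scope = scope)
      tab <- estimate_rates(cases[cases$nationality == scope, ], py)
      truth <- fraxbuildr:::fracture_hazard_at(
        reg$config, band_midpoint(tab$age_band), tab$sex, scope
      ) * 1e5
      hits <- hits + sum(tab$ci_low <= truth & truth <= tab$ci_high)
      total <- total + nrow(tab)
    }
  }
  expect_gte(total, 50)
  expect_gte(hits / total, 0.90)
})
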