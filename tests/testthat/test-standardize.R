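std_pop <- function(counts, sex = "female",
                    bands = age_band_labels()[seq_along(counts)]) {
  tibble::tibble(sex = sex, age_band = bands, count = counts)
}

test_that("standardizing to the table's own person-year distribution
           recovers the crude rate", {
  tab <- incidence_from_counts(c(3, 10, 25), c(40000, 30000, 10000),
                               bands = c("60-64", "70-74", "80+"))
  std <- age_standardize(tab, std_pop(c(40000, 30000, 10000),
                                      bands = c("60-64", "70-74", "80+")))
  crude <- sum(tab$n) / sum(tab$py) * 1e5
  expect_equal(std$rate, crude, tolerance = 1e-12)
})

test_that("the standardized rate is the weighted mean of stratum rates", {
  # rates 10 and 30 per 1e5 with standard weights 0.25 / 0.75
  tab <- incidence_from_counts(c(10, 30), c(1e5, 1e5),
                               bands = c("60-64", "70-74"))
  std <- age_standardize(tab, std_pop(c(250, 750),
                                      bands = c("60-64", "70-74")))
  expect_equal(std$rate, 25)
  w <- std$weights[[1]]
  expect_equal(sum(w), 1)
  expect_equal(unname(w), c(0.25, 0.75))
})

test_that("standardization is linear in the stratum rates", {
  tab1 <- incidence_from_counts(c(4, 9, 18), c(5e4, 4e4, 2e4),
                                bands = c("60-64", "70-74", "80+"))
  tab3 <- incidence_from_counts(c(12, 27, 54), c(5e4, 4e4, 2e4),
                                bands = c("60-64", "70-74", "80+"))
  standard <- std_pop(c(5, 3, 2), bands = c("60-64", "70-74", "80+"))
  expect_equal(age_standardize(tab3, standard)$rate,
               3 * age_standardize(tab1, standard)$rate,
               tolerance = 1e-12)
})

test_that("a band missing from the standard population is a hard error", {
  tab <- incidence_from_counts(c(5, 5), c(1e4, 1e4),
                               bands = c("60-64", "70-74"))
  expect_error(age_standardize(tab, std_pop(1000, bands = "60-64")),
               "70-74")
})

test_that("gamma interval for the standardized rate holds its coverage at
           sparse registry-like counts", {
  # strata shaped like a national registry table: low PY, counts 0-20
  py <- c(16000, 15000, 14000, 12000, 9000, 6000, 4000, 2500, 2200) * 3
  true_rate <- c(5, 8, 15, 30, 55, 170, 210, 560, 900) / 1e5
  bands <- age_band_labels()
  standard <- std_pop(c(9, 8, 7, 5.5, 4, 2.5, 1.5, 0.9, 0.7) * 1000)
  w <- standard$count / sum(standard$count)
  target <- sum(w * true_rate) * 1e5

  set.seed(4242)
  n_rep <- 2000
  draws <- matrix(rpois(n_rep * 9, rep(true_rate * py, n_rep)),
                  nrow = n_rep, byrow = TRUE)
  covered <- vapply(seq_len(n_rep), function(i) {
    tab <- incidence_from_counts(draws[i, ], py)
    s <- age_standardize(tab, standard)
    s$ci_low <= target && target <= s$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("log-scale z-test behaves at its reference points", {
  same <- tibble::tibble(rate = 80, se = 8)
  expect_equal(compare_standardized(same, same)$p_value, 1)

  a <- tibble::tibble(rate = 74, se = 8)
  b <- tibble::tibble(rate = 107, se = 10)
  res <- compare_standardized(a, b)
  # hand-computed: z = log(107/74) / sqrt((8/74)^2 + (10/107)^2) = 2.581
  expect_equal(res$z, 2.581, tolerance = 2e-3)
  expect_lt(abs(res$p_value - 0.0099), 2e-4)
  expect_equal(res$ratio, 107 / 74)

  zero <- tibble::tibble(rate = 0, se = 1)
  expect_error(compare_standardized(zero, b), "exact")
})

test_that("z-test p-value agrees with a parametric bootstrap under the
           null", {
  # two registries with a genuine rate difference; the bootstrap refits the
  # whole standardization path under the pooled null
  py_a <- c(5e4, 4e4, 2e4)
  py_b <- c(6e4, 3e4, 1e4)
  n_a <- c(6, 14, 18)
  n_b <- c(14, 21, 16)
  bands <- c("60-64", "70-74", "80+")
  standard <- std_pop(c(5, 3, 2), bands = bands)

  tab_a <- incidence_from_counts(n_a, py_a, bands = bands)
  tab_b <- incidence_from_counts(n_b, py_b, bands = bands)
  std_a <- age_standardize(tab_a, standard)
  std_b <- age_standardize(tab_b, standard)
  p_z <- compare_standardized(std_a, std_b)$p_value

  # pooled stratum rates define the null; resample counts, re-standardize
  pooled <- (n_a + n_b) / (py_a + py_b)
  w <- standard$count / sum(standard$count)
  set.seed(99)
  n_boot <- 1e5
  ra <- matrix(rpois(n_boot * 3, rep(pooled * py_a, n_boot)),
               nrow = n_boot, byrow = TRUE)
  rb <- matrix(rpois(n_boot * 3, rep(pooled * py_b, n_boot)),
               nrow = n_boot, byrow = TRUE)
  sr_a <- ra %*% (w / py_a)
  sr_b <- rb %*% (w / py_b)
  ok <- sr_a > 0 & sr_b > 0
  obs <- abs(log(std_b$rate / std_a$rate))
  p_boot <- mean(abs(log(sr_b[ok] / sr_a[ok])) >= obs)
  expect_lt(abs(p_z - p_boot), 0.005)
})

test_that("crude sex ratio reproduces its defining arithmetic", {
  py <- tibble::tibble(sex = c("female", "male"),
                       age_band = "70-74", py = c(1e5, 1e5))
  equal <- tibble::tibble(sex = rep(c("female", "male"), each = 50),
                          age_band = "70-74")
  expect_equal(crude_sex_ratio(equal, py), 1)

  skew <- tibble::tibble(sex = rep(c("female", "male"), c(100, 80)),
                         age_band = "70-74")
  expect_equal(crude_sex_ratio(skew, py), 1.25)

  none <- tibble::tibble(sex = "female", age_band = "70-74")
  expect_error(crude_sex_ratio(none, py), "male")
})
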