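#' Smooth banded incidence into a continuous per-age hazard
#'
#' Fits a Poisson regression of the band event counts on band-midpoint age
#' with log link and log person-years offset — a log-quadratic in age by
#' default, since hip-fracture incidence is near-exponential in age and two
#' shape parameters avoid overfitting nine bands; a natural cubic spline with
#' configurable degrees of freedom is available for richer shapes. The fitted
#' hazard is evaluated at each single year of age from 40 to `max_fit_age`
#' (default 90) and carried forward as a constant to the terminal age; the
#' open 80+ band enters the fit at a conventional midpoint of 85.
#'
#' @param table An `incidence_table` from [estimate_rates()].
#' @param sex Optional: restrict to `"male"` or `"female"` (default: fit each
#'   sex present).
#' @param method `"quadratic"` (default) or `"spline"`.
#' @param df Spline degrees of freedom when `method = "spline"`.
#' @param terminal_age Last age on the grid (default 105).
#' @param max_fit_age Age beyond which the fitted value is held constant
#'   (default 90).
#' @param open_band_midpoint Midpoint assigned to the open band (default 85).
#' @return A `hazard_curve` tibble: `sex`, `kind = "hip"`, `age`, `hazard`
#'   (events per person-year). The underlying [stats::glm] fits are attached
#'   and surfaced by [tidy()] and [glance()].
#' @export
smooth_incidence <- function(table, sex = NULL,
                             method = c("quadratic", "spline"), df = 3,
                             terminal_age = 105, max_fit_age = 90,
                             open_band_midpoint = 85) {
  method <- match.arg(method)
  tab <- tibble::as_tibble(table)
  if (!is.null(sex)) tab <- tab[tab$sex %in% sex, , drop = FALSE]
  fits <- list()
  curves <- purrr::map(split(tab, tab$sex), function(d) {
    d <- d[d$py > 0, , drop = FALSE]
    if (nrow(d) < 4) {
      abort("need at least 4 age bands with positive person-years per sex")
    }
    d$mid <- band_midpoint(d$age_band, open_band_midpoint)
    ages <- 40:terminal_age
    if (all(d$n == 0)) {
      warn(sprintf("all counts zero for %s: returning a zero hazard curve",
                   d$sex[1]))
      return(tibble::tibble(sex = d$sex[1], kind = "hip", age = ages,
                            hazard = 0))
    }
    fit <- if (method == "quadratic") {
      glm(n ~ mid + I(mid^2) + offset(log(py)), family = poisson(), data = d)
    } else {
      glm(n ~ splines::ns(mid, df = df) + offset(log(py)),
          family = poisson(), data = d)
    }
    if (!fit$converged) {
      abort(sprintf(
        "Poisson smoothing did not converge for %s (bands: %d, events: %d)",
        d$sex[1], nrow(d), sum(d$n)
      ))
    }
    fits[[d$sex[1]]] <<- fit
    eval_age <- pmin(ages, max_fit_age)
    h <- predict(fit, newdata = data.frame(mid = eval_age, py = 1),
                 type = "response")
    tibble::tibble(sex = d$sex[1], kind = "hip", age = ages,
                   hazard = unname(h))
  })
  out <- dplyr::bind_rows(curves)
  class(out) <- c("hazard_curve", class(out))
  attr(out, "fits") <- fits
  attr(out, "method") <- method
  out
}

#' Impute the major osteoporotic fracture hazard from the hip hazard
#'
#' Scales the hip hazard by age- and sex-specific ratios of other major
#' osteoporotic fractures (clinical spine, forearm, humerus) to hip fracture:
#' `mof(age) = hip(age) * (1 + r(age, sex))`. This is the standard
#' construction for countries without direct MOF incidence, borrowing the
#' ratio pattern from a reference population. Overlap between fracture types
#' in one person is not modelled. Ratio bands are held constant within band
#' and the last band extends to the end of the age grid.
#'
#' @param hip A `hazard_curve` of kind `"hip"`.
#' @param ratios Ratio table: `sex`, `age_band`, `ratio` (other-MOF : hip,
#'   dimensionless, >= 0).
#' @return A `hazard_curve` of kind `"mof"` on the same age grid.
#' @export
mof_from_hip <- function(hip, ratios) {
  ratios <- tibble::as_tibble(ratios)
  if (any(ratios$ratio < 0)) abort("MOF:hip ratios must be >= 0")
  out <- tibble::as_tibble(hip) |>
    dplyr::group_by(.data$sex) |>
    dplyr::group_modify(function(d, key) {
      r <- ratios[ratios$sex == key$sex, , drop = FALSE]
      if (nrow(r) == 0) {
        abort(sprintf("ratio table has no rows for sex %s", key$sex))
      }
      band <- match_band(d$age, r$age_band)
      rr <- r$ratio[match(band, as.character(r$age_band))]
      dplyr::mutate(d, kind = "mof", hazard = .data$hazard * (1 + rr))
    }) |>
    dplyr::ungroup() |>
    dplyr::select("sex", "kind", "age", "hazard")
  class(out) <- c("hazard_curve", class(out))
  out
}

#' Per-age death hazard from a life table
#'
#' Converts annual death probabilities to central rates via
#' `m = -log(1 - q)` (central rates `m`, when supplied, are used directly),
#' expands abridged age bands by holding the rate constant within band, and
#' extends the table to the terminal age by log-linear (Gompertz)
#' extrapolation from the last two bands — mortality beyond the oldest
#' tabulated ages is assumed to keep growing at the same exponential rate.
#'
#' @param lt Life table: `sex`, either `age` (single years) or `age_band`,
#'   and either `q` (annual death probability, < 1) or `m` (central rate).
#' @param sex Optional: restrict to one sex.
#' @param terminal_age Last age of the output grid (default 105).
#' @return A `hazard_curve` of kind `"death"` on ages 40 to `terminal_age`.
#' @export
mortality_hazard <- function(lt, sex = NULL, terminal_age = 105) {
  lt <- tibble::as_tibble(lt)
  if (!is.null(sex)) lt <- lt[lt$sex %in% sex, , drop = FALSE]
  has_q <- "q" %in% names(lt)
  has_m <- "m" %in% names(lt)
  if (!has_q && !has_m) abort("life table needs a `q` or `m` column")
  out <- purrr::map(split(lt, lt$sex), function(d) {
    if (has_m) {
      m <- d$m
    } else {
      if (any(d$q >= 1)) abort("q = 1 implies an infinite death hazard")
      if (any(d$q < 0)) abort("death probabilities must be >= 0")
      m <- -log(1 - d$q)
    }
    if ("age" %in% names(d)) {
      pt_age <- d$age
      cover_min <- min(d$age)
      cover_max <- max(d$age)
    } else if ("age_band" %in% names(d)) {
      pt_age <- band_midpoint(d$age_band, open_band_midpoint = NA)
      # open terminal band: place its value at its lower edge + 2.5
      open <- is.na(pt_age)
      pt_age[open] <- band_lower(d$age_band[open]) + 2.5
      cover_min <- min(band_lower(d$age_band))
      cover_max <- max(ifelse(is.finite(band_upper(d$age_band)),
                              band_upper(d$age_band) - 1,
                              band_lower(d$age_band)))
    } else {
      abort("life table needs an `age` or `age_band` column")
    }
    if (cover_min > 40 || cover_max < 85) {
      abort("life table must cover ages 40 to at least 85")
    }
    ord <- order(pt_age)
    pt_age <- pt_age[ord]
    m <- m[ord]

    ages <- 40:terminal_age
    idx <- findInterval(ages, pt_age)
    idx[idx == 0] <- 1
    h <- m[idx]

    beyond <- ages > cover_max
    if (any(beyond)) {
      k <- length(m)
      if (k >= 2 && m[k] > 0 && m[k - 1] > 0 &&
          pt_age[k] > pt_age[k - 1]) {
        slope <- (log(m[k]) - log(m[k - 1])) / (pt_age[k] - pt_age[k - 1])
        h[beyond] <- m[k] * exp(slope * (ages[beyond] - pt_age[k]))
      } else {
        h[beyond] <- m[k]
      }
    }
    tibble::tibble(sex = d$sex[1], kind = "death", age = ages, hazard = h)
  }) |>
    dplyr::bind_rows()
  class(out) <- c("hazard_curve", class(out))
  out
}
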