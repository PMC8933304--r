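#' Pair a fracture hazard with its competing death hazard
#'
#' Joins a fracture hazard curve (hip or MOF) and a death hazard curve for
#' one sex onto a common single-year age grid. Both hazards are treated as
#' piecewise constant over one-year age intervals.
#'
#' @param fracture,death `hazard_curve` tibbles (single sex each), or any
#'   data frames with `age` and `hazard`.
#' @return Tibble (class `competing_hazards`) with columns `age`, `h_f`,
#'   `h_d`.
#' @export
competing_hazards <- function(fracture, death) {
  f <- tibble::as_tibble(fracture)
  d <- tibble::as_tibble(death)
  n_sex <- function(x) {
    if ("sex" %in% names(x)) length(unique(x$sex)) else 1L
  }
  if (n_sex(f) > 1 || n_sex(d) > 1) {
    abort("supply one sex at a time to competing_hazards()")
  }
  out <- dplyr::inner_join(
    dplyr::select(f, "age", h_f = "hazard"),
    dplyr::select(d, "age", h_d = "hazard"),
    by = "age"
  ) |>
    dplyr::arrange(.data$age)
  if (any(out$h_f < 0) || any(out$h_d < 0)) abort("hazards must be >= 0")
  class(out) <- c("competing_hazards", class(out))
  out
}

# closed-form per-interval pieces shared by the probability functions:
# over interval k with constant hazards, the chance of reaching it event-free
# is S_k and the chance of a first fracture inside it is
# S_k * h_f/(h_f+h_d) * (1 - exp(-(h_f+h_d)))
interval_contributions <- function(ch, age, horizon) {
  need <- age + seq_len(horizon) - 1
  rows <- match(need, ch$age)
  if (anyNA(rows)) {
    abort(sprintf(
      "hazard grid does not cover ages %d-%d (missing %d)",
      age, age + horizon - 1, need[which(is.na(rows))[1]]
    ))
  }
  h_f <- ch$h_f[rows]
  h_d <- ch$h_d[rows]
  h <- h_f + h_d
  surv_start <- cumprod(c(1, exp(-h[-length(h)])))
  contrib <- ifelse(h == 0, 0,
                    surv_start * h_f / h * (1 - exp(-h)))
  tibble::tibble(age = need, h_f = h_f, h_d = h_d,
                 surv_start = surv_start, contribution = contrib)
}

#' Fracture probability over a fixed horizon under competing mortality
#'
#' Probability of a first fracture before death within `horizon` years from
#' `age`, with both hazards piecewise constant on one-year intervals and
#' integrated in closed form — no step-size error. Interval k contributes
#' `S_k * h_f/(h_f + h_d) * (1 - exp(-(h_f + h_d)))`, where `S_k` is the
#' probability of surviving all earlier intervals free of both events.
#'
#' @param ch A [competing_hazards()] table covering `[age, age + horizon)`.
#' @param age Starting age in whole years.
#' @param horizon Horizon in whole years (> 0).
#' @return One-row tibble (class `probability_result`): `start_age`,
#'   `horizon`, `probability`; the per-interval contributions are attached
#'   as `attr(, "contributions")`.
#' @export
#' @examples
#' ch <- tibble::tibble(age = 50:59, h_f = 0.01, h_d = 0.02)
#' horizon_probability(ch, 50, 10) # (1/3) * (1 - exp(-0.3)) = 0.0864
horizon_probability <- function(ch, age, horizon) {
  stopifnot(horizon > 0)
  pieces <- interval_contributions(ch, age, horizon)
  out <- tibble::tibble(
    start_age = age, horizon = horizon,
    probability = sum(pieces$contribution)
  )
  attr(out, "contributions") <- pieces
  class(out) <- c("probability_result", class(out))
  out
}

#' Remaining lifetime fracture probability
#'
#' Fracture probability from `age` to the terminal age of the model's closed
#' table (default 105), under competing mortality — the "lifetime risk" of
#' the fracture-epidemiology literature.
#'
#' @param ch A [competing_hazards()] table covering `[age, terminal_age)`.
#' @param age Starting age in whole years.
#' @param terminal_age End of the hazard table (default 105).
#' @return One-row `probability_result` tibble; `horizon` is
#'   `terminal_age - age`.
#' @export
lifetime_probability <- function(ch, age, terminal_age = 105) {
  stopifnot(terminal_age > age)
  horizon_probability(ch, age, terminal_age - age)
}

#' Fracture probability across starting ages
#'
#' Maps [horizon_probability()] over a vector of starting ages — the curve
#' conventionally plotted for 10-year probabilities at ages 50 to 90. Under
#' a fracture hazard rising with age and a death hazard rising faster, the
#' curve rises to a turning age and plateaus or declines beyond it: the
#' competing-mortality signature.
#'
#' @param ch A [competing_hazards()] table covering every requested window.
#' @param ages Starting ages (default `seq(50, 90, by = 5)`).
#' @param horizon Horizon in years (default 10).
#' @return Tibble (class `probability_curve_table`): `start_age`, `horizon`,
#'   `probability`, `percent`.
#' @export
probability_curve <- function(ch, ages = seq(50, 90, by = 5), horizon = 10) {
  out <- purrr::map_dfr(ages, function(a) {
    tibble::as_tibble(horizon_probability(ch, a, horizon))
  }) |>
    dplyr::mutate(percent = 100 * .data$probability)
  class(out) <- c("probability_curve_table", class(out))
  out
}

#' Fracture vs death vs event-free decomposition
#'
#' Splits the horizon into the three exhaustive outcomes: first fracture,
#' death before fracture (same closed form with the hazard roles swapped),
#' and surviving the horizon free of both. The three sum to one exactly.
#'
#' @inheritParams horizon_probability
#' @return One-row tibble: `p_fracture`, `p_death_first`, `p_event_free`.
#' @export
competing_decomposition <- function(ch, age, horizon) {
  pieces <- interval_contributions(ch, age, horizon)
  h <- pieces$h_f + pieces$h_d
  p_death <- sum(ifelse(h == 0, 0,
                        pieces$surv_start * pieces$h_d / h * (1 - exp(-h))))
  tibble::tibble(
    p_fracture = sum(pieces$contribution),
    p_death_first = p_death,
    p_event_free = prod(exp(-h))
  )
}

#' Monte-Carlo check of the analytic fracture probability
#'
#' Simulates subjects one-year interval by interval: in each interval a
#' competing exponential event time is drawn at the combined hazard, and an
#' event occurring within the year is a fracture with probability
#' `h_f / (h_f + h_d)`. Returns the fracture fraction with its binomial
#' standard error. This discrete-event simulation is deliberately independent
#' of the closed-form integrator and serves to validate it.
#'
#' @inheritParams horizon_probability
#' @param n_subjects Number of simulated subjects (>= 1).
#' @param seed Seed for the simulation stream.
#' @return One-row tibble: `estimate`, `se`, `n_subjects`.
#' @export
monte_carlo_probability <- function(ch, age, horizon, n_subjects = 1e5,
                                    seed = 1L) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  pieces <- interval_contributions(ch, age, horizon)
  active <- rep(TRUE, n_subjects)
  fractured <- 0L
  for (k in seq_len(nrow(pieces))) {
    n_act <- sum(active)
    if (n_act == 0) break
    h <- pieces$h_f[k] + pieces$h_d[k]
    if (h == 0) next
    t_event <- rexp(n_act, rate = h)
    event <- t_event < 1
    is_frac <- event & (runif(n_act) < pieces$h_f[k] / h)
    fractured <- fractured + sum(is_frac)
    idx <- which(active)
    active[idx[event]] <- FALSE
  }
  p <- fractured / n_subjects
  tibble::tibble(
    estimate = p, se = sqrt(p * (1 - p) / n_subjects),
    n_subjects = n_subjects
  )
}
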