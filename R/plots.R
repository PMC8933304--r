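#' Plot an incidence table
#'
#' Age-specific rates with their exact Poisson intervals on a log scale,
#' faceted by sex — the conventional registry-incidence display.
#'
#' @param object An `incidence_table` from [estimate_rates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.incidence_table <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(mid = band_midpoint(.data$age_band))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = pmax(.data$rate, 0.1))) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$ci_low, 0.1), ymax = .data$ci_high
    )) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex)) +
    ggplot2::labs(
      x = "Age (years)", y = "Rate per 100,000 person-years",
      title = "Hip fracture incidence by age"
    )
}

#' Plot hazard curves
#'
#' Annual hazards against age, coloured by kind (hip, MOF, death) and
#' faceted by sex.
#'
#' @param object A `hazard_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hazard_curve <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$age, y = .data$hazard, colour = .data$kind)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex)) +
    ggplot2::labs(
      x = "Age (years)", y = "Annual hazard (events / person-year)",
      colour = NULL
    )
}

#' Plot fracture probability curves
#'
#' 10-year (or other fixed-horizon) fracture probability against starting
#' age; under competing mortality the curve typically rises to a turning
#' age and plateaus or declines beyond it.
#'
#' @param object A `probability_curve_table` from [probability_curve()] or
#'   [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.probability_curve_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data$start_age, y = .data$percent)
  )
  p <- if ("outcome" %in% names(d)) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$outcome))
  } else {
    p + ggplot2::geom_line()
  }
  if ("sex" %in% names(d)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$sex))
  }
  p + ggplot2::labs(
    x = "Age (years)",
    y = sprintf("%d-year fracture probability (%%)",
                unique(d$horizon)[1]),
    colour = NULL
  )
}
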