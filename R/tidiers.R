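#' Tidy the Poisson smoothing fits behind a hazard curve
#'
#' Returns the coefficient table of the underlying log-link Poisson
#' regression(s), one block per sex, in broom's column convention.
#'
#' @param x A `hazard_curve` produced by [smooth_incidence()].
#' @param ... Unused.
#' @return Tibble: `sex`, `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.hazard_curve <- function(x, ...) {
  fits <- attr(x, "fits")
  if (is.null(fits) || length(fits) == 0) {
    abort("no model fits attached: tidy() applies to smooth_incidence() output")
  }
  purrr::imap_dfr(fits, function(fit, sex) {
    co <- summary(fit)$coefficients
    tibble::tibble(
      sex = sex, term = rownames(co),
      estimate = co[, "Estimate"], std.error = co[, "Std. Error"],
      statistic = co[, "z value"], p.value = co[, "Pr(>|z|)"]
    )
  })
}

#' One-row fit summaries of the hazard smoothing models
#'
#' @param x A `hazard_curve` produced by [smooth_incidence()].
#' @param ... Unused.
#' @return Tibble: `sex`, `null.deviance`, `df.null`, `deviance`,
#'   `df.residual`, `AIC`, `nobs`.
#' @export
glance.hazard_curve <- function(x, ...) {
  fits <- attr(x, "fits")
  if (is.null(fits) || length(fits) == 0) {
    abort("no model fits attached: glance() applies to smooth_incidence() output")
  }
  purrr::imap_dfr(fits, function(fit, sex) {
    tibble::tibble(
      sex = sex,
      null.deviance = fit$null.deviance, df.null = fit$df.null,
      deviance = fit$deviance, df.residual = fit$df.residual,
      AIC = fit$aic, nobs = length(fit$y)
    )
  })
}
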