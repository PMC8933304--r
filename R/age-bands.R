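#' Five-year age bands used throughout the pipeline
#'
#' The fracture analysis uses half-open five-year bands from age 40 upwards,
#' with a single open terminal band: `"40-44"`, `"45-49"`, ..., `"75-79"`,
#' `"80+"`. Ages are completed years at the admission date.
#'
#' @return Character vector of band labels, in age order.
#' @export
#' @examples
#' age_band_labels()
age_band_labels <- function() {
  lo <- seq(40, 75, by = 5)
  c(sprintf("%d-%d", lo, lo + 4), "80+")
}

#' Assign an age in completed years to its five-year band
#'
#' @param age Numeric vector of ages in completed years. Ages below 40 return
#'   `NA` (they fall outside the analysis).
#' @return Factor with levels [age_band_labels()].
#' @export
#' @examples
#' assign_age_band(c(40, 44, 45, 79, 80, 97))
assign_age_band <- function(age) {
  cut(age,
    breaks = c(seq(40, 80, by = 5), Inf),
    labels = age_band_labels(), right = FALSE
  )
}

#' Band midpoints for hazard evaluation
#'
#' Closed bands use their arithmetic midpoint (e.g. 42.5 for 40-44 under the
#' half-open [40, 45) convention); the open `"80+"` band is assigned a
#' conventional midpoint.
#'
#' @param band Character or factor vector of band labels.
#' @param open_band_midpoint Midpoint assigned to the open terminal band
#'   (default 85 years).
#' @return Numeric vector of midpoints in years.
#' @export
band_midpoint <- function(band, open_band_midpoint = 85) {
  band <- as.character(band)
  lo <- band_lower(band)
  ifelse(grepl("\\+$", band), open_band_midpoint, lo + 2.5)
}

# lower edge of a band label ("40-44" -> 40, "80+" -> 80)
band_lower <- function(band) {
  as.numeric(sub("[-+].*$|\\+$", "", as.character(band)))
}

# upper (exclusive) edge; Inf for open bands
band_upper <- function(band) {
  band <- as.character(band)
  up <- suppressWarnings(as.numeric(sub("^.*-", "", band))) + 1
  ifelse(grepl("\\+$", band), Inf, up)
}

# map single ages onto a set of band labels, extending the last band upward
match_band <- function(age, bands) {
  bands <- as.character(bands)
  lo <- band_lower(bands)
  ord <- order(lo)
  bands <- bands[ord]
  lo <- lo[ord]
  idx <- findInterval(age, lo)
  if (any(idx == 0)) {
    abort(sprintf(
      "age %s below the first band (%s)", min(age), bands[1]
    ))
  }
  bands[idx]
}
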