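# delta-notation arithmetic, calibration, and the analytical-noise model.

#' Default analytical precision of nitrate isotope measurements
#'
#' One standard deviation, in per mil, of a single delta measurement by the
#' denitrifier method as run on this instrument line: 0.59 permil for
#' delta-18O and 0.19 permil for delta-15N. Used as the default `sd_permil`
#' wherever a measurement does not carry its own.
#'
#' @param element `"O18"` or `"N15"`.
#' @return Numeric scalar, permil.
#' @export
#' @examples
#' analytical_precision("O18")
analytical_precision <- function(element = c("O18", "N15")) {
  element <- match.arg(element)
  c(O18 = 0.59, N15 = 0.19)[[element]]
}

#' Convert an isotope ratio to delta notation
#'
#' delta = (R_sample / R_standard - 1) * 1000, in permil relative to the
#' standard (VSMOW for 18O/16O, atmospheric N2 for 15N/14N). The reference
#' ratio is an argument, never hard-coded: the pipeline works in delta space.
#'
#' @param r_sample,r_standard Positive isotope ratios (e.g. 18O/16O).
#' @return delta value(s) in permil.
#' @seealso [ratio_from_delta()] for the inverse.
#' @export
#' @examples
#' delta_from_ratio(0.0020100, 0.0020052)
delta_from_ratio <- function(r_sample, r_standard) {
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)) ||
      any(r_sample <= 0) || any(r_standard <= 0)) {
    stop("isotope ratios must be positive and finite", call. = FALSE)
  }
  (r_sample / r_standard - 1) * 1000
}

#' Convert a delta value back to an isotope ratio
#'
#' @param delta delta value(s) in permil; must exceed -1000 (ratios are
#'   positive).
#' @param r_standard Positive reference ratio.
#' @return Ratio(s), `r_standard * (1 + delta / 1000)`.
#' @export
ratio_from_delta <- function(delta, r_standard) {
  if (any(!is.finite(delta)) || any(delta <= -1000)) {
    stop("delta must be finite and > -1000 permil", call. = FALSE)
  }
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop("r_standard must be positive and finite", call. = FALSE)
  }
  r_standard * (1 + delta / 1000)
}

#' Construct a table of isotope measurements
#'
#' A light constructor for the tidy measurement representation used across
#' the package: one row per delta value, with the element, reference scale,
#' and per-measurement analytical SD. Missing SDs default to
#' [analytical_precision()] for the element.
#'
#' @param delta_permil Numeric vector of delta values (permil), each > -1000.
#' @param element `"O18"` or `"N15"` (recycled).
#' @param sd_permil Analytical SD(s), permil; `NA` entries are filled with the
#'   default precision for the element.
#' @param analyte Analyte name; only nitrate is used here.
#' @return A tibble with columns `analyte`, `element`, `delta_permil`,
#'   `reference`, `sd_permil`.
#' @export
#' @examples
#' isotope_measurement(c(74.1, 49.8), "O18")
isotope_measurement <- function(delta_permil, element = c("O18", "N15"),
                                sd_permil = NA_real_, analyte = "nitrate") {
  element <- match.arg(element)
  if (any(!is.finite(delta_permil)) || any(delta_permil <= -1000)) {
    stop("delta_permil must be finite and > -1000", call. = FALSE)
  }
  sd_permil <- rep_len(as.numeric(sd_permil), length(delta_permil))
  sd_permil[is.na(sd_permil)] <- analytical_precision(element)
  if (any(sd_permil < 0)) stop("sd_permil must be nonnegative", call. = FALSE)
  reference <- if (element == "O18") "VSMOW" else "AIR_N2"
  tibble::tibble(
    analyte = analyte,
    element = element,
    delta_permil = as.numeric(delta_permil),
    reference = reference,
    sd_permil = sd_permil
  )
}

#' Fit a calibration line from internal standards
#'
#' Ordinary least-squares line of assigned delta on measured delta, the usual
#' correction applied to denitrifier-method runs against internal standards
#' (e.g. IAEA-N3, USGS32, USGS34, USGS35). With unbiased standards the fit
#' reduces to the identity.
#'
#' @param assigned,measured Numeric vectors (permil) of equal length >= 2:
#'   certified and measured delta values of the standards.
#' @param element Element the curve applies to (`"O18"` or `"N15"`).
#' @param names Optional standard names, stored for provenance.
#' @return An object of class `calibration_curve` with fields `slope`,
#'   `intercept`, `element`, `standards`.
#' @export
#' @examples
#' cc <- fit_calibration(assigned = c(4.7, 25.6), measured = c(5.0, 26.1))
#' calibrate(5.0, cc)
fit_calibration <- function(assigned, measured, element = c("O18", "N15"),
                            names = NULL) {
  element <- match.arg(element)
  if (length(assigned) != length(measured) || length(assigned) < 2) {
    stop("calibration needs >= 2 standards with assigned and measured values",
         call. = FALSE)
  }
  fit <- stats::lm(assigned ~ measured)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive; check the standards", call. = FALSE)
  }
  calibration_curve(slope, intercept, element,
                    standards = tibble::tibble(
                      name = names %||% paste0("std", seq_along(assigned)),
                      assigned = assigned, measured = measured))
}

#' @rdname fit_calibration
#' @param slope,intercept Line coefficients (`corrected = slope * measured +
#'   intercept`).
#' @param standards Optional tibble of the standards behind the fit.
#' @export
calibration_curve <- function(slope, intercept, element = c("O18", "N15"),
                              standards = NULL) {
  element <- match.arg(element)
  if (!is.finite(slope) || slope <= 0) stop("slope must be > 0", call. = FALSE)
  structure(list(slope = slope, intercept = intercept, element = element,
                 standards = standards),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration curve (%s): corrected = %.4f * measured %+.4f permil\n",
              x$element, x$slope, x$intercept))
  if (!is.null(x$standards)) {
    cat(sprintf("  fitted from %d standards\n", nrow(x$standards)))
  }
  invisible(x)
}

#' Apply a calibration curve to measured delta values
#'
#' @param x Either a numeric vector of measured delta values, or a
#'   measurement tibble (as from [isotope_measurement()] or
#'   [read_isotope_csv()]) whose `element` column must match the curve's.
#' @param curve A `calibration_curve`.
#' @return The same shape as `x`, with delta values corrected; ordering and
#'   count are preserved.
#' @export
calibrate <- function(x, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (is.data.frame(x)) {
    if (!all(x$element == curve$element)) {
      stop("element mismatch between measurements and calibration curve",
           call. = FALSE)
    }
    x$delta_permil <- curve$slope * x$delta_permil + curve$intercept
    x
  } else if (is.numeric(x)) {
    curve$slope * x + curve$intercept
  } else {
    stop("x must be numeric or a measurement data frame", call. = FALSE)
  }
}

#' Simulate replicate measurements of a fixed true delta value
#'
#' The package's analytical-noise model: additive Gaussian noise in delta
#' space with the instrument SD. Used by the simulator and available directly
#' for noise studies.
#'
#' @param n Number of replicate measurements.
#' @param true_delta True delta value, permil.
#' @param sd_permil Analytical SD, permil.
#' @return Numeric vector of `n` simulated delta values.
#' @export
rdelta <- function(n, true_delta, sd_permil = analytical_precision("O18")) {
  if (sd_permil < 0) stop("sd_permil must be nonnegative", call. = FALSE)
  stats::rnorm(n, mean = true_delta, sd = sd_permil)
}

#' Read a tidy isotope measurement table
#'
#' Expected columns: `sample_id`, `source`, `treatment`, `week`, `element`,
#' `delta_permil`, and optionally `sd_permil`. Missing or `NA` SDs are filled
#' with the default analytical precision for the element.
#'
#' @param path CSV file path.
#' @return Validated tibble.
#' @export
read_isotope_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("sample_id", "source", "treatment", "week", "element",
                "delta_permil")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("isotope table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !df$element %in% c("O18", "N15")
  if (any(bad)) {
    stop("unknown element in rows: ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$delta_permil <= -1000, na.rm = TRUE)) {
    stop("delta_permil must be > -1000", call. = FALSE)
  }
  if (!"sd_permil" %in% names(df)) df$sd_permil <- NA_real_
  fill <- is.na(df$sd_permil)
  df$sd_permil[fill] <- vapply(df$element[fill], analytical_precision,
                               numeric(1))
  tibble::as_tibble(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
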