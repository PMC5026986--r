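# Two-end-member mixing of nitrate oxygen isotopes: endmember prediction,
# mass-balance fractions, and the attribution summary.

#' Predict the delta-18O endmember of freshly nitrified nitrate
#'
#' During microbial nitrification about two thirds of the oxygen atoms of the
#' product nitrate come from ambient water and one third from dissolved O2.
#' Given a plausible range for water delta-18O and a value for dissolved O2
#' (atmospheric O2 is +23.5 permil), the endmember of newly produced nitrate
#' is the corresponding mixture, evaluated at both water bounds:
#'
#'   endmember = water_fraction * water + (1 - water_fraction) * o2
#'
#' With the defaults (water in \[-10, -5\] permil, O2 at +23.5, fraction 2/3)
#' this gives \[+1.2, +4.5\] permil at reporting precision.
#'
#' @param water_low,water_high Bounds of ambient-water delta-18O, permil
#'   (VSMOW). Equal values give a degenerate (point) endmember.
#' @param o2 delta-18O of dissolved O2, permil.
#' @param water_fraction Fraction of nitrate O atoms derived from water,
#'   in \[0, 1\]; default 2/3.
#' @return An object of class `endmember_spec`: a list with the inputs plus
#'   `endmember_low` and `endmember_high` (permil).
#' @export
#' @examples
#' nitrification_endmember()
#' nitrification_endmember(-5, -5) # degenerate, +4.5
nitrification_endmember <- function(water_low = -10, water_high = -5,
                                    o2 = 23.5, water_fraction = 2 / 3) {
  if (!is.finite(water_low) || !is.finite(water_high) || water_low > water_high) {
    stop("water delta-18O range is inverted or not finite", call. = FALSE)
  }
  if (water_fraction < 0 || water_fraction > 1) {
    stop("water_fraction must lie in [0, 1]", call. = FALSE)
  }
  lo <- water_fraction * water_low + (1 - water_fraction) * o2
  hi <- water_fraction * water_high + (1 - water_fraction) * o2
  structure(list(water_delta18o_low = water_low,
                 water_delta18o_high = water_high,
                 o2_delta18o = o2,
                 water_fraction = water_fraction,
                 endmember_low = min(lo, hi),
                 endmember_high = max(lo, hi)),
            class = "endmember_spec")
}

#' @export
print.endmember_spec <- function(x, ...) {
  cat(sprintf(
    "nitrification endmember: delta-18O in [%+.1f, %+.1f] permil\n",
    x$endmember_low, x$endmember_high))
  cat(sprintf("  (water [%+.1f, %+.1f], O2 %+.1f, water fraction %.4f)\n",
              x$water_delta18o_low, x$water_delta18o_high, x$o2_delta18o,
              x$water_fraction))
  invisible(x)
}

# Coerce numeric shorthand to an endmember_spec: one value = point endmember,
# two values = [low, high] taken as already-mixed endmember bounds.
as_endmember <- function(x) {
  if (inherits(x, "endmember_spec")) return(x)
  if (is.numeric(x) && length(x) %in% c(1L, 2L) && all(is.finite(x))) {
    lo <- min(x); hi <- max(x)
    return(structure(list(water_delta18o_low = NA_real_,
                          water_delta18o_high = NA_real_,
                          o2_delta18o = NA_real_, water_fraction = NA_real_,
                          endmember_low = lo, endmember_high = hi),
                     class = "endmember_spec"))
  }
  stop("endmember must be an endmember_spec or 1-2 numeric values",
       call. = FALSE)
}

#' Fraction of the final nitrate pool that is newly produced
#'
#' Two-end-member mass balance on delta-18O: if a pool starts at
#' `delta_initial` and ends at `delta_final` after receiving new nitrate with
#' signature `delta_new`, the fraction of the final pool that is new is
#'
#'   f = (delta_initial - delta_final) / (delta_initial - delta_new)
#'
#' `delta_final` must lie between `delta_new` and `delta_initial`. Analytical
#' noise can push a measurement slightly past a bound: violations within
#' `clamp_sd * sd_permil` of a bound are clamped to the bound with a warning;
#' larger violations are an error (the data are then not a two-source
#' mixture).
#'
#' @param delta_initial,delta_final delta-18O of the pool before and after
#'   incubation, permil.
#' @param delta_new delta-18O of the newly produced nitrate (a point value;
#'   use both ends of an [nitrification_endmember()] interval to bracket).
#' @param sd_permil Analytical SD used for the clamping envelope.
#' @param clamp_sd Number of SDs of out-of-envelope slack tolerated.
#' @return The fraction f in \[0, 1\].
#' @export
#' @examples
#' mixing_fraction(74.1, 49.8, 1.2) # 1/3 of the final pool is new
mixing_fraction <- function(delta_initial, delta_final, delta_new,
                            sd_permil = analytical_precision("O18"),
                            clamp_sd = 2) {
  stopifnot(is.finite(delta_initial), is.finite(delta_final),
            is.finite(delta_new))
  if (delta_new == delta_initial) {
    stop("delta_new equals delta_initial: mixture is undefined", call. = FALSE)
  }
  lo <- min(delta_new, delta_initial)
  hi <- max(delta_new, delta_initial)
  slack <- clamp_sd * sd_permil
  if (delta_final < lo - slack || delta_final > hi + slack) {
    stop(sprintf(
      "delta_final (%.2f) lies outside the mixing envelope [%.2f, %.2f] by more than %g SD",
      delta_final, lo, hi, clamp_sd), call. = FALSE)
  }
  if (delta_final < lo || delta_final > hi) {
    clamped <- min(max(delta_final, lo), hi)
    warning(sprintf(
      "delta_final (%.2f) outside the mixing envelope [%.2f, %.2f]; clamped to %.2f (within %g SD)",
      delta_final, lo, hi, clamped, clamp_sd), call. = FALSE)
    delta_final <- clamped
  }
  (delta_initial - delta_final) / (delta_initial - delta_new)
}

#' Express the new fraction as a percentage of the original pool
#'
#' The headline quantity "new nitrate as a percentage of the original amount"
#' uses the original (surviving) pool as denominator: for a fraction `f` of
#' the final pool that is new, new:original = 100 * f / (1 - f) percent.
#'
#' @param frac_new_of_final Fraction in \[0, 1).
#' @return Percentage (nonnegative).
#' @seealso [frac_from_pct()] for the inverse.
#' @export
new_to_original_pct <- function(frac_new_of_final) {
  if (any(frac_new_of_final < 0) || any(frac_new_of_final >= 1)) {
    stop("frac_new_of_final must lie in [0, 1): the ratio diverges at 1",
         call. = FALSE)
  }
  100 * frac_new_of_final / (1 - frac_new_of_final)
}

#' @rdname new_to_original_pct
#' @param pct New:original percentage (nonnegative).
#' @export
frac_from_pct <- function(pct) {
  if (any(pct < 0)) stop("pct must be nonnegative", call. = FALSE)
  pct / (100 + pct)
}

#' Percentage increase of a concentration
#'
#' The concentration-based counterpart of the isotopic attribution: the
#' relative increase of the nitrate pool over incubation.
#'
#' @param c_initial,c_final Concentrations (uM); `c_initial` must be > 0.
#' @return Percent change, `100 * (c_final - c_initial) / c_initial`.
#' @export
#' @examples
#' concentration_increase_pct(219, 332)
concentration_increase_pct <- function(c_initial, c_final) {
  if (any(!is.finite(c_initial)) || any(c_initial <= 0)) {
    stop("c_initial must be positive", call. = FALSE)
  }
  100 * (c_final - c_initial) / c_initial
}

#' delta-15N implied for the newly produced nitrate
#'
#' Inverts the mixing mass balance on delta-15N: given the pool's initial and
#' final delta-15N and the new fraction `f` estimated from delta-18O, the new
#' nitrate's delta-15N must have been
#' `(delta_final - (1 - f) * delta_initial) / f`. A value below the initial
#' pool's (typically < 0 permil) is the signature expected when nitrate is
#' produced from ammonium, whose delta-15N in throughfall is generally
#' negative.
#'
#' @param delta_initial,delta_final delta-15N before and after, permil.
#' @param frac_new_of_final Fraction of the final pool that is new, in (0, 1].
#' @return Implied delta-15N of the new nitrate, permil.
#' @export
#' @examples
#' implied_new_delta15n(6.1, -1.7, 1 / 3)
implied_new_delta15n <- function(delta_initial, delta_final,
                                 frac_new_of_final) {
  if (any(frac_new_of_final <= 0) || any(frac_new_of_final > 1)) {
    stop("frac_new_of_final must lie in (0, 1]", call. = FALSE)
  }
  (delta_final - (1 - frac_new_of_final) * delta_initial) / frac_new_of_final
}

#' Delta-method SD of the new:original percentage
#'
#' Propagates independent analytical noise on `delta_initial` and
#' `delta_final` (each with SD `sd_permil`) through the mass balance to the
#' new:original percentage. Used as the default uncertainty band in
#' [recovery_study()].
#'
#' @inheritParams mixing_fraction
#' @return SD of the percentage, in percentage points.
#' @export
mixing_pct_sd <- function(delta_initial, delta_final, delta_new,
                          sd_permil = analytical_precision("O18")) {
  f <- (delta_initial - delta_final) / (delta_initial - delta_new)
  df_dfinal <- -1 / (delta_initial - delta_new)
  df_dinit <- (delta_final - delta_new) / (delta_initial - delta_new)^2
  sd_f <- sd_permil * sqrt(df_dfinal^2 + df_dinit^2)
  (100 / (1 - f)^2) * sd_f
}

#' Attribute nitrate production to nitrification by isotope mass balance
#'
#' Runs the two-end-member mass balance at both bounds of the endmember
#' interval, converts to new:original percentages, and (when concentrations
#' are supplied) cross-checks against the observed relative increase of the
#' nitrate pool. The attribution is called consistent when the
#' concentration-based percentage lies within the isotopic interval widened
#' by `tolerance_pp` percentage points on each side.
#'
#' @param delta_initial,delta_final delta-18O of nitrate before and after
#'   incubation, permil.
#' @param endmember An [nitrification_endmember()] object, or 1-2 numeric
#'   endmember values.
#' @param c_initial,c_final Optional nitrate concentrations (uM) for the
#'   cross-check.
#' @param tolerance_pp Consistency tolerance, percentage points (default 2,
#'   covering reporting rounding plus propagated analytical noise).
#' @param sd_permil Analytical SD for the mixing envelope clamp.
#' @return An object of class `mixing_result`: a list with the inputs, the
#'   fraction and percentage interval bounds (`frac_new_of_final_low/high`,
#'   `new_to_original_pct_low/high`), `conc_based_pct` (or `NA`), and
#'   `consistent` (logical, `NA` without concentrations).
#' @export
#' @examples
#' attribute_nitrification(74.1, 49.8, nitrification_endmember(),
#'                         c_initial = 219, c_final = 332)
attribute_nitrification <- function(delta_initial, delta_final, endmember,
                                    c_initial = NA_real_, c_final = NA_real_,
                                    tolerance_pp = 2,
                                    sd_permil = analytical_precision("O18")) {
  em <- as_endmember(endmember)
  f_at <- vapply(c(em$endmember_low, em$endmember_high), function(dn) {
    mixing_fraction(delta_initial, delta_final, dn, sd_permil = sd_permil)
  }, numeric(1))
  f_lo <- min(f_at); f_hi <- max(f_at)
  pct_lo <- new_to_original_pct(f_lo)
  pct_hi <- new_to_original_pct(f_hi)
  conc_pct <- if (is.finite(c_initial) && is.finite(c_final)) {
    concentration_increase_pct(c_initial, c_final)
  } else NA_real_
  consistent <- if (is.na(conc_pct)) NA else {
    conc_pct >= pct_lo - tolerance_pp && conc_pct <= pct_hi + tolerance_pp
  }
  structure(list(delta_initial = delta_initial, delta_final = delta_final,
                 endmember = em,
                 frac_new_of_final_low = f_lo, frac_new_of_final_high = f_hi,
                 new_to_original_pct_low = pct_lo,
                 new_to_original_pct_high = pct_hi,
                 conc_based_pct = conc_pct,
                 tolerance_pp = tolerance_pp,
                 consistent = consistent),
            class = "mixing_result")
}

#' @export
print.mixing_result <- function(x, ...) {
  cat(sprintf("nitrate delta-18O: %+.1f -> %+.1f permil\n",
              x$delta_initial, x$delta_final))
  cat(sprintf("endmember: [%+.1f, %+.1f] permil\n",
              x$endmember$endmember_low, x$endmember$endmember_high))
  cat(sprintf("new fraction of final pool: [%.3f, %.3f]\n",
              x$frac_new_of_final_low, x$frac_new_of_final_high))
  cat(sprintf("new:original nitrate: [%.1f, %.1f] %%\n",
              x$new_to_original_pct_low, x$new_to_original_pct_high))
  if (!is.na(x$conc_based_pct)) {
    cat(sprintf("concentration-based increase: %.1f %% -> %s (tolerance %.1f pp)\n",
                x$conc_based_pct,
                if (isTRUE(x$consistent)) "consistent" else "NOT consistent",
                x$tolerance_pp))
  }
  invisible(x)
}
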