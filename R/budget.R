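# Inorganic-N bookkeeping across incubation weeks and filter treatments.

# Canonical factor levels for the experimental design.
N_SOURCES <- c("tree", "rainfall")
N_TREATMENTS <- c("unfiltered", "f10um", "f2um", "f0_4um", "f0_2um")

#' Read and validate a tidy inorganic-N concentration table
#'
#' Expected columns: `sample_id`, `source` (`tree`/`rainfall`), `treatment`
#' (`unfiltered`, `f10um`, `f2um`, `f0_4um`, `f0_2um`), `week` (integer 0-4),
#' `nh4_uM`, `no2_uM`, `no3_uM`. Not-determined cells stay `NA` (flagged, not
#' imputed) — e.g. ammonium measured only at weeks 0, 1 and 4.
#'
#' @param x CSV path or data frame.
#' @return Validated tibble.
#' @export
read_profiles <- function(x) {
  df <- if (is.character(x)) readr::read_csv(x, show_col_types = FALSE) else x
  validate_profiles(df)
}

#' @rdname read_profiles
#' @param df Data frame of concentration profiles.
#' @export
validate_profiles <- function(df) {
  required <- c("sample_id", "source", "treatment", "week",
                "nh4_uM", "no2_uM", "no3_uM")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("profile table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  bad_source <- which(!df$source %in% N_SOURCES)
  if (length(bad_source) > 0) {
    problems <- c(problems, paste0("unknown source in rows ",
                                   paste(bad_source, collapse = ",")))
  }
  bad_trt <- which(!df$treatment %in% N_TREATMENTS)
  if (length(bad_trt) > 0) {
    problems <- c(problems, paste0("unknown treatment in rows ",
                                   paste(bad_trt, collapse = ",")))
  }
  bad_week <- which(!(df$week %in% 0:4))
  if (length(bad_week) > 0) {
    problems <- c(problems, paste0("week outside 0-4 in rows ",
                                   paste(bad_week, collapse = ",")))
  }
  for (col in c("nh4_uM", "no2_uM", "no3_uM")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0) {
      problems <- c(problems, paste0("negative ", col, " in rows ",
                                     paste(bad, collapse = ",")))
    }
  }
  key <- paste(df$source, df$treatment, df$week, sep = "|")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    problems <- c(problems, paste0("duplicate (source, treatment, week) in rows ",
                                   paste(dup, collapse = ",")))
  }
  if (length(problems) > 0) {
    stop("invalid profile table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Total mineral nitrogen of a sample
#'
#' Sum of ammonium, nitrite and nitrate (all uM). Nitrite is included: the
#' three inorganic species together make up the mineral-N pool. All three
#' species must be determined.
#'
#' @param nh4_uM,no2_uM,no3_uM Concentrations, uM (vectorized).
#' @return Mineral N, uM.
#' @export
#' @examples
#' mineral_nitrogen(174, 11, 219) # 404
mineral_nitrogen <- function(nh4_uM, no2_uM, no3_uM) {
  if (any(is.na(nh4_uM)) || any(is.na(no2_uM)) || any(is.na(no3_uM))) {
    stop("mineral N requires all three species to be determined", call. = FALSE)
  }
  if (any(nh4_uM < 0) || any(no2_uM < 0) || any(no3_uM < 0)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  nh4_uM + no2_uM + no3_uM
}

#' Classification thresholds for incubation budgets
#'
#' The observed incubation patterns are qualitative; these cutoffs turn them
#' into a three-way call. A treatment is `nitrifying` when the nitrate gain
#' is both absolutely (>= `no3_min_uM`) and relatively (>= `no3_min_frac` of
#' the initial nitrate pool) substantial; `nitrite_accumulating` when nitrite
#' builds up (>= `no2_min_uM`) without a nitrifying-scale nitrate gain (the
#' fingerprint of ammonia oxidizers present but nitrite oxidizers removed);
#' otherwise `inactive`.
#'
#' @param no3_min_uM Minimum nitrate increase, uM (default 20).
#' @param no3_min_frac Minimum nitrate increase relative to initial nitrate
#'   (default 0.1).
#' @param no2_min_uM Minimum nitrite increase, uM (default 5).
#' @return A named list of thresholds.
#' @export
budget_thresholds <- function(no3_min_uM = 20, no3_min_frac = 0.1,
                              no2_min_uM = 5) {
  stopifnot(no3_min_uM >= 0, no3_min_frac >= 0, no2_min_uM >= 0)
  list(no3_min_uM = no3_min_uM, no3_min_frac = no3_min_frac,
       no2_min_uM = no2_min_uM)
}

#' Classify one treatment's incubation outcome
#'
#' @param delta_no3,delta_no2 Final-minus-initial concentration changes, uM.
#' @param no3_initial Initial nitrate, uM.
#' @param thresholds From [budget_thresholds()].
#' @return One of `"nitrifying"`, `"nitrite_accumulating"`, `"inactive"`.
#' @export
classify_budget <- function(delta_no3, delta_no2, no3_initial,
                            thresholds = budget_thresholds()) {
  if (is.na(delta_no3)) return(NA_character_)
  nitrifying <- delta_no3 >= thresholds$no3_min_uM &&
    delta_no3 >= thresholds$no3_min_frac * no3_initial
  if (nitrifying) return("nitrifying")
  if (!is.na(delta_no2) && delta_no2 >= thresholds$no2_min_uM) {
    return("nitrite_accumulating")
  }
  "inactive"
}

#' Summarize inorganic-N changes per source and treatment
#'
#' For each (source, treatment) group, computes endpoint differences (week 0
#' to the latest week with data; ammonium uses the latest week at which it
#' was determined), oxidized-N production (`delta_no3 + delta_no2`), the
#' production in excess of ammonium consumption (positive excess indicates a
#' contribution from mineralized organic N), and the classification.
#'
#' @param profiles Validated profile tibble (see [read_profiles()]).
#' @param thresholds From [budget_thresholds()].
#' @param strict If `TRUE` (default), a group without post-incubation nitrate
#'   data is an error; if `FALSE` it yields an `NA` classification with a
#'   note (used by the pipeline).
#' @return Tibble, one row per (source, treatment): `week_final`,
#'   `delta_nh4`, `delta_no2`, `delta_no3`, `oxidized_n_produced`,
#'   `excess_over_nh4_consumption`, `classification`, `note`.
#' @export
summarize_budget <- function(profiles, thresholds = budget_thresholds(),
                             strict = TRUE) {
  profiles <- validate_profiles(profiles)
  groups <- unique(profiles[, c("source", "treatment")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- profiles[profiles$source == groups$source[i] &
                    profiles$treatment == groups$treatment[i], ]
    g <- g[order(g$week), ]
    base <- tibble::tibble(
      source = groups$source[i], treatment = groups$treatment[i],
      week_final = NA_integer_, delta_nh4 = NA_real_, delta_no2 = NA_real_,
      delta_no3 = NA_real_, oxidized_n_produced = NA_real_,
      excess_over_nh4_consumption = NA_real_,
      classification = NA_character_, note = NA_character_)
    w0 <- g[g$week == 0, ]
    later_no3 <- g[g$week > 0 & !is.na(g$no3_uM), ]
    if (nrow(w0) != 1 || nrow(later_no3) == 0) {
      msg <- sprintf("%s/%s: no week-0 profile or no post-incubation nitrate",
                     groups$source[i], groups$treatment[i])
      if (strict) stop(msg, call. = FALSE)
      base$note <- msg
      return(base)
    }
    wf <- max(later_no3$week)
    fin <- g[g$week == wf, ]
    base$week_final <- as.integer(wf)
    base$delta_no3 <- fin$no3_uM - w0$no3_uM
    if (!is.na(w0$no2_uM) && !is.na(fin$no2_uM)) {
      base$delta_no2 <- fin$no2_uM - w0$no2_uM
    }
    # ammonium: latest determined week, never blocked by NA weeks in between
    nh4_weeks <- g[!is.na(g$nh4_uM) & g$week > 0, ]
    if (!is.na(w0$nh4_uM) && nrow(nh4_weeks) > 0) {
      base$delta_nh4 <- nh4_weeks$nh4_uM[which.max(nh4_weeks$week)] - w0$nh4_uM
    }
    if (!is.na(base$delta_no2)) {
      base$oxidized_n_produced <- base$delta_no3 + base$delta_no2
    }
    if (!is.na(base$oxidized_n_produced) && !is.na(base$delta_nh4)) {
      base$excess_over_nh4_consumption <-
        base$oxidized_n_produced - max(0, -base$delta_nh4)
    }
    base$classification <- classify_budget(base$delta_no3, base$delta_no2,
                                           w0$no3_uM, thresholds)
    base
  })
  do.call(rbind, out)
}
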