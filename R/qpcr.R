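# qPCR amoA copy-number normalization with LOQ censoring, and the
# presence/absence detection matrix across filter fractions.

QPCR_TARGETS <- c("archaeal_amoA", "betaproteobacterial_amoA")
DETECTION_OUTCOMES <- c("detected", "not_detected", "not_tested")

#' Scale per-reaction copies to per-filter copies
#'
#' Each qPCR reaction receives a fraction of the DNA extracted from one
#' filter. With `reaction_fraction = 1` (the default) per-reaction values are
#' taken as already expressed per filter, which reproduces reported
#' per-filter totals without extra assumptions about extraction volumes.
#'
#' @param copies_per_reaction Mean copies per reaction (nonnegative).
#' @param reaction_fraction Fraction of the filter's extract loaded per
#'   reaction, in (0, 1].
#' @return Copies per filter.
#' @export
per_filter_abundance <- function(copies_per_reaction, reaction_fraction = 1) {
  if (any(reaction_fraction <= 0) || any(reaction_fraction > 1)) {
    stop("reaction_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (any(copies_per_reaction < 0, na.rm = TRUE)) {
    stop("copies_per_reaction must be nonnegative", call. = FALSE)
  }
  copies_per_reaction / reaction_fraction
}

#' Scale per-filter copies to copies per mL of filtered sample
#'
#' @param copies_per_filter Copies on the filter (nonnegative).
#' @param volume_mL Volume of sample passed through the filter, mL (> 0).
#' @return Copies per mL.
#' @export
#' @examples
#' per_ml_abundance(5424, 300) # 18.08, below the printed bound of 20
per_ml_abundance <- function(copies_per_filter, volume_mL) {
  if (any(volume_mL <= 0)) stop("volume_mL must be positive", call. = FALSE)
  if (any(copies_per_filter < 0, na.rm = TRUE)) {
    stop("copies_per_filter must be nonnegative", call. = FALSE)
  }
  copies_per_filter / volume_mL
}

#' Censoring decision against the limit of quantification
#'
#' A measurement below the LOQ is censored and must be reported as a bound,
#' never a point value. The boundary is inclusive: a mean exactly at the LOQ
#' is quantifiable (the LOQ is the smallest quantifiable value). An `NA` mean
#' (target detected but not quantified) is censored.
#'
#' @param mean_copies Mean copies per reaction.
#' @param loq Limit of quantification, copies per reaction (default 44).
#' @return Logical: `TRUE` if censored.
#' @export
#' @examples
#' apply_loq(30) # TRUE
#' apply_loq(44) # FALSE (boundary inclusive)
apply_loq <- function(mean_copies, loq = 44) {
  if (any(loq <= 0)) stop("loq must be positive", call. = FALSE)
  is.na(mean_copies) | mean_copies < loq
}

#' Normalize a table of qPCR results
#'
#' Computes per-filter and per-mL abundances with LOQ censoring. Censored
#' rows never carry numeric point abundances: their `copies_per_filter`,
#' `copies_per_mL` (and SDs) are `NA`, and the LOQ-equivalent upper bounds
#' are given in `copies_per_filter_upper` / `copies_per_mL_upper`. SDs scale
#' with the same factors as the means (pure rescaling; replicate-level data
#' are not modelled).
#'
#' @param df Data frame with columns `source`, `fraction`, `target`,
#'   `copies_per_reaction_mean`, and optionally `copies_per_reaction_sd`,
#'   `n_replicates`, `volume_filtered_mL`, `loq`, `reaction_fraction`.
#' @param default_loq LOQ used where the table has none (copies/reaction).
#' @return Tibble with abundance and censoring columns added.
#' @export
normalize_qpcr <- function(df, default_loq = 44) {
  required <- c("source", "fraction", "target", "copies_per_reaction_mean")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("qPCR table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$target %in% QPCR_TARGETS)
  if (length(bad) > 0) {
    stop("unknown qPCR target in rows ", paste(bad, collapse = ","),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  if (!"loq" %in% names(df)) df$loq <- default_loq
  df$loq[is.na(df$loq)] <- default_loq
  if (!"reaction_fraction" %in% names(df)) df$reaction_fraction <- 1
  if (!"copies_per_reaction_sd" %in% names(df)) {
    df$copies_per_reaction_sd <- NA_real_
  }
  if (!"volume_filtered_mL" %in% names(df)) df$volume_filtered_mL <- NA_real_

  df$censored <- apply_loq(df$copies_per_reaction_mean, df$loq)
  scale_filter <- 1 / df$reaction_fraction
  df$copies_per_filter <- ifelse(
    df$censored, NA_real_,
    per_filter_abundance(df$copies_per_reaction_mean, df$reaction_fraction))
  df$copies_per_filter_sd <- ifelse(
    df$censored, NA_real_, df$copies_per_reaction_sd * scale_filter)
  df$copies_per_filter_upper <- ifelse(df$censored, df$loq * scale_filter,
                                       NA_real_)
  has_vol <- !is.na(df$volume_filtered_mL) & df$volume_filtered_mL > 0
  df$copies_per_mL <- ifelse(
    !df$censored & has_vol,
    df$copies_per_filter / df$volume_filtered_mL, NA_real_)
  df$copies_per_mL_sd <- ifelse(
    !df$censored & has_vol,
    df$copies_per_filter_sd / df$volume_filtered_mL, NA_real_)
  df$copies_per_mL_upper <- ifelse(
    df$censored & has_vol,
    df$copies_per_filter_upper / df$volume_filtered_mL, NA_real_)
  df
}

#' Read a qPCR results table
#'
#' @param path CSV path; see [normalize_qpcr()] for the columns.
#' @param default_loq LOQ used where the table has none.
#' @return Normalized tibble.
#' @export
read_qpcr_csv <- function(path, default_loq = 44) {
  normalize_qpcr(readr::read_csv(path, show_col_types = FALSE),
                 default_loq = default_loq)
}

#' Assemble a presence/absence matrix of marker-gene detections
#'
#' @param records Data frame with columns `source`, `fraction`, `target`,
#'   `outcome` (each outcome one of `detected`, `not_detected`,
#'   `not_tested`). Conflicting duplicates for the same cell are an error;
#'   combinations never reported are filled as `not_tested`.
#' @return Tibble: one row per (source, fraction), one column per target,
#'   cells in the three explicit states.
#' @export
build_detection_matrix <- function(records) {
  required <- c("source", "fraction", "target", "outcome")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("detection table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) {
    return(tibble::tibble(source = character(0), fraction = character(0)))
  }
  bad <- which(!records$outcome %in% DETECTION_OUTCOMES)
  if (length(bad) > 0) {
    stop("unknown detection outcome in rows ", paste(bad, collapse = ","),
         call. = FALSE)
  }
  key <- paste(records$source, records$fraction, records$target, sep = "|")
  for (k in unique(key[duplicated(key)])) {
    vals <- unique(records$outcome[key == k])
    if (length(vals) > 1) {
      stop("conflicting detection outcomes for ", k, ": ",
           paste(vals, collapse = " vs "), call. = FALSE)
    }
  }
  records <- records[!duplicated(key), ]
  rows <- unique(records[, c("source", "fraction")])
  targets <- unique(records$target)
  out <- rows
  for (tg in targets) {
    col <- rep("not_tested", nrow(rows))
    sub <- records[records$target == tg, ]
    idx <- match(paste(rows$source, rows$fraction, sep = "|"),
                 paste(sub$source, sub$fraction, sep = "|"))
    col[!is.na(idx)] <- sub$outcome[idx[!is.na(idx)]]
    out[[tg]] <- col
  }
  tibble::as_tibble(out)
}
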