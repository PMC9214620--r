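as_day <- function(x) {
  d <- as.Date(x)
  if (anyNA(d)) stop("unparseable date(s): ",
                     paste(utils::head(x[is.na(d)], 3), collapse = ", "))
  d
}

#' Assign the multiple-birth outcome at the delivery date
#'
#' A delivery is coded MB = 1 iff the patient has a diagnosis from the MB
#' code list dated exactly on the delivery date (within `tolerance_days`,
#' default 0). MB codes assigned during pregnancy but not at delivery are
#' deliberately ignored: a multifetal pregnancy that does not end in a
#' multiple birth (e.g. vanishing twin) must not count.
#'
#' @param deliveries Data frame with `patient_id`, `delivery_id`,
#'   `delivery_date`.
#' @param diagnoses Data frame with `patient_id`, `code_system`, `code`,
#'   `date`.
#' @param mb_codes MB [code_list()]; default from [default_code_lists()].
#' @param tolerance_days Half-width in days of the "at delivery" match
#'   (default 0: same day).
#' @return Integer 0/1 vector along the rows of `deliveries`.
#' @export
assign_mb <- function(deliveries, diagnoses,
                      mb_codes = default_code_lists()$MB,
                      tolerance_days = 0L) {
  stopifnot(tolerance_days >= 0L)
  ddate <- as_day(deliveries$delivery_date)
  if (nrow(diagnoses) == 0L) return(integer(nrow(deliveries)))
  keep <- match_codes(diagnoses, mb_codes)
  dx <- diagnoses[keep, , drop = FALSE]
  if (nrow(dx) == 0L) return(integer(nrow(deliveries)))
  flag_in_window(deliveries$patient_id, ddate,
                 dx$patient_id, as_day(dx$date),
                 lo = -as.integer(tolerance_days),
                 hi = as.integer(tolerance_days))
}

#' Assign ART and infertility covariates from a diagnosis lookback
#'
#' A covariate is 1 iff a matching code for the patient is dated within
#' `lookback_days` before the delivery date, both endpoints inclusive:
#' `[delivery_date - lookback_days, delivery_date]`.
#'
#' @inheritParams assign_mb
#' @param art_codes,inf_codes ART and infertility [code_list()]s.
#' @param lookback_days Lookback window length in days (default 315).
#' @return Data frame with integer columns `art`, `infertility` along the
#'   rows of `deliveries`.
#' @export
assign_art_infertility <- function(deliveries, diagnoses,
                                   art_codes = default_code_lists()$ART,
                                   inf_codes = default_code_lists()$INFERTILITY,
                                   lookback_days = 315L) {
  stopifnot(lookback_days > 0L)
  ddate <- as_day(deliveries$delivery_date)
  one <- function(codes) {
    if (nrow(diagnoses) == 0L) return(integer(nrow(deliveries)))
    dx <- diagnoses[match_codes(diagnoses, codes), , drop = FALSE]
    if (nrow(dx) == 0L) return(integer(nrow(deliveries)))
    flag_in_window(deliveries$patient_id, ddate,
                   dx$patient_id, as_day(dx$date),
                   lo = -as.integer(lookback_days), hi = 0L)
  }
  data.frame(art = one(art_codes), infertility = one(inf_codes))
}

# 1 iff patient has an event dated in [anchor + lo, anchor + hi] days.
flag_in_window <- function(patient, anchor, ev_patient, ev_date, lo, hi) {
  out <- integer(length(patient))
  ev <- split(as.integer(ev_date), ev_patient)
  idx <- match(patient, names(ev))
  anc <- as.integer(anchor)
  for (i in which(!is.na(idx))) {
    d <- ev[[idx[i]]] - anc[i]
    if (any(d >= lo & d <= hi)) out[i] <- 1L
  }
  out
}

#' Build the analysis cohort
#'
#' Combines [assign_mb()] and [assign_art_infertility()] into one
#' delivery-level analysis table. The unit of analysis is the delivery; a
#' patient with several deliveries contributes one independent row each.
#'
#' @inheritParams assign_art_infertility
#' @param code_lists Named list with `MB`, `ART`, `INFERTILITY`
#'   [code_list()]s; default [default_code_lists()].
#' @param tolerance_days Passed to [assign_mb()].
#' @return Data frame with `delivery_id`, `patient_id`, `delivery_date`,
#'   `maternal_age`, `mb`, `art`, `infertility`.
#' @export
build_cohort <- function(deliveries, diagnoses,
                         code_lists = default_code_lists(),
                         tolerance_days = 0L, lookback_days = 315L) {
  stopifnot(!anyDuplicated(deliveries$delivery_id))
  cov <- assign_art_infertility(deliveries, diagnoses,
                                code_lists$ART, code_lists$INFERTILITY,
                                lookback_days)
  data.frame(
    delivery_id = as.character(deliveries$delivery_id),
    patient_id = as.character(deliveries$patient_id),
    delivery_date = as.character(as_day(deliveries$delivery_date)),
    maternal_age = as.numeric(deliveries$maternal_age),
    mb = assign_mb(deliveries, diagnoses, code_lists$MB, tolerance_days),
    art = cov$art,
    infertility = cov$infertility,
    stringsAsFactors = FALSE
  )
}

#' Summarize the cohort in four exposure strata
#'
#' Counts and percentages of MB, ART and infertility, and maternal-age
#' mean/SD, for four strata: all deliveries, deliveries with no medication
#' exposure, deliveries with any exposure, and deliveries with fertility-
#' medication exposure (the last is a subset of any-exposure). Percentages
#' are additionally reported rounded to 3 significant digits (`*_pct`),
#' matching typical cohort-table precision; full precision is kept in
#' `*_pct_raw`.
#'
#' @param cohort Analysis cohort from [build_cohort()].
#' @param exposure An `exposure_matrix` (see [window_exposure()]) aligned
#'   on `delivery_id`, or `NULL` for a cohort with no exposure data (the
#'   exposure strata are then empty).
#' @param fertility_ids Medication ids defining the fertility stratum.
#' @return Data frame with one row per stratum.
#' @export
summarize_cohort <- function(cohort, exposure = NULL,
                             fertility_ids = character(0)) {
  if (is.null(exposure)) {
    any_exp <- rep(FALSE, nrow(cohort))
    fert_exp <- rep(FALSE, nrow(cohort))
  } else {
    m <- exposure$m
    stopifnot(setequal(rownames(m), cohort$delivery_id))
    m <- m[match(cohort$delivery_id, rownames(m)), , drop = FALSE]
    any_exp <- rowSums(m) > 0
    fids <- intersect(fertility_ids, colnames(m))
    fert_exp <- rowSums(m[, fids, drop = FALSE]) > 0
  }
  strata <- list(
    all = rep(TRUE, nrow(cohort)),
    no_exposure = !any_exp,
    any_exposure = any_exp,
    fertility_exposure = fert_exp
  )
  one <- function(label, keep) {
    s <- cohort[keep, , drop = FALSE]
    n <- nrow(s)
    pct <- function(k) if (n == 0L) 0 else 100 * k / n
    data.frame(
      stratum = label, n = n,
      mb_n = sum(s$mb), mb_pct_raw = pct(sum(s$mb)),
      art_n = sum(s$art), art_pct_raw = pct(sum(s$art)),
      infertility_n = sum(s$infertility),
      infertility_pct_raw = pct(sum(s$infertility)),
      age_mean = if (n) mean(s$maternal_age) else NA_real_,
      age_sd = if (n > 1L) stats::sd(s$maternal_age) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, Map(one, names(strata), strata))
  rownames(out) <- NULL
  for (v in c("mb", "art", "infertility")) {
    out[[paste0(v, "_pct")]] <- signif(out[[paste0(v, "_pct_raw")]], 3)
  }
  out
}
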