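#' Configuration for the synthetic EHR cohort generator
#'
#' Builds and validates the stated world for [generate_cohort()]. Defaults
#' emulate a large US delivery cohort: 63,334 deliveries with a 2.47%
#' multiple-birth (MB) rate, 2.96% of deliveries exposed to any of 123
#' medications in the preconception window, ART-resulting-pregnancy
#' diagnoses at 0.39%, infertility diagnoses at 0.08%, and maternal age
#' 29.5 (SD 6.1) years truncated to \[12, 55\].
#'
#' The outcome follows the logistic model
#' `logit P(MB) = baseline + beta_age*age + beta_art*ART +
#' beta_infertility*INF + sum_m beta_m*exposure_m`.
#' When `baseline_mb_logit` is `NULL` it is calibrated numerically so the
#' marginal MB rate equals `mb_target` under the configured age
#' distribution, covariate prevalences and planted effects.
#'
#' @param n_deliveries Number of deliveries (>= 1).
#' @param n_medications Number of medications.
#' @param annotations Medication annotation table; must cover
#'   `n_medications` ids ([default_annotations()]).
#' @param gold_ids Medication ids treated as fertility medications; default
#'   the annotation's `fertility_flag == 1` set.
#' @param exposure_prevalence Per-medication exposure probability in (0,1);
#'   scalar or named vector by medication id. Default solves
#'   `1 - (1-p)^n_medications = 0.0296` so that any-exposure prevalence
#'   matches 2.96% under independent draws.
#' @param baseline_mb_logit Intercept of the outcome model, or `NULL` to
#'   calibrate to `mb_target`.
#' @param mb_target Marginal MB rate used for calibration (default 0.0247).
#' @param beta_age Log-odds of MB per year of maternal age.
#' @param beta_art,beta_infertility Log-odds for the ART and infertility
#'   indicators.
#' @param beta_medication Named vector of planted per-medication log-odds;
#'   unspecified medications default to 0. Default plants `log(6)` on every
#'   gold medication.
#' @param art_prevalence,infertility_prevalence Diagnosis prevalences.
#' @param age_mean,age_sd Maternal age distribution (years); draws are
#'   truncated to \[12, 55\].
#' @param deliveries_per_patient Deliveries per patient (uniform 500-day
#'   spacing when > 1).
#' @param exposure_blocks Optional correlated-exposure hook: list of
#'   `list(ids = <medication ids>, rho = <share of a common draw>)` blocks;
#'   medications inside a block must share one prevalence.
#' @param decoy_fraction Fraction of eligible records receiving decoy codes
#'   or orders in [emit_decoys()].
#' @param seed Integer seed; identical configs give byte-identical cohorts.
#' @return A validated list of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_deliveries = 500, n_medications = 20, seed = 7)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort$deliveries)
simulation_config <- function(n_deliveries = 63334L,
                              n_medications = 123L,
                              annotations = default_annotations(n_medications),
                              gold_ids = gold_standard_ids(annotations),
                              exposure_prevalence = NULL,
                              baseline_mb_logit = NULL,
                              mb_target = 0.0247,
                              beta_age = log(1.05),
                              beta_art = log(8),
                              beta_infertility = log(3),
                              beta_medication = NULL,
                              art_prevalence = 0.0039,
                              infertility_prevalence = 0.0008,
                              age_mean = 29.5,
                              age_sd = 6.1,
                              deliveries_per_patient = 1L,
                              exposure_blocks = NULL,
                              decoy_fraction = 0.02,
                              seed = 1L) {
  n_deliveries <- as.integer(n_deliveries)
  n_medications <- as.integer(n_medications)
  if (is.na(n_deliveries) || n_deliveries < 1L) {
    stop("configuration error: n_deliveries must be >= 1")
  }
  if (is.na(n_medications) || n_medications < 1L) {
    stop("configuration error: n_medications must be >= 1")
  }
  med_ids <- unique(annotations$medication_id)
  if (length(med_ids) < n_medications) {
    stop("configuration error: annotation table covers ", length(med_ids),
         " medications but n_medications = ", n_medications)
  }
  med_ids <- med_ids[seq_len(n_medications)]
  if (!all(gold_ids %in% med_ids)) {
    stop("configuration error: gold ids outside the medication set: ",
         paste(setdiff(gold_ids, med_ids), collapse = ", "))
  }

  if (is.null(exposure_prevalence)) {
    exposure_prevalence <- 1 - (1 - 0.0296)^(1 / n_medications)
  }
  # allow exactly-zero prevalence as the documented degenerate case
  p <- rep_len(0, n_medications)
  names(p) <- med_ids
  if (is.null(names(exposure_prevalence))) {
    p[] <- rep_len(exposure_prevalence, n_medications)
  } else {
    unknown <- setdiff(names(exposure_prevalence), med_ids)
    if (length(unknown)) {
      stop("configuration error: exposure_prevalence names not in the ",
           "medication set: ", paste(unknown, collapse = ", "))
    }
    p[names(exposure_prevalence)] <- exposure_prevalence
  }
  check_prob <- function(x, what, open = TRUE) {
    bad <- if (open) any(x < 0 | x >= 1) else any(x <= 0 | x >= 1)
    if (any(is.na(x)) || bad) {
      stop("configuration error: ", what, " must be a probability in [0,1)")
    }
  }
  check_prob(p, "exposure_prevalence")
  check_prob(art_prevalence, "art_prevalence")
  check_prob(infertility_prevalence, "infertility_prevalence")
  if (!is.finite(age_mean) || !is.finite(age_sd) || age_sd <= 0) {
    stop("configuration error: invalid age distribution")
  }
  if (decoy_fraction < 0 || decoy_fraction > 1) {
    stop("configuration error: decoy_fraction must be in [0,1]")
  }

  beta <- rep_len(0, n_medications)
  names(beta) <- med_ids
  if (is.null(beta_medication)) {
    beta[gold_ids] <- log(6)
  } else {
    unknown <- setdiff(names(beta_medication), med_ids)
    if (length(unknown)) {
      stop("configuration error: beta_medication names not in the ",
           "medication set: ", paste(unknown, collapse = ", "))
    }
    beta[names(beta_medication)] <- beta_medication
  }

  if (!is.null(exposure_blocks)) {
    for (b in exposure_blocks) {
      stopifnot(all(b$ids %in% med_ids), b$rho >= 0, b$rho <= 1)
      if (length(unique(p[b$ids])) != 1L) {
        stop("configuration error: medications in a correlated block must ",
             "share one exposure prevalence")
      }
    }
  }

  cfg <- structure(list(
    n_deliveries = n_deliveries, n_medications = n_medications,
    medication_ids = med_ids, annotations = annotations,
    gold_ids = gold_ids, exposure_prevalence = p,
    baseline_mb_logit = baseline_mb_logit, mb_target = mb_target,
    beta_age = beta_age, beta_art = beta_art,
    beta_infertility = beta_infertility, beta_medication = beta,
    art_prevalence = art_prevalence,
    infertility_prevalence = infertility_prevalence,
    age_mean = age_mean, age_sd = age_sd,
    deliveries_per_patient = as.integer(deliveries_per_patient),
    exposure_blocks = exposure_blocks,
    decoy_fraction = decoy_fraction,
    seed = as.integer(seed)
  ), class = "simulation_config")
  if (is.null(cfg$baseline_mb_logit)) {
    cfg$baseline_mb_logit <- calibrate_baseline(cfg)
  }
  cfg
}

# Marginal MB rate implied by the config at intercept b0, by quadrature over
# the truncated-normal age distribution, the four ART x infertility cells,
# and (since per-medication prevalences are small) an at-most-one-exposure
# expansion of the planted medication effects.
marginal_mb_rate <- function(cfg, b0) {
  lo <- stats::pnorm(12, cfg$age_mean, cfg$age_sd)
  hi <- stats::pnorm(55, cfg$age_mean, cfg$age_sd)
  u <- seq(lo, hi, length.out = 401L)
  age <- stats::qnorm(u, cfg$age_mean, cfg$age_sd)
  pa <- cfg$art_prevalence
  pi_ <- cfg$infertility_prevalence
  cells <- rbind(c(0, 0, (1 - pa) * (1 - pi_)),
                 c(1, 0, pa * (1 - pi_)),
                 c(0, 1, (1 - pa) * pi_),
                 c(1, 1, pa * pi_))
  planted <- cfg$beta_medication[cfg$beta_medication != 0]
  p_exp <- cfg$exposure_prevalence[names(planted)]
  p_none <- max(0, 1 - sum(p_exp))
  rate <- 0
  for (k in seq_len(nrow(cells))) {
    eta <- b0 + cfg$beta_age * age + cfg$beta_art * cells[k, 1] +
      cfg$beta_infertility * cells[k, 2]
    mix <- p_none * stats::plogis(eta)
    if (length(planted)) {
      for (j in seq_along(planted)) {
        mix <- mix + p_exp[j] * stats::plogis(eta + planted[j])
      }
    }
    rate <- rate + cells[k, 3] * mean(mix)
  }
  rate
}

calibrate_baseline <- function(cfg, target = cfg$mb_target) {
  stats::uniroot(function(b0) marginal_mb_rate(cfg, b0) - target,
                 lower = -20, upper = 5, tol = 1e-10)$root
}

# Truncated-normal draw via inverse-CDF on the truncated quantile range.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Generate a synthetic EHR delivery cohort
#'
#' Draws deliveries, medication orders and diagnosis records with the
#' statistical structure the downstream screen assumes. Maternal age is
#' truncated-normal; ART and infertility indicators are Bernoulli and are
#' emitted as ICD codes dated uniformly within the 315-day pre-delivery
#' lookback; per-medication exposures are Bernoulli and exposed deliveries
#' receive an order dated uniformly in \[delivery - 275 d, delivery - 215 d\]
#' under a randomly chosen brand or generic name; the MB outcome is drawn
#' from the configured logistic model and emitted as an MB diagnosis code
#' dated exactly on the delivery date.
#'
#' The same config (including seed) reproduces the tables byte-for-byte.
#'
#' @param config A [simulation_config()].
#' @return An object of class `synthetic_cohort`: list with `deliveries`,
#'   `orders`, `diagnoses` data frames, `truth` (planted log-odds by
#'   medication id), and internal simulation state (`outcome`, `art`,
#'   `infertility`, `exposure`) used by tests.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_deliveries
  m <- cfg$n_medications
  ids <- cfg$medication_ids

  npat <- ceiling(n / cfg$deliveries_per_patient)
  patient <- sprintf("pt_%06d", rep(seq_len(npat),
                                    each = cfg$deliveries_per_patient)[seq_len(n)])
  parity <- stats::ave(seq_len(n), patient, FUN = seq_along)
  base_date <- as.Date("2010-01-01") + sample.int(2922L, npat, replace = TRUE) - 1L
  delivery_date <- base_date[match(patient, unique(patient))] +
    (parity - 1L) * 500L
  deliveries <- data.frame(
    patient_id = patient,
    delivery_id = sprintf("dl_%06d", seq_len(n)),
    delivery_date = as.character(delivery_date),
    maternal_age = round(rtruncnorm(n, cfg$age_mean, cfg$age_sd, 12, 55), 2),
    stringsAsFactors = FALSE
  )

  art <- stats::rbinom(n, 1L, cfg$art_prevalence)
  inf <- stats::rbinom(n, 1L, cfg$infertility_prevalence)

  # exposure matrix, with optional correlated blocks sharing a common draw
  expo <- matrix(0L, n, m, dimnames = list(deliveries$delivery_id, ids))
  for (j in seq_len(m)) {
    expo[, j] <- stats::rbinom(n, 1L, cfg$exposure_prevalence[j])
  }
  if (!is.null(cfg$exposure_blocks)) {
    for (b in cfg$exposure_blocks) {
      shared <- stats::rbinom(n, 1L, cfg$exposure_prevalence[b$ids[1]])
      use <- matrix(stats::rbinom(n * length(b$ids), 1L, b$rho),
                    n, length(b$ids))
      expo[, b$ids] <- use * shared + (1L - use) * expo[, b$ids]
    }
  }

  eta <- cfg$baseline_mb_logit + cfg$beta_age * deliveries$maternal_age +
    cfg$beta_art * art + cfg$beta_infertility * inf +
    drop(expo %*% cfg$beta_medication)
  outcome <- stats::rbinom(n, 1L, stats::plogis(eta))

  # orders for exposed deliveries, dated uniformly inside the exposure window
  hit <- which(expo == 1L, arr.ind = TRUE)
  orders <- data.frame(patient_id = character(0), drug_name = character(0),
                       order_date = character(0), stringsAsFactors = FALSE)
  if (nrow(hit)) {
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    med <- ids[hit[, 2L]]
    offs <- sample(215:275, nrow(hit), replace = TRUE)
    name_pool <- split(cfg$annotations$name, cfg$annotations$medication_id)
    pick <- vapply(name_pool[med], function(nm) nm[sample.int(length(nm), 1L)],
                   character(1))
    orders <- data.frame(
      patient_id = deliveries$patient_id[hit[, 1L]],
      drug_name = unname(pick),
      order_date = as.character(delivery_date[hit[, 1L]] - offs),
      stringsAsFactors = FALSE
    )
  }

  dx <- list()
  if (any(outcome == 1L)) {
    w <- which(outcome == 1L)
    dx$mb <- data.frame(patient_id = deliveries$patient_id[w],
                        code_system = "ICD-10", code = "O30.0",
                        date = deliveries$delivery_date[w],
                        stringsAsFactors = FALSE)
  }
  if (any(art == 1L)) {
    w <- which(art == 1L)
    dx$art <- data.frame(patient_id = deliveries$patient_id[w],
                         code_system = "ICD-10", code = "O09.81",
                         date = as.character(delivery_date[w] -
                                               sample(0:315, length(w),
                                                      replace = TRUE)),
                         stringsAsFactors = FALSE)
  }
  if (any(inf == 1L)) {
    w <- which(inf == 1L)
    dx$inf <- data.frame(patient_id = deliveries$patient_id[w],
                         code_system = "ICD-10", code = "N97.9",
                         date = as.character(delivery_date[w] -
                                               sample(0:315, length(w),
                                                      replace = TRUE)),
                         stringsAsFactors = FALSE)
  }
  diagnoses <- if (length(dx)) do.call(rbind, unname(dx)) else
    data.frame(patient_id = character(0), code_system = character(0),
               code = character(0), date = character(0),
               stringsAsFactors = FALSE)
  rownames(diagnoses) <- NULL

  structure(list(
    deliveries = deliveries, orders = orders, diagnoses = diagnoses,
    truth = cfg$beta_medication,
    outcome = outcome, art = art, infertility = inf, exposure = expo,
    config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$deliveries), "deliveries,",
      nrow(x$orders), "orders,", nrow(x$diagnoses), "diagnosis records\n")
  cat("  MB rate:", round(mean(x$outcome), 4),
      "| planted medications:", sum(x$truth != 0), "\n")
  invisible(x)
}

#' Add decoy records that must not change any downstream assignment
#'
#' Appends (a) MB codes dated mid-pregnancy (not at delivery) for a
#' fraction of non-MB deliveries, (b) ART/infertility codes dated more than
#' 315 days before delivery, and (c) medication orders dated outside the
#' 275-215 day exposure window, including post-delivery orders. A correct
#' cohort/exposure builder ignores all of them: MB counts only when coded
#' at delivery, covariates only inside the lookback, exposure only inside
#' the window.
#'
#' @param cohort A `synthetic_cohort`.
#' @param config The same [simulation_config()] (uses `decoy_fraction` and
#'   a seed derived from `seed`).
#' @return The cohort with decoy rows appended (truth unchanged).
#' @export
emit_decoys <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  frac <- config$decoy_fraction
  if (frac == 0) return(cohort)
  set.seed((config$seed %% 1000003L) + 524287L)
  del <- cohort$deliveries
  ddate <- as.Date(del$delivery_date)
  n <- nrow(del)

  pickn <- function(k) if (k >= 1L) sample.int(n, min(n, k)) else integer(0)

  # (a) in-pregnancy MB codes on non-MB deliveries
  nonmb <- which(cohort$outcome == 0L)
  ka <- round(frac * length(nonmb))
  wa <- if (ka >= 1L) sample(nonmb, ka) else integer(0)
  # (b) ART / infertility codes before the 315-day lookback
  wb <- pickn(round(frac * n))
  # (c) orders outside the exposure window (both sides, incl. post-delivery)
  wc <- pickn(round(frac * n))

  add_dx <- list()
  if (length(wa)) {
    add_dx$mb <- data.frame(
      patient_id = del$patient_id[wa], code_system = "ICD-10", code = "O30.0",
      date = as.character(ddate[wa] - sample(60:200, length(wa),
                                             replace = TRUE)),
      stringsAsFactors = FALSE)
  }
  if (length(wb)) {
    half <- length(wb) %/% 2L
    add_dx$cov <- data.frame(
      patient_id = del$patient_id[wb],
      code_system = "ICD-10",
      code = rep(c("O09.81", "N97.9"), c(half, length(wb) - half)),
      date = as.character(ddate[wb] - sample(316:600, length(wb),
                                             replace = TRUE)),
      stringsAsFactors = FALSE)
  }
  if (length(add_dx)) {
    cohort$diagnoses <- rbind(cohort$diagnoses, do.call(rbind, unname(add_dx)))
    rownames(cohort$diagnoses) <- NULL
  }
  if (length(wc)) {
    offs <- sample(c(-30:214, 276:400), length(wc), replace = TRUE)
    meds <- sample(config$medication_ids, length(wc), replace = TRUE)
    first_name <- vapply(split(config$annotations$name,
                               config$annotations$medication_id),
                         `[`, character(1), 1L)
    cohort$orders <- rbind(cohort$orders, data.frame(
      patient_id = del$patient_id[wc],
      drug_name = unname(first_name[meds]),
      order_date = as.character(ddate[wc] - offs),
      stringsAsFactors = FALSE))
    rownames(cohort$orders) <- NULL
  }
  cohort
}

#' Write a synthetic cohort to delimited text files
#'
#' Writes `deliveries.csv`, `orders.csv`, `diagnoses.csv` and `truth.json`
#' (planted per-medication log-odds) into a directory.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$deliveries, file.path(dir, "deliveries.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$orders, file.path(dir, "orders.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$diagnoses, file.path(dir, "diagnoses.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(cohort$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
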