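#' Adjustment-model specification for the screen
#'
#' The three screening models share the per-medication binary exposure and
#' differ only in covariate adjustment: model 1 none, model 2 maternal
#' age, model 3 maternal age plus the ART-resulting-pregnancy and
#' infertility indicators.
#'
#' @param label `"model1"`, `"model2"` or `"model3"`.
#' @param alpha Significance level (default 0.05).
#' @return List of class `model_spec` with `label`, `covariates`, `alpha`.
#' @export
model_spec <- function(label = c("model3", "model1", "model2"),
                       alpha = 0.05) {
  label <- match.arg(label)
  stopifnot(alpha > 0, alpha < 1)
  covariates <- switch(label,
    model1 = character(0),
    model2 = "maternal_age",
    model3 = c("maternal_age", "art", "infertility"))
  structure(list(label = label, covariates = covariates, alpha = alpha),
            class = "model_spec")
}

#' Run the medication-wide association screen
#'
#' Fits one logistic model per retained medication: MB outcome on the
#' medication's binary exposure plus the model's covariates. The control
#' group for each medication is every other delivery, including deliveries
#' with no medication exposure at all. Odds ratios use the Wald 95% CI
#' `exp(beta +- 1.96 se)`; P values are two-sided Wald z tests; Bonferroni
#' adjustment multiplies by the family size `m` = number of retained
#' medications, fixed before fitting, and caps at 1. Non-converged or
#' separated fits are flagged and their OR/CI/P suppressed (`NA`), never
#' aborting the screen. Results are ordered by `medication_id`.
#'
#' @param cohort Analysis cohort from [build_cohort()].
#' @param exposure A filtered `exposure_matrix` aligned with `cohort` on
#'   `delivery_id`.
#' @param spec A [model_spec()] (or a model label passed to it).
#' @return Object of class `mwas_screen`: list with
#'   * `results`: one row per medication with `medication_id`, `n_exposed`,
#'     `n_exposed_mb`, `beta`, `se`, `or_`, `ci_low`, `ci_high`, `p`,
#'     `p_bonf`, `sig_nominal`, `sig_bonf`, `converged`;
#'   * `terms`: long table of every fitted coefficient (exposure and
#'     covariates) per medication, for forest-plot export;
#'   * `model`, `alpha`, `m` (Bonferroni family size), `n`.
#' @export
run_mwas <- function(cohort, exposure, spec = model_spec("model3")) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"), inherits(exposure, "exposure_matrix"))
  mat <- exposure$m
  stopifnot(setequal(rownames(mat), cohort$delivery_id))
  mat <- mat[match(cohort$delivery_id, rownames(mat)), , drop = FALSE]
  miss <- setdiff(spec$covariates, names(cohort))
  if (length(miss)) stop("cohort lacks covariate(s): ",
                         paste(miss, collapse = ", "))

  meds <- sort(colnames(mat))
  m <- length(meds)
  y <- cohort$mb
  covs <- as.matrix(cohort[, spec$covariates, drop = FALSE])
  z975 <- 1.96

  res <- vector("list", m)
  terms <- vector("list", m)
  for (j in seq_along(meds)) {
    ex <- mat[, meds[j]]
    x <- cbind(`(Intercept)` = 1, exposure = ex, covs)
    fit <- fit_logistic(y, x)
    b <- fit$coefficients["exposure"]
    s <- fit$se["exposure"]
    ok <- fit$converged == 1L && !is.na(b) && !is.na(s)
    p <- if (ok) 2 * stats::pnorm(-abs(b / s)) else NA_real_
    res[[j]] <- data.frame(
      medication_id = meds[j],
      n_exposed = sum(ex),
      n_exposed_mb = sum(ex * y),
      beta = if (ok) unname(b) else NA_real_,
      se = if (ok) unname(s) else NA_real_,
      or_ = if (ok) exp(unname(b)) else NA_real_,
      ci_low = if (ok) exp(unname(b) - z975 * unname(s)) else NA_real_,
      ci_high = if (ok) exp(unname(b) + z975 * unname(s)) else NA_real_,
      p = p,
      converged = as.integer(ok),
      stringsAsFactors = FALSE
    )
    est <- fit$coefficients
    ses <- fit$se
    keep <- setdiff(names(est), "(Intercept)")
    terms[[j]] <- data.frame(
      medication_id = meds[j],
      term = keep,
      beta = unname(est[keep]),
      se = unname(ses[keep]),
      or_ = exp(unname(est[keep])),
      ci_low = exp(unname(est[keep]) - z975 * unname(ses[keep])),
      ci_high = exp(unname(est[keep]) + z975 * unname(ses[keep])),
      converged = as.integer(fit$converged == 1L),
      stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, res)
  results$p_bonf <- pmin(1, m * results$p)
  results$sig_nominal <- as.integer(!is.na(results$p) &
                                      results$p < spec$alpha)
  results$sig_bonf <- as.integer(!is.na(results$p_bonf) &
                                   results$p_bonf < spec$alpha)
  rownames(results) <- NULL
  terms <- do.call(rbind, terms)
  rownames(terms) <- NULL
  structure(list(results = results, terms = terms, model = spec$label,
                 alpha = spec$alpha, m = m, n = nrow(cohort)),
            class = "mwas_screen")
}

#' @export
print.mwas_screen <- function(x, ...) {
  cat("<mwas_screen>", x$model, "-", x$m, "medications,", x$n,
      "deliveries\n")
  cat("  nominal P <", x$alpha, ":", sum(x$results$sig_nominal),
      "| Bonferroni:", sum(x$results$sig_bonf),
      "| non-converged:", sum(x$results$converged == 0L), "\n")
  invisible(x)
}

#' Export forest-plot data
#'
#' Long-format table of odds ratios and 95% CI bounds for the medication
#' exposure and each model covariate, one row per (medication, term), for
#' plotting model-3 style forest plots. Non-converged medications are
#' excluded and listed in the `excluded` attribute.
#'
#' @param screen An `mwas_screen` from [run_mwas()].
#' @param significant_only Restrict to nominally significant medications
#'   (default `TRUE`).
#' @return Data frame `medication_id`, `term`, `or_`, `ci_low`, `ci_high`;
#'   attribute `excluded` names the non-converged medications.
#' @export
export_forest <- function(screen, significant_only = TRUE) {
  stopifnot(inherits(screen, "mwas_screen"))
  res <- screen$results
  keep_ids <- res$medication_id[res$converged == 1L &
                                  (!significant_only | res$sig_nominal == 1L)]
  dropped <- res$medication_id[res$converged == 0L]
  out <- screen$terms[screen$terms$medication_id %in% keep_ids,
                      c("medication_id", "term", "or_", "ci_low", "ci_high")]
  out <- out[order(out$medication_id, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- dropped
  out
}
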