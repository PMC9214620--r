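#' Score a screen against a gold-standard medication list
#'
#' Treats the chosen significance flag (nominal or Bonferroni) as the
#' positive call and membership in the gold-standard list as the truth,
#' tallying TP/FP/FN/TN over all scored medications. Non-converged
#' medications count as negative calls (they carry no significance flag).
#'
#' @param results An `mwas_screen` or its `results` data frame (needs
#'   `medication_id`, `sig_nominal`, `sig_bonf`).
#' @param gold_ids Gold-standard medication ids; must all be among the
#'   scored medications.
#' @param mode `"nominal"` or `"bonferroni"`.
#' @return Object of class `confusion_matrix`: list with `tp`, `fp`, `fn`,
#'   `tn`, `total`, `mode`.
#' @export
score_screen <- function(results, gold_ids,
                         mode = c("nominal", "bonferroni")) {
  mode <- match.arg(mode)
  if (inherits(results, "mwas_screen")) results <- results$results
  stopifnot(all(c("medication_id", "sig_nominal", "sig_bonf") %in%
                  names(results)))
  missing_gold <- setdiff(gold_ids, results$medication_id)
  if (length(missing_gold)) {
    stop("gold-standard id(s) not among the scored medications: ",
         paste(missing_gold, collapse = ", "))
  }
  call <- if (mode == "nominal") results$sig_nominal else results$sig_bonf
  call <- call == 1L
  truth <- results$medication_id %in% gold_ids
  confusion_matrix(tp = sum(call & truth), fp = sum(call & !truth),
                   fn = sum(!call & truth), tn = sum(!call & !truth),
                   mode = mode)
}

#' Construct a confusion matrix
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @param mode Optional label for the calling mode.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn, mode = NA_character_) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion-matrix counts must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 total = as.integer(tp + fp + fn + tn), mode = mode),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>", if (!is.na(x$mode)) paste0("(", x$mode, ")"),
      "tp =", x$tp, "fp =", x$fp, "fn =", x$fn, "tn =", x$tn, "\n")
  invisible(x)
}

#' Performance metrics from a confusion matrix
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/total`, precision `tp/(tp+fp)` and F1
#' `2*precision*sensitivity/(precision+sensitivity)` at full precision. A
#' metric whose denominator is zero is undefined and reported as `NA`,
#' never coerced to 0.
#'
#' The `rounded` component reproduces the presentation convention of
#' published cohort-screen performance tables: sensitivity, specificity,
#' accuracy and precision rounded to 2 decimals, with F1 recomputed from
#' the rounded precision and sensitivity and then rounded. (Full-precision
#' F1 is retained in `metrics`; the two can differ in the second decimal.)
#'
#' @param cm A `confusion_matrix`.
#' @return Object of class `metric_bundle`: list with `metrics`
#'   (full-precision named vector), `rounded` (2-dp presentation vector),
#'   `undefined` (names of undefined metrics), and the source counts.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$total == 0L) stop("confusion matrix is empty")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(cm$tp, cm$tp + cm$fn)
  spec <- ratio(cm$tn, cm$tn + cm$fp)
  acc <- ratio(cm$tp + cm$tn, cm$total)
  prec <- ratio(cm$tp, cm$tp + cm$fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  metrics <- c(sensitivity = sens, specificity = spec, accuracy = acc,
               precision = prec, f1 = f1)
  r <- round(metrics[c("sensitivity", "specificity", "accuracy",
                       "precision")], 2)
  f1r <- if (is.na(r["precision"]) || is.na(r["sensitivity"]) ||
             r["precision"] + r["sensitivity"] == 0) NA_real_ else
    round(2 * r[["precision"]] * r[["sensitivity"]] /
            (r[["precision"]] + r[["sensitivity"]]), 2)
  rounded <- c(r, f1 = f1r)
  structure(list(metrics = metrics, rounded = rounded,
                 undefined = names(metrics)[is.na(metrics)],
                 counts = c(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)),
            class = "metric_bundle")
}

#' @export
print.metric_bundle <- function(x, ...) {
  cat("<metric_bundle>\n")
  print(round(x$metrics, 4))
  if (length(x$undefined)) {
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Six-row performance table over three screens and two calling modes
#'
#' One row per (model, mode) with the five metrics in 2-dp presentation
#' form (see [compute_metrics()] for the rounding convention) plus the
#' underlying counts.
#'
#' @param screens Named list of `mwas_screen` objects (or results data
#'   frames), e.g. `list(model1 = ..., model2 = ..., model3 = ...)`.
#' @param gold_ids Gold-standard medication ids.
#' @return Data frame with columns `model`, `mode`, `tp`, `fp`, `fn`,
#'   `tn`, `sensitivity`, `specificity`, `accuracy`, `precision`, `f1`.
#' @export
performance_table <- function(screens, gold_ids) {
  rows <- list()
  for (lab in names(screens)) {
    for (mode in c("nominal", "bonferroni")) {
      cm <- score_screen(screens[[lab]], gold_ids, mode)
      mb <- compute_metrics(cm)
      rows[[paste(lab, mode)]] <- data.frame(
        model = lab, mode = mode,
        tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
        t(mb$rounded), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
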