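#' Map raw order names to ingredient-level medication ids
#'
#' Case-insensitive exact match of the raw `drug_name` against the
#' annotation's name set, collapsing brand and generic products to one
#' ingredient-level `medication_id` (e.g. "Imitrex" and "sumatriptan" both
#' map to the sumatriptan id). Unmatched orders are excluded; their count
#' is attached as the `n_unmatched` attribute and reported via `message()`.
#'
#' @param orders Data frame with `patient_id`, `drug_name`, `order_date`.
#' @param annotations Annotation table with `medication_id`, `name` (one
#'   row per raw name); a raw name mapping to more than one id is an error.
#' @return `orders` with a `medication_id` column, unmatched rows dropped.
#' @export
map_orders <- function(orders, annotations = default_annotations()) {
  key <- tolower(trimws(annotations$name))
  dup <- unique(key[duplicated(paste(key))])
  dup <- dup[vapply(dup, function(k) {
    length(unique(annotations$medication_id[key == k])) > 1L
  }, logical(1))]
  if (length(dup)) {
    stop("annotation-table error: name(s) mapped to more than one ",
         "medication id: ", paste(dup, collapse = ", "))
  }
  if (nrow(orders) == 0L) {
    out <- orders
    out$medication_id <- character(0)
    attr(out, "n_unmatched") <- 0L
    return(out)
  }
  stopifnot(all(nzchar(orders$drug_name)))
  id <- annotations$medication_id[match(tolower(trimws(orders$drug_name)), key)]
  n_un <- sum(is.na(id))
  if (n_un > 0L) {
    message(n_un, " order(s) with unmatched drug names excluded (e.g. ",
            paste(utils::head(unique(orders$drug_name[is.na(id)]), 3),
                  collapse = ", "), ")")
  }
  out <- orders[!is.na(id), , drop = FALSE]
  out$medication_id <- id[!is.na(id)]
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- n_un
  out
}

#' Build the binary preconception-exposure matrix
#'
#' A delivery is exposed to a medication iff its patient has at least one
#' mapped order of that medication dated in
#' `[delivery_date - window[1], delivery_date - window[2]]` days, both
#' endpoints inclusive (default 275 to 215 days before delivery, bracketing
#' conception and the early first trimester). Multiple orders collapse to a
#' single 1. Orders dated after the delivery raise a warning and are
#' ignored, as are orders outside the window.
#'
#' @param cohort Analysis cohort (rows unique on `delivery_id`) from
#'   [build_cohort()].
#' @param mapped_orders Orders carrying `medication_id` ([map_orders()]).
#' @param window Integer pair `c(start, end)` in days before delivery,
#'   `start > end`.
#' @return An object of class `exposure_matrix`: list with `m` (integer 0/1
#'   matrix, rownames `delivery_id`, colnames `medication_id`),
#'   `patient_id` (along rows), and `n_patients` (distinct exposed patients
#'   per medication).
#' @export
window_exposure <- function(cohort, mapped_orders, window = c(275L, 215L)) {
  stopifnot(!anyDuplicated(cohort$delivery_id),
            length(window) == 2L, window[1] > window[2], window[2] >= 0)
  meds <- sort(unique(mapped_orders$medication_id))
  m <- matrix(0L, nrow(cohort), length(meds),
              dimnames = list(cohort$delivery_id, meds))
  if (nrow(mapped_orders)) {
    odate <- as_day(mapped_orders$order_date)
    ddate <- as_day(cohort$delivery_date)
    # one row per (order, same-patient delivery) pair
    by_pat <- split(seq_len(nrow(cohort)), cohort$patient_id)
    hits <- match(mapped_orders$patient_id, names(by_pat))
    reps <- lengths(by_pat)[hits]
    reps[is.na(reps)] <- 0L
    oi <- rep(seq_len(nrow(mapped_orders)), reps)
    di <- unlist(by_pat[hits[!is.na(hits)]], use.names = FALSE)
    if (length(oi)) {
      lag <- as.integer(ddate[di]) - as.integer(odate[oi])
      post <- lag < 0
      if (any(post)) {
        warning(sum(post), " order(s) dated after a same-patient delivery ",
                "ignored")
      }
      keep <- lag >= window[2] & lag <= window[1]
      if (any(keep)) {
        m[cbind(di[keep],
                match(mapped_orders$medication_id[oi[keep]], meds))] <- 1L
      }
    }
  }
  new_exposure_matrix(m, cohort$patient_id)
}

new_exposure_matrix <- function(m, patient_id) {
  stopifnot(nrow(m) == length(patient_id))
  n_pat <- vapply(seq_len(ncol(m)), function(j) {
    length(unique(patient_id[m[, j] == 1L]))
  }, integer(1))
  names(n_pat) <- colnames(m)
  structure(list(m = m, patient_id = as.character(patient_id),
                 n_patients = n_pat),
            class = "exposure_matrix")
}

#' @export
print.exposure_matrix <- function(x, ...) {
  cat("<exposure_matrix>", nrow(x$m), "deliveries x", ncol(x$m),
      "medications;", sum(rowSums(x$m) > 0), "deliveries with any exposure\n")
  invisible(x)
}

#' Drop medications prescribed to fewer than `threshold` patients
#'
#' Retains only medications with at least `threshold` distinct exposed
#' patients (not deliveries) inside the exposure window; the retained
#' column count is the Bonferroni family size for the screen. Idempotent.
#'
#' @param exposure An `exposure_matrix`.
#' @param threshold Minimum distinct-patient count (default 5).
#' @return A filtered `exposure_matrix`.
#' @export
filter_min_patients <- function(exposure, threshold = 5L) {
  stopifnot(inherits(exposure, "exposure_matrix"), threshold >= 1L)
  keep <- exposure$n_patients >= threshold
  new_exposure_matrix(exposure$m[, keep, drop = FALSE], exposure$patient_id)
}
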