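# Tiny fixture builders used across test files.

# A hand-sized delivery table: one row per (patient, delivery date offset).
make_deliveries <- function(dates = c("2015-06-01", "2016-03-15"),
                            ages = NULL) {
  n <- length(dates)
  if (is.null(ages)) ages <- rep(30, n)
  data.frame(
    patient_id = sprintf("p%02d", seq_len(n)),
    delivery_id = sprintf("d%02d", seq_len(n)),
    delivery_date = dates,
    maternal_age = ages,
    stringsAsFactors = FALSE
  )
}

make_dx <- function(patient_id, code, date, code_system = "ICD-10") {
  data.frame(patient_id = patient_id,
             code_system = rep_len(code_system, length(patient_id)),
             code = code, date = date, stringsAsFactors = FALSE)
}

make_orders <- function(patient_id, drug_name, order_date) {
  data.frame(patient_id = patient_id, drug_name = drug_name,
             order_date = order_date, stringsAsFactors = FALSE)
}

empty_dx <- function() make_dx(character(0), character(0), character(0))

offset_date <- function(date, days) as.character(as.Date(date) + days)

# Expand a 2x2 table (exposed/unexposed x MB/no-MB) into outcome and
# exposure vectors.
expand_2x2 <- function(exp_mb, exp_no, unexp_mb, unexp_no) {
  list(
    y = rep(c(1, 0, 1, 0), c(exp_mb, exp_no, unexp_mb, unexp_no)),
    ex = rep(c(1, 1, 0, 0), c(exp_mb, exp_no, unexp_mb, unexp_no))
  )
}

# A fabricated screen-results table with prescribed call sets, for
# validation tests: ids med_001..med_<n>.
fake_results <- function(n, nominal_ids, bonf_ids) {
  ids <- sprintf("med_%03d", seq_len(n))
  stopifnot(all(bonf_ids %in% nominal_ids), all(nominal_ids %in% ids))
  data.frame(
    medication_id = ids,
    sig_nominal = as.integer(ids %in% nominal_ids),
    sig_bonf = as.integer(ids %in% bonf_ids),
    converged = 1L,
    stringsAsFactors = FALSE
  )
}

# Build an exposure_matrix directly from a 0/1 matrix (rows = deliveries).
raw_exposure <- function(m, patient_id = rownames(m)) {
  medwas:::new_exposure_matrix(m, patient_id)
}
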