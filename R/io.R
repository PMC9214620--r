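read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop(path, " lacks required column(s): ", paste(miss, collapse = ", "))
  }
  x
}

#' Read the EHR-style input tables
#'
#' Thin CSV readers that validate the required columns: deliveries
#' (`patient_id`, `delivery_id`, `delivery_date`, `maternal_age`), orders
#' (`patient_id`, `drug_name`, `order_date`) and diagnoses (`patient_id`,
#' `code_system`, `code`, `date`). Dates are ISO-8601 day strings.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_deliveries <- function(path) {
  x <- read_csv_checked(path, c("patient_id", "delivery_id",
                                "delivery_date", "maternal_age"))
  x$maternal_age <- as.numeric(x$maternal_age)
  x
}

#' @rdname read_deliveries
#' @export
read_orders <- function(path) {
  read_csv_checked(path, c("patient_id", "drug_name", "order_date"))
}

#' @rdname read_deliveries
#' @export
read_diagnoses <- function(path) {
  read_csv_checked(path, c("patient_id", "code_system", "code", "date"))
}

#' Read diagnosis code lists from CSV
#'
#' Expects columns `list_name` (`MB`, `ART`, `INFERTILITY`), `code_system`
#' and `code`; returns the named list of [code_list()] objects that
#' [build_cohort()] takes.
#'
#' @param path CSV file path.
#' @return Named list of `code_list` objects.
#' @export
read_code_lists <- function(path) {
  x <- read_csv_checked(path, c("list_name", "code_system", "code"))
  out <- lapply(split(x, x$list_name), function(d) {
    code_list(d$list_name[1], d[, c("code_system", "code")])
  })
  need <- c("MB", "ART", "INFERTILITY")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop(path, " lacks code list(s): ",
                         paste(miss, collapse = ", "))
  out[need]
}

#' Read a medication annotation table from CSV
#'
#' Expects `medication_id`, `name`, `generic_name`, `drug_class`,
#' `pregnancy_category`, `fertility_flag` with one row per raw name.
#'
#' @param path CSV file path.
#' @return Annotation data frame.
#' @export
read_annotations <- function(path) {
  x <- read_csv_checked(path, c("medication_id", "name", "generic_name",
                                "drug_class", "pregnancy_category",
                                "fertility_flag"))
  x$fertility_flag <- as.integer(x$fertility_flag)
  x
}

#' Write / read screen results
#'
#' `write_screen()` writes the per-medication results of an `mwas_screen`
#' to CSV; `read_results()` reads such a file back, validating the columns
#' the validation stage needs.
#'
#' @param screen An `mwas_screen`.
#' @param path CSV file path.
#' @return `write_screen()`: `path` invisibly; `read_results()`: data
#'   frame.
#' @export
write_screen <- function(screen, path) {
  stopifnot(inherits(screen, "mwas_screen"))
  utils::write.csv(screen$results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen
#' @export
read_results <- function(path) {
  read_csv_checked(path, c("medication_id", "n_exposed", "n_exposed_mb",
                           "or_", "p", "p_bonf", "sig_nominal", "sig_bonf",
                           "converged"))
}

#' Write an exposure matrix to CSV
#'
#' Wide binary layout: `delivery_id`, `patient_id`, one 0/1 column per
#' medication.
#'
#' @param exposure An `exposure_matrix`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_exposure_matrix <- function(exposure, path) {
  stopifnot(inherits(exposure, "exposure_matrix"))
  out <- data.frame(delivery_id = rownames(exposure$m),
                    patient_id = exposure$patient_id,
                    exposure$m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exposure_matrix
#' @export
read_exposure_matrix <- function(path) {
  x <- read_csv_checked(path, c("delivery_id", "patient_id"))
  m <- as.matrix(x[, setdiff(names(x), c("delivery_id", "patient_id")),
                   drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- x$delivery_id
  new_exposure_matrix(m, x$patient_id)
}
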