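#' Default diagnosis code lists
#'
#' Editable default ICD code lists for the multiple-birth (MB) outcome and
#' the ART-resulting-pregnancy and infertility covariates. These are
#' plausible ICD-9-CM / ICD-10 families for each concept, used by the
#' synthetic generator and as defaults for cohort construction; they are a
#' configurable stand-in, not an authoritative clinical list, and real
#' analyses should supply their own lists via `code_list()` or a CSV.
#'
#' A code ending in `"."` is a dot-terminated prefix and matches the whole
#' family (e.g. `"O30."` matches `"O30"`, `"O30.0"`, `"O30.003"`).
#'
#' @return A named list of three `code_list` objects: `MB`, `ART`,
#'   `INFERTILITY`.
#' @seealso [code_list()], [match_codes()]
#' @export
#' @examples
#' default_code_lists()$MB
default_code_lists <- function() {
  list(
    MB = code_list("MB", data.frame(
      code_system = c("ICD-9-CM", "ICD-9-CM", "ICD-9-CM", "ICD-9-CM",
                      "ICD-9-CM", "ICD-9-CM", "ICD-9-CM",
                      "ICD-10", "ICD-10", "ICD-10", "ICD-10", "ICD-10",
                      "ICD-10", "ICD-10"),
      code = c("651.", "V27.2", "V27.3", "V27.4", "V27.5", "V27.6", "V27.7",
               "O30.", "Z37.2", "Z37.3", "Z37.4", "Z37.5", "Z37.6", "Z37.7")
    )),
    ART = code_list("ART", data.frame(
      code_system = c("ICD-9-CM", "ICD-10"),
      code = c("V23.85", "O09.81")
    )),
    INFERTILITY = code_list("INFERTILITY", data.frame(
      code_system = c("ICD-9-CM", "ICD-10"),
      code = c("628.", "N97.")
    ))
  )
}

#' Construct a diagnosis code list
#'
#' @param name Label for the list; one of `"MB"`, `"ART"`, `"INFERTILITY"`.
#' @param codes Data frame with columns `code_system` (one of `"ICD-9-CM"`,
#'   `"ICD-10"`) and `code`. Codes are exact strings, or dot-terminated
#'   prefixes matching a whole family.
#' @return An object of class `code_list`.
#' @export
code_list <- function(name, codes) {
  name <- match.arg(name, c("MB", "ART", "INFERTILITY"))
  stopifnot(is.data.frame(codes),
            all(c("code_system", "code") %in% names(codes)))
  codes <- codes[, c("code_system", "code")]
  codes$code_system <- as.character(codes$code_system)
  codes$code <- as.character(codes$code)
  if (nrow(codes) == 0L) stop("code list '", name, "' is empty")
  if (any(!nzchar(codes$code))) stop("code list '", name, "' has empty codes")
  bad <- setdiff(unique(codes$code_system), c("ICD-9-CM", "ICD-10"))
  if (length(bad)) {
    stop("code list '", name, "' has unrecognized code systems: ",
         paste(bad, collapse = ", "))
  }
  structure(list(name = name, codes = codes), class = "code_list")
}

#' @export
print.code_list <- function(x, ...) {
  cat("<code_list>", x$name, "-", nrow(x$codes), "entries\n")
  print(x$codes, row.names = FALSE)
  invisible(x)
}

#' Match diagnosis codes against a code list
#'
#' Exact match on `(code_system, code)`, plus family matching for list
#' entries whose code ends in `"."`: the entry `"O30."` matches the code
#' `"O30"` itself and any code starting with `"O30."`. Records with an
#' unrecognized code system are skipped with one warning.
#'
#' @param diagnoses Data frame with columns `code_system`, `code`.
#' @param codes A [code_list()].
#' @return Logical vector along the rows of `diagnoses`.
#' @export
match_codes <- function(diagnoses, codes) {
  stopifnot(inherits(codes, "code_list"))
  sys <- as.character(diagnoses$code_system)
  code <- as.character(diagnoses$code)
  known <- sys %in% c("ICD-9-CM", "ICD-10")
  if (any(!known)) {
    warning(sum(!known), " diagnosis record(s) with unrecognized code system ",
            "skipped: ", paste(unique(sys[!known]), collapse = ", "))
  }
  hit <- rep(FALSE, length(code))
  entries <- codes$codes
  prefix <- endsWith(entries$code, ".")
  if (any(!prefix)) {
    key <- paste(sys, code, sep = "\r")
    exact <- paste(entries$code_system[!prefix], entries$code[!prefix],
                   sep = "\r")
    hit <- hit | (key %in% exact)
  }
  for (i in which(prefix)) {
    stem <- sub("\\.$", "", entries$code[i])
    hit <- hit | (sys == entries$code_system[i] &
                    (code == stem | startsWith(code, paste0(stem, "."))))
  }
  hit & known
}

#' Default medication annotation table
#'
#' An editable default annotation of `n_medications` ingredient-level
#' medications: the first 15 are fertility/ART-treatment medications
#' (`fertility_flag = 1`, the default gold standard), the next block names
#' medications commonly screened in pregnancy pharmacoepidemiology, and the
#' remainder are synthetic fillers. Brand and generic names map to one
#' ingredient-level `medication_id` (e.g. Imitrex and sumatriptan).
#'
#' This table is a synthetic default for simulation and testing; real
#' analyses supply their own annotation CSV.
#'
#' @param n_medications Total number of medications; tables smaller than
#'   the named set truncate it (the first 15 ids stay the fertility set).
#' @return Data frame with one row per raw name: `medication_id`, `name`,
#'   `generic_name`, `drug_class`, `pregnancy_category`, `fertility_flag`.
#' @export
#' @examples
#' ann <- default_annotations()
#' subset(ann, fertility_flag == 1)[1:5, ]
default_annotations <- function(n_medications = 123L) {
  stopifnot(n_medications >= 1L)
  named <- list(
    # generic name, brand names, class, pregnancy category, fertility flag
    list("clomiphene", c("Clomid"), "fertility treatment", "X", 1L),
    list("letrozole", c("Femara"), "fertility treatment", "X", 1L),
    list("follitropin alfa", c("Gonal-F"), "fertility treatment", "X", 1L),
    list("follitropin beta", c("Follistim"), "fertility treatment", "X", 1L),
    list("menotropins", c("Menopur"), "fertility treatment", "X", 1L),
    list("urofollitropin", c("Bravelle"), "fertility treatment", "X", 1L),
    list("chorionic gonadotropin", c("Novarel", "Pregnyl"),
         "fertility treatment", "X", 1L),
    list("choriogonadotropin alfa", c("Ovidrel"), "fertility treatment",
         "X", 1L),
    list("leuprolide", c("Lupron"), "fertility treatment", "X", 1L),
    list("ganirelix", c("Antagon"), "fertility treatment", "X", 1L),
    list("cetrorelix", c("Cetrotide"), "fertility treatment", "X", 1L),
    list("progesterone", c("Crinone", "Endometrin"), "fertility treatment",
         "B", 1L),
    list("estradiol", c("Vivelle", "Estrace"), "fertility treatment", "X", 1L),
    list("tamoxifen", c("Nolvadex"), "fertility treatment", "D", 1L),
    list("bromocriptine", c("Parlodel"), "fertility treatment", "B", 1L),
    # non-fertility medications named in published MB screens
    list("sumatriptan", c("Imitrex"), "pain", "C", 0L),
    list("oxytocin", c("Pitocin"), "obstetrics", "unassigned", 0L),
    list("lorazepam", c("Ativan"), "psychiatric", "D", 0L),
    list("albuterol", c("Ventolin", "ProAir"), "asthma", "C", 0L),
    list("fluticasone propionate and salmeterol", c("Advair"), "asthma",
         "C", 0L),
    list("epinephrine", c("EpiPen"), "asthma", "C", 0L),
    list("dicyclomine", c("Bentyl"), "gastrointestinal", "B", 0L),
    list("heparin", character(0), "anticoagulant", "C", 0L),
    list("insulin aspart, human", c("NovoLog"), "antidiabetic", "B", 0L),
    list("lidocaine and prilocaine", c("EMLA"), "pain", "B", 0L),
    list("methylprednisolone", c("Medrol"), "corticosteroid", "C", 0L),
    list("diazepam", c("Valium"), "psychiatric", "D", 0L),
    list("amoxicillin", c("Amoxil"), "antibiotic", "B", 0L),
    list("doxycycline", c("Vibramycin"), "antibiotic", "D", 0L),
    list("medroxyprogesterone acetate", c("Provera"), "hormone", "X", 0L)
  )
  filler_classes <- c("pain", "antibiotic", "antihistamine", "antiemetic",
                      "cardiovascular", "dermatologic", "thyroid",
                      "antidepressant", "gastrointestinal", "antiviral")
  filler_cats <- c("unassigned", "C", "B", "A", "D")
  named <- named[seq_len(min(length(named), n_medications))]
  rows <- vector("list", n_medications)
  for (i in seq_along(named)) {
    x <- named[[i]]
    id <- sprintf("med_%03d", i)
    nm <- c(x[[1]], x[[2]])
    rows[[i]] <- data.frame(
      medication_id = id, name = nm, generic_name = x[[1]],
      drug_class = x[[3]], pregnancy_category = x[[4]],
      fertility_flag = x[[5]]
    )
  }
  for (i in seq_len(n_medications - length(named)) + length(named)) {
    id <- sprintf("med_%03d", i)
    gen <- sprintf("genericin-%03d", i)
    rows[[i]] <- data.frame(
      medication_id = id, name = c(gen, sprintf("Brandex-%03d", i)),
      generic_name = gen,
      drug_class = filler_classes[(i %% length(filler_classes)) + 1L],
      pregnancy_category = filler_cats[(i %% length(filler_cats)) + 1L],
      fertility_flag = 0L
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default gold-standard medication ids
#'
#' Medication ids flagged as fertility/ART-treatment medications in an
#' annotation table; the default annotation yields 15 such medications.
#'
#' @param annotations Annotation table from [default_annotations()] or
#'   [read_annotations()].
#' @return Character vector of unique medication ids.
#' @export
gold_standard_ids <- function(annotations = default_annotations()) {
  unique(annotations$medication_id[annotations$fertility_flag == 1L])
}
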