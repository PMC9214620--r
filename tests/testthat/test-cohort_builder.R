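test_that("MB is assigned only when coded exactly at delivery", {
  del <- make_deliveries(c("2015-06-01", "2016-03-15", "2014-01-10"))
  dx <- rbind(
    make_dx("p01", "O30.0", "2015-06-01"),              # at delivery -> 1
    make_dx("p02", "O30.0", offset_date("2016-03-15", -60))  # in pregnancy
  )
  expect_identical(assign_mb(del, dx), c(1L, 0L, 0L))
  expect_identical(assign_mb(del, empty_dx()), c(0L, 0L, 0L))
  # ICD-9 family code via dot-terminated prefix
  dx9 <- make_dx("p03", "651.01", "2014-01-10", code_system = "ICD-9-CM")
  expect_identical(assign_mb(del, dx9), c(0L, 0L, 1L))
})

test_that("the at-delivery tolerance widens the MB match symmetrically", {
  del <- make_deliveries("2015-06-01")
  dx <- make_dx("p01", "Z37.2", offset_date("2015-06-01", -2))
  expect_identical(assign_mb(del, dx), 0L)
  expect_identical(assign_mb(del, dx, tolerance_days = 2), 1L)
  dx_after <- make_dx("p01", "Z37.2", offset_date("2015-06-01", 2))
  expect_identical(assign_mb(del, dx_after, tolerance_days = 2), 1L)
})

test_that("ART/infertility lookback endpoints are inclusive at -315 and 0", {
  del <- make_deliveries("2016-03-15")
  at <- function(days, code = "O09.81") {
    cov <- assign_art_infertility(del, make_dx("p01", code,
                                               offset_date("2016-03-15",
                                                           days)))
    if (code == "O09.81") cov$art else cov$infertility
  }
  expect_identical(at(-315), 1L)   # boundary: inside
  expect_identical(at(-316), 0L)   # one day earlier: outside
  expect_identical(at(0, "N97.9"), 1L)  # delivery date itself: inside
  expect_identical(at(1), 0L)      # after delivery: outside
})

test_that("unknown code systems are skipped with a warning", {
  del <- make_deliveries("2015-06-01")
  dx <- make_dx("p01", "O30.0", "2015-06-01", code_system = "SNOMED")
  expect_warning(mb <- assign_mb(del, dx), "unrecognized code system")
  expect_identical(mb, 0L)
})

test_that("code matching distinguishes exact codes from dot prefixes", {
  del <- make_deliveries("2015-06-01")
  # "O30." must match O30 itself and any child, but not O300 or O31
  for (code in c("O30", "O30.0", "O30.003")) {
    expect_identical(assign_mb(del, make_dx("p01", code, "2015-06-01")), 1L)
  }
  for (code in c("O300", "O31", "O3")) {
    expect_identical(assign_mb(del, make_dx("p01", code, "2015-06-01")), 0L)
  }
  # exact entries match only themselves
  expect_identical(assign_mb(del, make_dx("p01", "Z37.21", "2015-06-01")), 0L)
})

test_that("adding a qualifying diagnosis never turns a flag off", {
  set.seed(20)
  for (i in 1:25) {
    n <- 6
    del <- make_deliveries(as.character(as.Date("2015-01-01") +
                                          sample(0:700, n)))
    dx <- make_dx(sample(del$patient_id, 4, replace = TRUE), "O09.81",
                  as.character(as.Date("2015-01-01") + sample(0:700, 4)))
    before <- assign_art_infertility(del, dx)$art
    extra_pat <- sample(del$patient_id, 1)
    extra_date <- del$delivery_date[del$patient_id == extra_pat]
    after <- assign_art_infertility(del, rbind(dx, make_dx(extra_pat,
                                                           "O09.81",
                                                           extra_date)))$art
    expect_true(all(after >= before))
    expect_identical(after[del$patient_id == extra_pat], 1L)
  }
})

test_that("build_cohort assembles outcome and covariates per delivery", {
  del <- make_deliveries(c("2015-06-01", "2016-03-15"), ages = c(28, 41))
  dx <- rbind(
    make_dx("p01", "O30.0", "2015-06-01"),
    make_dx("p01", "N97.1", offset_date("2015-06-01", -100)),
    make_dx("p02", "O09.81", offset_date("2016-03-15", -400))  # too early
  )
  co <- build_cohort(del, dx)
  expect_identical(co$mb, c(1L, 0L))
  expect_identical(co$infertility, c(1L, 0L))
  expect_identical(co$art, c(0L, 0L))
  expect_identical(co$maternal_age, c(28, 41))
  expect_error(build_cohort(rbind(del, del), dx))
})

test_that("cohort summary reproduces published-scale stratum arithmetic", {
  # deliveries: 231 fertility-exposed (37 MB), 1646 other-exposed (49 MB),
  # 61457 unexposed (1476 MB) -> totals 63334 deliveries, 1562 MB
  n <- 63334L
  mb <- integer(n); mb[1:37] <- 1L; mb[232:280] <- 1L; mb[1878:3353] <- 1L
  cohort <- data.frame(
    delivery_id = sprintf("d%06d", 1:n), patient_id = sprintf("p%06d", 1:n),
    delivery_date = "2015-01-01", maternal_age = 29.5,
    mb = mb, art = 0L, infertility = 0L, stringsAsFactors = FALSE)
  m <- matrix(0L, n, 2, dimnames = list(cohort$delivery_id,
                                        c("med_fert", "med_other")))
  m[1:231, "med_fert"] <- 1L
  m[232:1877, "med_other"] <- 1L
  s <- summarize_cohort(cohort, raw_exposure(m, cohort$patient_id),
                        fertility_ids = "med_fert")
  expect_identical(s$n, c(63334L, 61457L, 1877L, 231L))
  expect_identical(s$mb_n, c(1562L, 1476L, 86L, 37L))
  expect_equal(s$mb_pct, c(2.47, 2.40, 4.58, 16.0))
  # exposure strata partition the cohort
  expect_identical(s$n[s$stratum == "no_exposure"] +
                     s$n[s$stratum == "any_exposure"],
                   s$n[s$stratum == "all"])
})

test_that("empty strata report zero counts and percentages", {
  cohort <- data.frame(delivery_id = "d1", patient_id = "p1",
                       delivery_date = "2015-01-01", maternal_age = 30,
                       mb = 0L, art = 0L, infertility = 0L)
  s <- summarize_cohort(cohort, NULL)
  fert <- s[s$stratum == "fertility_exposure", ]
  expect_identical(fert$n, 0L)
  expect_identical(fert$mb_pct, 0)
})
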