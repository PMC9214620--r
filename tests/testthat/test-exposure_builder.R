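test_that("brand and generic names map to one ingredient id", {
  ann <- default_annotations(30)
  orders <- make_orders(c("p1", "p2", "p3"),
                        c("Imitrex", "SUMATRIPTAN", "xyzzy"),
                        rep("2015-01-01", 3))
  expect_message(mapped <- map_orders(orders, ann), "unmatched")
  expect_identical(nrow(mapped), 2L)
  expect_identical(unique(mapped$medication_id), "med_016")
  expect_identical(attr(mapped, "n_unmatched"), 1L)
})

test_that("duplicate names across medication ids are an annotation error", {
  ann <- data.frame(medication_id = c("m1", "m2"), name = c("DrugA", "druga"),
                    generic_name = "a", drug_class = "x",
                    pregnancy_category = "C", fertility_flag = 0L)
  expect_error(map_orders(make_orders("p1", "DrugA", "2015-01-01"), ann),
               "more than one")
  # the same name twice under one id is fine
  ann$medication_id <- "m1"
  expect_silent(mapped <- map_orders(make_orders("p1", "DrugA", "2015-01-01"),
                                     ann))
  expect_identical(mapped$medication_id, "m1")
})

test_that("an empty order table maps to an empty mapped table", {
  mapped <- map_orders(make_orders(character(0), character(0), character(0)))
  expect_identical(nrow(mapped), 0L)
  expect_true("medication_id" %in% names(mapped))
})

test_that("exposure window 275-215 days before delivery is inclusive", {
  del <- make_deliveries("2016-03-15")
  cohort <- build_cohort(del, empty_dx())
  ann <- default_annotations(5)
  for (case in list(list(-275, 1L), list(-245, 1L), list(-215, 1L),
                    list(-214, 0L), list(-276, 0L))) {
    orders <- map_orders(make_orders("p01", "Clomid",
                                     offset_date("2016-03-15", case[[1]])),
                         ann)
    ex <- window_exposure(cohort, orders)
    expect_identical(unname(ex$m[1, "med_001"]), case[[2]])
  }
})

test_that("multiple in-window orders collapse to a single binary entry", {
  del <- make_deliveries("2016-03-15")
  cohort <- build_cohort(del, empty_dx())
  orders <- map_orders(
    make_orders(rep("p01", 3), c("Clomid", "clomiphene", "Clomid"),
                offset_date("2016-03-15", c(-275, -240, -215))),
    default_annotations(5))
  ex <- window_exposure(cohort, orders)
  expect_identical(unname(ex$m[1, "med_001"]), 1L)
  expect_identical(unname(ex$n_patients["med_001"]), 1L)
})

test_that("orders after delivery warn and are ignored", {
  del <- make_deliveries("2016-03-15")
  cohort <- build_cohort(del, empty_dx())
  orders <- map_orders(make_orders("p01", "Clomid",
                                   offset_date("2016-03-15", 10)),
                       default_annotations(5))
  expect_warning(ex <- window_exposure(cohort, orders), "after")
  expect_true(all(ex$m == 0L))
})

test_that("window membership is translation invariant", {
  set.seed(31)
  ann <- default_annotations(10)
  for (k in c(-400, 17, 1000)) {
    dates <- as.character(as.Date("2015-01-01") + sample(0:900, 8))
    del <- make_deliveries(dates)
    orders <- make_orders(sample(del$patient_id, 30, replace = TRUE),
                          sample(ann$name, 30, replace = TRUE),
                          as.character(as.Date("2015-01-01") +
                                         sample(0:900, 30, replace = TRUE)))
    cohort <- build_cohort(del, empty_dx())
    base <- suppressWarnings(
      window_exposure(cohort, map_orders(orders, ann)))
    del2 <- del; del2$delivery_date <- offset_date(del$delivery_date, k)
    orders2 <- orders; orders2$order_date <- offset_date(orders$order_date, k)
    shifted <- suppressWarnings(
      window_exposure(build_cohort(del2, empty_dx()),
                      map_orders(orders2, ann)))
    expect_identical(shifted$m, base$m)
  }
})

test_that("a patient's order can expose each of their deliveries", {
  del <- make_deliveries(c("2015-06-01", "2016-10-01"))
  del$patient_id <- "p01"        # same patient, two deliveries
  cohort <- build_cohort(del, empty_dx())
  # in the window of the first delivery only
  orders <- map_orders(make_orders("p01", "Clomid",
                                   offset_date("2015-06-01", -240)),
                       default_annotations(5))
  ex <- window_exposure(cohort, orders)
  expect_identical(unname(ex$m[, "med_001"]), c(1L, 0L))
  expect_identical(unname(ex$n_patients["med_001"]), 1L)
})

test_that("the minimum-patient filter boundary sits at exactly 5 patients", {
  m <- matrix(0L, 10, 2, dimnames = list(sprintf("d%02d", 1:10),
                                         c("med_four", "med_five")))
  m[1:4, "med_four"] <- 1L
  m[1:5, "med_five"] <- 1L
  ex <- raw_exposure(m, sprintf("p%02d", 1:10))
  kept <- filter_min_patients(ex, 5L)
  expect_identical(colnames(kept$m), "med_five")
  # distinct patients, not deliveries: med_five exposures on one patient
  ex2 <- raw_exposure(m, c(rep("p01", 5), sprintf("p%02d", 6:10)))
  expect_identical(ncol(filter_min_patients(ex2, 5L)$m), 0L)
})

test_that("filtering is idempotent and threshold 1 keeps nonzero columns", {
  set.seed(8)
  m <- matrix(rbinom(200, 1, 0.3), 20, 10,
              dimnames = list(sprintf("d%02d", 1:20),
                              sprintf("med_%03d", 1:10)))
  storage.mode(m) <- "integer"
  ex <- raw_exposure(m, sprintf("p%02d", 1:20))
  once <- filter_min_patients(ex, 5L)
  twice <- filter_min_patients(once, 5L)
  expect_identical(twice$m, once$m)
  expect_identical(colnames(filter_min_patients(ex, 1L)$m),
                   colnames(m)[colSums(m) > 0])
})
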