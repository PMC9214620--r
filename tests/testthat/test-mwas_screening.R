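test_that("a 2x2 fit reproduces the cross-product odds ratio of 6", {
  d <- expand_2x2(4, 6, 9, 81)      # OR = (4*81)/(6*9) = 6
  fit <- fit_logistic(d$y, cbind(1, exposure = d$ex))
  expect_equal(exp(fit$coefficients[["exposure"]]), 6, tolerance = 1e-8)
  # Wald SE for a 2x2 table has the closed form sqrt(sum of 1/cells)
  expect_equal(fit$se[["exposure"]], sqrt(1 / 4 + 1 / 6 + 1 / 9 + 1 / 81),
               tolerance = 1e-6)
})

test_that("exposure independent of a balanced outcome gives OR exactly 1", {
  d <- expand_2x2(5, 5, 20, 20)     # same outcome split in both groups
  fit <- fit_logistic(d$y, cbind(1, exposure = d$ex))
  expect_equal(fit$coefficients[["exposure"]], 0, tolerance = 1e-10)
})

test_that("complete separation is detected and flagged, not reported", {
  d <- expand_2x2(10, 0, 5, 100)    # every exposed delivery has MB
  fit <- fit_logistic(d$y, cbind(1, exposure = d$ex))
  expect_identical(fit$converged, 0L)
})

test_that("the fitter matches the GLM oracle on seeded datasets", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 400
    x1 <- rbinom(n, 1, 0.3)
    x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x1 - 0.4 * x2))
    ours <- fit_logistic(y, cbind(1, x1, x2))
    oracle <- glm(y ~ x1 + x2, family = binomial,
                  control = glm.control(epsilon = 1e-12))
    expect_equal(unname(ours$coefficients), unname(coef(oracle)),
                 tolerance = 1e-6)
    expect_equal(unname(ours$se),
                 unname(sqrt(diag(vcov(oracle)))), tolerance = 1e-6)
  }
})

test_that("non-binary outcomes and rank deficiency are handled", {
  expect_error(fit_logistic(c(0, 1, 2), cbind(1, 1:3)), "binary")
  # a column constant across deliveries is aliased with the intercept and
  # must not move the exposure estimate
  d <- expand_2x2(8, 12, 15, 65)
  base <- fit_logistic(d$y, cbind(1, exposure = d$ex))
  with_const <- fit_logistic(d$y, cbind(1, exposure = d$ex, const = 1))
  expect_false(with_const$estimable[3])
  expect_true(is.na(with_const$coefficients[["const"]]))
  expect_equal(with_const$coefficients[["exposure"]],
               base$coefficients[["exposure"]], tolerance = 1e-10)
})

make_screen_input <- function(n = 400, n_med = 4, seed = 1) {
  set.seed(seed)
  cohort <- data.frame(
    delivery_id = sprintf("d%04d", 1:n), patient_id = sprintf("p%04d", 1:n),
    delivery_date = "2015-01-01",
    maternal_age = round(rnorm(n, 30, 5), 1),
    mb = rbinom(n, 1, 0.2), art = rbinom(n, 1, 0.05),
    infertility = rbinom(n, 1, 0.02), stringsAsFactors = FALSE)
  m <- matrix(rbinom(n * n_med, 1, 0.2), n, n_med,
              dimnames = list(cohort$delivery_id,
                              sprintf("med_%03d", 1:n_med)))
  storage.mode(m) <- "integer"
  list(cohort = cohort, exposure = raw_exposure(m, cohort$patient_id))
}

test_that("run_mwas screens every medication against its own control group", {
  inp <- make_screen_input()
  sc <- run_mwas(inp$cohort, inp$exposure, model_spec("model3"))
  expect_s3_class(sc, "mwas_screen")
  expect_identical(sc$m, 4L)
  expect_identical(sc$results$medication_id, sort(colnames(inp$exposure$m)))
  expect_equal(sc$results$n_exposed, unname(colSums(inp$exposure$m)))
  # per-medication fit equals a direct GLM with the same design
  for (j in sc$results$medication_id) {
    g <- glm(inp$cohort$mb ~ inp$exposure$m[, j] + maternal_age + art +
               infertility, family = binomial, data = inp$cohort,
             control = glm.control(epsilon = 1e-12))
    row <- sc$results[sc$results$medication_id == j, ]
    expect_equal(row$beta, unname(coef(g)[2]), tolerance = 1e-6)
    expect_equal(row$ci_low, exp(unname(coef(g)[2]) -
                                   1.96 * sqrt(vcov(g)[2, 2])),
                 tolerance = 1e-6)
  }
  expect_equal(sc$results$p_bonf, pmin(1, sc$m * sc$results$p))
})

test_that("Bonferroni calls are always a subset of nominal calls", {
  for (seed in 1:10) {
    inp <- make_screen_input(n = 300, n_med = 6, seed = seed)
    res <- run_mwas(inp$cohort, inp$exposure, model_spec("model1"))$results
    expect_true(all(res$sig_nominal[res$sig_bonf == 1L] == 1L))
    expect_true(all(res$or_[res$converged == 1L] ==
                      exp(res$beta[res$converged == 1L])))
    ok <- res$converged == 1L
    expect_true(all(res$ci_low[ok] <= res$or_[ok] &
                      res$or_[ok] <= res$ci_high[ok]))
  }
})

test_that("a single-medication family leaves P unadjusted", {
  inp <- make_screen_input(n_med = 1)
  res <- run_mwas(inp$cohort, inp$exposure, model_spec("model1"))$results
  expect_identical(res$p_bonf, res$p)
})

test_that("a separated medication is flagged and does not abort the screen", {
  inp <- make_screen_input(n = 300, n_med = 3, seed = 2)
  # force complete separation for med_001: exposure iff MB
  inp$exposure$m[, "med_001"] <- inp$cohort$mb
  sc <- run_mwas(inp$cohort, inp$exposure, model_spec("model1"))
  res <- sc$results
  expect_identical(res$converged[res$medication_id == "med_001"], 0L)
  expect_true(is.na(res$or_[res$medication_id == "med_001"]))
  expect_identical(res$sig_nominal[res$medication_id == "med_001"], 0L)
  expect_true(all(res$converged[res$medication_id != "med_001"] == 1L))
})

test_that("forest export is long-format, per significant medication", {
  inp <- make_screen_input(n = 2000, n_med = 5, seed = 6)
  # plant a strong effect so at least one medication is significant
  set.seed(60)
  inp$cohort$mb <- rbinom(2000, 1,
                          plogis(-2 + 2 * inp$exposure$m[, "med_002"]))
  sc <- run_mwas(inp$cohort, inp$exposure, model_spec("model3"))
  fd <- export_forest(sc)
  expect_true("med_002" %in% fd$medication_id)
  per_med <- table(fd$medication_id)
  expect_true(all(per_med == 4))  # exposure + 3 model-3 covariates
  expect_setequal(unique(fd$term),
                  c("exposure", "maternal_age", "art", "infertility"))
  # all medications when not restricted to significant ones
  fd_all <- export_forest(sc, significant_only = FALSE)
  expect_setequal(unique(fd_all$medication_id),
                  sc$results$medication_id[sc$results$converged == 1L])
})

test_that("a screen with no significant medications exports an empty table", {
  inp <- make_screen_input(n = 200, n_med = 2, seed = 3)
  sc <- run_mwas(inp$cohort, inp$exposure, model_spec("model2"))
  sc$results$sig_nominal[] <- 0L
  expect_identical(nrow(export_forest(sc)), 0L)
})
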