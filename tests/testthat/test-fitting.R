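test_that("zero-noise synthetic data is interpolated exactly", {
  study <- gen_study(study_spec(n_complexes = 20, noise_sd = 0, seed = 5))
  ds <- bfe_dataset(study$delta, study$exp)
  f <- fit(ds, "spt")
  expect_equal(unname(f$coefficients["gamma"]), 0.1394, tolerance = 1e-8)
  expect_equal(unname(f$coefficients["p"]), 0.0163, tolerance = 1e-8)
  expect_equal(unname(f$coefficients["b"]), 0, tolerance = 1e-8)
  expect_equal(f$metrics_train$pearson_r, 1, tolerance = 1e-10)
})

test_that("pinned coefficients are held fixed", {
  study <- gen_study(study_spec(n_complexes = 30, noise_sd = 0.5, seed = 6))
  ds <- bfe_dataset(study$delta, study$exp)
  f <- fit(ds, "spt", fixed = c(b = 0))
  expect_identical(unname(f$coefficients["b"]), 0)
  expect_false("b" %in% names(f$se))
})

test_that("collinear design columns raise a singular-design error", {
  d <- rand_delta(12)
  d$dSAV <- d$dSASA            # perfectly collinear fixture
  exp <- data.frame(complex_id = d$complex_id, dG_exp = rnorm(12, -9, 2))
  ds <- bfe_dataset(d, exp)
  err <- expect_error(fit(ds, "spt"),
                      class = "mmpbsar_singular_design_error")
  expect_match(conditionMessage(err), "gamma|p")
})

test_that("the least-squares solution is a local SSE minimum", {
  study <- gen_study(study_spec(n_complexes = 30, noise_sd = 1, seed = 8))
  ds <- bfe_dataset(study$delta, study$exp)
  f <- fit(ds, "spt")
  sse_of <- function(cf) {
    pred <- score(ds$delta, model_spec("spt", cf))$dG_pred
    sum((pred - ds$dG_exp)^2)
  }
  base <- sse_of(f$coefficients)
  expect_equal(base, f$sse, tolerance = 1e-8)
  for (k in names(f$coefficients)) {
    for (dlt in c(-1e-4, 1e-4)) {
      cf <- f$coefficients; cf[k] <- cf[k] + dlt
      expect_gte(sse_of(cf), base - 1e-10)
    }
  }
})

test_that("refitting with the returned coefficients reproduces the metrics", {
  study <- gen_study(study_spec(n_complexes = 25, noise_sd = 1, seed = 9))
  ds <- bfe_dataset(study$delta, study$exp)
  f <- fit(ds, "spt")
  pred <- score(ds$delta, f$model)$dG_pred
  m <- metrics_report(pred, ds$dG_exp)
  expect_equal(m$pearson_r, f$metrics_train$pearson_r, tolerance = 1e-10)
  expect_equal(m$MUE, f$metrics_train$MUE, tolerance = 1e-10)
})

test_that("held-out split yields a test metrics report", {
  study <- gen_study(study_spec(n_complexes = 30, noise_sd = 1, seed = 10))
  split <- data.frame(complex_id = study$delta$complex_id,
                      split = rep(c("train", "test"), c(20, 10)))
  ds <- bfe_dataset(study$delta, study$exp, split = split)
  f <- fit(ds, "spt")
  expect_equal(f$n_train, 20)
  expect_s3_class(f$metrics_test, "metrics_report")
})

test_that("a two-valued scan recovers the generating dielectric pair", {
  spec <- study_spec(n_complexes = 40, noise_sd = 0,
                     pair = dielectric_pair(1, 4), seed = 11)
  study <- gen_study(spec)
  ds <- bfe_dataset(study$delta, study$exp)
  model <- model_spec(spec$regime, spec$coefficients)
  scan2 <- scan_dielectrics(ds, model, grid = 1:10, two_valued = TRUE)
  expect_equal(scan2$best_pair$eps_ele, 1)
  expect_equal(scan2$best_pair$eps_pb, 4)
  expect_equal(scan2$table$pearson_r[scan2$best], 1, tolerance = 1e-10)
  # the diagonal-constrained scan cannot reach R = 1 on two-valued truth
  scan1 <- scan_dielectrics(ds, model, grid = 1:10, two_valued = FALSE)
  expect_lt(max(scan1$table$pearson_r), 1 - 1e-6)
  expect_lt(max(scan1$table$pearson_r), scan2$table$pearson_r[scan2$best])
})

test_that("restricting the two-valued grid to its diagonal is the single-valued scan", {
  study <- gen_study(study_spec(n_complexes = 20, noise_sd = 1, seed = 12))
  ds <- bfe_dataset(study$delta, study$exp)
  model <- model_spec("spt", c(gamma = 0.1394, p = 0.0163, b = 0))
  two <- scan_dielectrics(ds, model, grid = c(1, 2, 4), two_valued = TRUE)
  one <- scan_dielectrics(ds, model, grid = c(1, 2, 4), two_valued = FALSE)
  diag_rows <- two$table[two$table$eps_ele == two$table$eps_pb, ]
  rownames(diag_rows) <- NULL
  expect_equal(diag_rows, one$table)
})

test_that("a single-point scan reproduces score + metrics computed manually", {
  study <- gen_study(study_spec(n_complexes = 15, noise_sd = 1, seed = 13))
  ds <- bfe_dataset(study$delta, study$exp)
  model <- model_spec("spt", c(gamma = 0.1394, p = 0.0163, b = 0))
  sc <- scan_dielectrics(ds, model, grid = 2.1, two_valued = FALSE)
  pred <- score(ds$delta, model, dielectric_pair(2.1, 2.1))$dG_pred
  m <- metrics_report(pred, ds$dG_exp)
  expect_equal(sc$table$pearson_r, m$pearson_r, tolerance = 1e-12)
  expect_equal(sc$table$PI, m$PI, tolerance = 1e-12)
  expect_equal(sc$table$MUEsc, m$MUEsc, tolerance = 1e-12)
})

test_that("scan input validation", {
  study <- gen_study(study_spec(n_complexes = 10, seed = 14))
  ds <- bfe_dataset(study$delta, study$exp)
  model <- model_spec("spt", c(gamma = 0.1, p = 0.01, b = 0))
  expect_error(scan_dielectrics(ds, model, grid = numeric(0)),
               class = "mmpbsar_config_error")
  expect_error(scan_dielectrics(ds, model, grid = c(0.5, 2)),
               class = "mmpbsar_domain_error")
})

test_that("pearson objective never does worse than the SSE fit on correlation", {
  study <- gen_study(study_spec(n_complexes = 30, noise_sd = 2, seed = 15))
  ds <- bfe_dataset(study$delta, study$exp)
  f_sse <- fit(ds, "spt", objective = "sse")
  f_cor <- fit(ds, "spt", objective = "pearson")
  expect_gte(f_cor$metrics_train$pearson_r,
             f_sse$metrics_train$pearson_r - 1e-9)
})
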