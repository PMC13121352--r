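test_that("agreement metrics match hand-computed values", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(crm(c(2, 2), c(1, 1)), 0.5)
  expect_equal(crm(c(1, 2), c(1, 2)), 0)
  expect_lt(crm(c(1, 2), c(2, 3)), 0)  # over-prediction -> negative
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_equal(willmott_d(c(1, 2, 4), c(1, 2, 4)), 1)
  expect_equal(willmott_d(c(0, 2), c(2, 0)), 0)
})

test_that("metric edge cases raise typed errors", {
  expect_error(rmse(1:3, 1:4), class = "rootstress_invalid_input")
  expect_error(crm(c(-1, 1), c(0, 0)), class = "rootstress_undefined_metric")
  expect_error(pearson_r(c(1, 1), c(1, 2)), class = "rootstress_undefined_metric")
  expect_error(willmott_d(c(1, 1), c(1, 1)), class = "rootstress_undefined_metric")
})

test_that("metric invariances hold on random data", {
  set.seed(31)
  for (i in 1:5) {
    o <- rnorm(20); p <- rnorm(20)
    idx <- sample(20)
    expect_equal(rmse(o[idx], p[idx]), rmse(o, p))
    expect_equal(rmse(o + 5, p + 5), rmse(o, p))
    expect_false(isTRUE(all.equal(crm(o + 5, p + 5), crm(o, p))))
    expect_equal(pearson_r(2 * o + 3, p), pearson_r(o, p))
    expect_lte(willmott_d(o, p), 1)
    expect_gte(pearson_r(o, p), -1)
    expect_lte(pearson_r(o, p), 1)
  }
})

test_that("stratified split is exhaustive, proportional and seed-stable", {
  tab <- data.frame(id = 1:110,
                    matric_potential = rep(c(-10, -60, -100, -1000, -5000), 22))
  sp <- split_fit_validate(tab, 0.7, seed = 42)
  expect_equal(nrow(sp$fit), 77)
  expect_equal(nrow(sp$validation), 33)
  expect_equal(sort(c(sp$fit$id, sp$validation$id)), 1:110)
  # per-stratum counts within one sample of 0.7 * 22
  per <- table(sp$fit$matric_potential)
  expect_true(all(abs(per - 0.7 * 22) <= 1))
  sp2 <- split_fit_validate(tab, 0.7, seed = 42)
  expect_identical(sp$fit$id, sp2$fit$id)
  sp3 <- split_fit_validate(tab, 0.7, seed = 43)
  expect_false(identical(sp$fit$id, sp3$fit$id))
})

test_that("tiny strata fall back to the fit set with a warning", {
  tab <- data.frame(id = 1:11, matric_potential = c(rep(-10, 10), -60))
  expect_warning(sp <- split_fit_validate(tab, 0.7, seed = 1), "fewer than 2")
  expect_true(11 %in% sp$fit$id)
})

test_that("evaluate_model reports exact agreement and flags undefined metrics", {
  truth <- reference_surface_params("Field")
  val <- make_surface_grid(truth, s = seq(55, 90, length.out = 5),
                           qp = seq(0.5, 4, length.out = 5))
  rep_exact <- evaluate_model(truth, val)
  expect_equal(rep_exact$rmse, 0)
  expect_equal(rep_exact$crm, 0)
  expect_equal(rep_exact$r, 1)
  expect_equal(rep_exact$d, 1)
  expect_length(rep_exact$flags, 0)
  # constant observations: r undefined, flagged not zeroed
  val2 <- val; val2$re <- 0.5
  rep_flag <- evaluate_model(truth, val2)
  expect_true(is.na(rep_flag$r))
  expect_match(paste(rep_flag$flags, collapse = " "), "r:")
})

test_that("validation RMSE of a true model estimates the noise level", {
  truth <- reference_surface_params("Field")
  set.seed(77)
  val <- make_surface_grid(truth, s = runif(300, 50, 95),
                           qp = seq(0.5, 4, length.out = 4))
  val$re <- val$re + rnorm(nrow(val), 0, 0.1)
  rep <- evaluate_model(truth, val)
  expect_equal(rep$rmse, 0.1, tolerance = 0.15)
})
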