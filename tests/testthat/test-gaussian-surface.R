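test_that("surface evaluation peaks at the optimum and matches hand values", {
  p <- gaussian_surface_params(a = 1.7, b = 30, c = 5, x0 = 55, y0 = -2)
  expect_equal(relative_elongation(p, qp = -2, s = 55), 1.7)
  # one exp() by hand
  expect_equal(relative_elongation(p, qp = 0, s = 70),
               1.7 * exp(-0.5 * ((15 / 30)^2 + (2 / 5)^2)))
  expect_error(relative_elongation(p, Inf, 60), class = "rootstress_invalid_input")
})

test_that("surface is radially monotone and separable", {
  set.seed(5)
  for (i in 1:10) {
    p <- gaussian_surface_params(a = runif(1, 0.5, 5), b = runif(1, 10, 60),
                                 c = runif(1, 2, 12), x0 = runif(1, 20, 80),
                                 y0 = runif(1, -30, 2))
    s_up <- p$x0 + seq(0, 50, by = 5)
    expect_true(all(diff(relative_elongation(p, 1, s_up)) < 0))
    qp_up <- p$y0 + seq(0, 10, by = 1)
    expect_true(all(diff(relative_elongation(p, qp_up, 60)) < 0))
    # separability: Re = a * g(s) * h(qp) with unit-peak factors
    qp <- runif(1, 0, 5); s <- runif(1, 40, 95)
    g <- relative_elongation(p, p$y0, s) / p$a
    h <- relative_elongation(p, qp, p$x0) / p$a
    expect_equal(relative_elongation(p, qp, s), p$a * g * h, tolerance = 1e-12)
  }
})

test_that("normalisation divides by the group maximum or a reference", {
  expect_equal(normalize_elongation(c(2, 4)), c(0.5, 1))
  expect_equal(round(normalize_elongation(3.33, reference = 4.8261), 2), 0.69)
  expect_error(normalize_elongation(numeric(0)), class = "rootstress_invalid_input")
  expect_error(normalize_elongation(c(0, 0)), class = "rootstress_degenerate_design")
})

test_that("noise-free fit recovers the Field surface parameters", {
  truth <- reference_surface_params("Field")
  obs <- make_surface_grid(truth)
  fit <- fit_gaussian_surface(obs, n_starts = 30, seed = 3)
  est <- c(fit$a, fit$b, fit$c, fit$x0, fit$y0)
  tru <- c(truth$a, truth$b, truth$c, truth$x0, truth$y0)
  expect_lt(max(rel_err(est, tru)), 1e-4)
})

test_that("weakly identified amplitudes still recover the predicted surface", {
  truth <- reference_surface_params("Packed")
  obs <- make_surface_grid(truth)
  fit <- fit_gaussian_surface(obs, n_starts = 30, seed = 3)
  expect_lt(max(abs(relative_elongation(fit, obs$qp, obs$s) - obs$re)), 1e-3)
})

test_that("refitting on a fit's own predictions is idempotent", {
  truth <- reference_surface_params("Field")
  obs <- make_surface_grid(truth, s = seq(55, 95, length.out = 6),
                           qp = seq(0.3, 4, length.out = 6))
  set.seed(9)
  obs$re <- pmax(obs$re + rnorm(nrow(obs), 0, 0.05), 0)
  f1 <- fit_gaussian_surface(obs, n_starts = 25, seed = 4)
  obs2 <- obs
  obs2$re <- relative_elongation(f1, obs2$qp, obs2$s)
  f2 <- fit_gaussian_surface(obs2, init = c(f1$a, f1$b, f1$c, f1$x0, f1$y0))
  expect_lt(max(abs(relative_elongation(f2, obs$qp, obs$s) -
                    relative_elongation(f1, obs$qp, obs$s))), 1e-6)
})

test_that("degenerate spans are rejected", {
  truth <- reference_surface_params("Field")
  obs <- make_surface_grid(truth, s = 60)
  expect_error(fit_gaussian_surface(obs), class = "rootstress_degenerate_design")
  expect_error(fit_gaussian_surface(make_surface_grid(truth)[1:5, ]),
               class = "rootstress_degenerate_design")
})

test_that("stress reductions preserve sign and vanish for equal endpoints", {
  fld <- reference_surface_params("Field")
  expect_equal(stress_reduction(fld, "s", 60, 2, 2), 0)
  # moving toward the optimum increases elongation -> negative reduction
  expect_lt(stress_reduction(fld, "s", 60, 3, 1), 0)
  expect_error(stress_reduction(fld, "s", 60, 1e6, 1),
               class = "rootstress_degenerate_design")
})

test_that("structure contrast reports ratios and flags supra-unity nodes", {
  fld <- reference_surface_params("Field")
  pkd <- reference_surface_params("Packed")
  same <- compare_structures(fld, fld)
  expect_true(all(same$grid$ratio == 1))
  expect_equal(same$mean_pct_diff, 0)
  cmp <- compare_structures(fld, pkd, steps = c(36, 41))
  node <- cmp$grid[cmp$grid$qp == 4 & cmp$grid$s == 90, ]
  expect_equal(node$ratio, 3.034, tolerance = 1e-3)
  low <- relative_elongation(fld, 0.3, 60) / relative_elongation(pkd, 0.3, 60)
  expect_lt(low, 1)
  expect_error(compare_structures(fld, pkd, steps = c(0, 0)),
               class = "rootstress_invalid_input")
})
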