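test_that("retention curve is bounded, saturates at psi = 0 and dries monotonically", {
  p <- retention_params()
  expect_equal(retention_theta(p, 0), p$theta_s)
  th <- retention_theta(p, c(-10, -100, -1000, -1e7))
  expect_true(all(diff(th) < 0))
  expect_true(all(th > p$theta_r & th < p$theta_s))
  expect_lt(retention_theta(p, -1e7) - p$theta_r, 0.02)
  expect_error(retention_theta(p, 10), class = "rootstress_invalid_input")
})

test_that("generator reproduces the experimental design", {
  cfg <- synthetic_config(seed = 7)
  tab <- generate_experiment(cfg)
  expect_equal(nrow(tab), 200)
  expect_equal(sum(tab$structure == "Field"), 110)
  expect_equal(sum(tab$structure == "Packed"), 90)
  counts <- table(tab$structure, tab$matric_potential)
  expect_true(all(counts["Field", ] == 22))
  expect_true(all(counts["Packed", ] == 18))
  expect_setequal(unique(tab$bulk_density[tab$structure == "Packed"]),
                  c(1.02, 1.10, 1.18, 1.26, 1.34, 1.42))
  fb <- tab$bulk_density[tab$structure == "Field"]
  expect_true(all(fb >= 1.00 & fb <= 1.45))
})

test_that("generator is reproducible and physically consistent", {
  cfg <- synthetic_config(seed = 12)
  t1 <- generate_experiment(cfg)
  t2 <- generate_experiment(cfg)
  expect_identical(t1, t2)
  expect_true(all(t1$saturation_pct <= 100 + 1e-9))
  expect_true(all(t1$theta_v <= t1$total_porosity + 1e-12))
  expect_true(all(t1$re >= 0))
  # resistance rises with bulk density at fixed potential (Packed levels)
  pk <- t1[t1$structure == "Packed" & t1$matric_potential == -1000, ]
  agg <- tapply(pk$qp_true, pk$bulk_density, mean)
  expect_true(all(diff(agg[order(as.numeric(names(agg)))]) > 0))
})

test_that("noise-free tables close exactly on the truth surface", {
  cfg <- synthetic_config(noise_re_sd = 0, noise_qp_sd = 0, seed = 3)
  tab <- generate_experiment(cfg)
  expect_equal(tab$re, tab$re_true)
  expect_equal(tab$measured_qp, tab$qp_true)
  for (str in c("Field", "Packed")) {
    sub <- tab[tab$structure == str, ]
    expect_equal(sub$re, relative_elongation(cfg$truth_surface[[str]],
                                             sub$qp_true, sub$saturation_pct))
  }
})

test_that("generated stress cloud covers the studied window", {
  tab <- generate_experiment(synthetic_config(seed = 19))
  expect_lte(min(tab$qp_true), 0.5)
  expect_gte(max(tab$qp_true), 4)
  expect_lte(min(tab$saturation_pct), 60)
  expect_gte(max(tab$saturation_pct), 90)
})

test_that("recovery experiment validates inputs and closes noise-free", {
  expect_error(recovery_experiment(synthetic_config(), 0),
               class = "rootstress_invalid_input")
  cfg <- synthetic_config(noise_re_sd = 0, noise_qp_sd = 0, seed = 5)
  rec <- recovery_experiment(cfg, n_reps = 1)
  expect_equal(nrow(rec$reps), 2)
  expect_true(all(rec$reps$max_dre <= 1e-3))
  expect_true(all(rec$reps$val_rmse <= 1e-4))
})

test_that("missing truth parameters raise a config error", {
  expect_error(synthetic_config(truth_surface = list(Field = NULL)),
               class = "rootstress_config_error")
})
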