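test_that("total porosity follows the saturation-mass definition", {
  expect_equal(total_porosity(500, 350, 298.6), 150 / 298.6)
  expect_equal(total_porosity(300, 300, 298.6), 0)
  expect_error(total_porosity(349, 350, 298.6), class = "rootstress_invalid_input")
  expect_error(total_porosity(500, 350, 0), class = "rootstress_invalid_input")
  expect_error(total_porosity(500, 0, 298.6), class = "rootstress_invalid_input")
})

test_that("particle-density porosity route matches 1 - BD/PD", {
  expect_equal(total_porosity_from_density(1.02, 2.96), 1 - 1.02 / 2.96)
  expect_equal(round(total_porosity_from_density(1.02), 4), 0.6554)
  expect_error(total_porosity_from_density(3.0, 2.96),
               class = "rootstress_invalid_input")
})

test_that("volumetric water content is w * BD", {
  expect_equal(volumetric_water_content(0, 1.10), 0)
  expect_equal(volumetric_water_content(0.30, 1.00), 0.30)
  expect_equal(volumetric_water_content(0.30, 1.26), 0.378)
  expect_error(volumetric_water_content(-0.1, 1),
               class = "rootstress_invalid_input")
})

test_that("saturation degree is the theta/porosity percentage", {
  expect_equal(degree_of_saturation(0.60, 0.60), 100)
  expect_equal(degree_of_saturation(0, 0.60), 0)
  expect_equal(degree_of_saturation(0.39, 0.65), 60)
  expect_error(degree_of_saturation(0.3, 0), class = "rootstress_invalid_input")
})

test_that("saturation degree is scale-invariant and compactness linear in BD", {
  s <- degree_of_saturation(0.31, 0.58)
  expect_equal(degree_of_saturation(0.31 * 3.7, 0.58 * 3.7), s)
  k <- runif(1, 0.5, 2)
  expect_equal(degree_of_compactness(1.10 * k), degree_of_compactness(1.10) * k)
})

test_that("elongation rate converts 87-hour lengths to cm per day", {
  expect_equal(elongation_rate(0), 0)
  expect_equal(elongation_rate(14.5), 4)
  expect_equal(elongation_rate(c(10.875, 10.875)), 3)
  expect_error(elongation_rate(numeric(0)), class = "rootstress_invalid_input")
  expect_error(elongation_rate(10, 0), class = "rootstress_invalid_input")
})

test_that("derived state closes (air porosity + theta = total porosity) and flags wet rows", {
  tab <- data.frame(bulk_density = c(1.02, 1.26, 1.42),
                    gravimetric_wc = c(0.30, 0.25, 0.40))
  out <- derive_soil_state(tab)
  expect_equal(out$air_porosity + out$theta_v, out$total_porosity)
  expect_equal(out$porosity_route, rep("particle_density", 3))
  # BD 1.42: TP = 0.520, theta = 0.568 > TP + 0.02 -> flagged
  expect_equal(out$saturation_flag, c(FALSE, FALSE, TRUE))
  expect_gt(out$saturation_pct[3], 100)
})

test_that("mass-route and density-route saturation agree on consistent data", {
  bd <- c(1.02, 1.18, 1.34); pd <- 2.96; vol <- 298.6
  tp <- 1 - bd / pd
  w <- c(0.30, 0.28, 0.22)
  dry <- bd * vol  # g, density 1 Mg m^-3 = 1 g cm^-3
  tab <- data.frame(bulk_density = bd, gravimetric_wc = w,
                    saturated_mass = dry + tp * vol, dry_mass = dry,
                    volume = vol)
  mass <- derive_soil_state(tab)
  dens <- derive_soil_state(tab[, c("bulk_density", "gravimetric_wc")])
  expect_equal(mass$porosity_route[1], "mass")
  expect_equal(mass$saturation_pct, dens$saturation_pct, tolerance = 1e-10)
})
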