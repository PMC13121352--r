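#' Water-retention parameters (van Genuchten)
#'
#' Parameter set mapping matric potential to volumetric water content,
#' `theta(psi) = theta_r + (theta_s - theta_r) / (1 + (alpha*|psi|)^n)^(1-1/n)`.
#' The experiment tables this package emulates were equilibrated at set
#' matric potentials but no retention curve accompanies them, so the
#' generator uses a synthetic curve with defaults plausible for a very
#' clayey Oxisol; all four parameters are exposed.
#'
#' @param theta_r Residual water content (m^3 m^-3).
#' @param theta_s Saturated water content (m^3 m^-3).
#' @param alpha Inverse air-entry scale (hPa^-1).
#' @param n_shape Shape parameter, > 1.
#' @return An object of class `retention_params`.
#' @export
retention_params <- function(theta_r = 0.25, theta_s = 0.65, alpha = 0.02,
                             n_shape = 1.25) {
  stopifnot(theta_r >= 0, theta_r < theta_s, theta_s <= 1, alpha > 0,
            n_shape > 1)
  structure(list(theta_r = theta_r, theta_s = theta_s, alpha = alpha,
                 n_shape = n_shape),
            class = "retention_params")
}

#' Volumetric water content from matric potential
#'
#' Evaluates the van Genuchten retention curve; monotone non-increasing in
#' suction `|psi|`, equal to `theta_s` at saturation (`psi = 0`) and tending
#' to `theta_r` as the soil dries.
#'
#' @param params A [retention_params()] object.
#' @param matric_potential Matric potential in hPa, `<= 0`.
#' @param theta_s_cap Optional per-sample cap on `theta_s` (m^3 m^-3), used
#'   by the generator to keep water content below total porosity at high
#'   bulk density.
#' @return Volumetric water content (m^3 m^-3), vectorised.
#' @export
retention_theta <- function(params, matric_potential, theta_s_cap = NULL) {
  stopifnot(inherits(params, "retention_params"))
  check_finite(matric_potential, "matric_potential")
  if (any(matric_potential > 0))
    stop_invalid("`matric_potential` must be <= 0 (suction)")
  ts <- if (is.null(theta_s_cap)) params$theta_s
        else pmin(params$theta_s, theta_s_cap)
  tr <- pmin(params$theta_r, ts)
  m <- 1 - 1 / params$n_shape
  tr + (ts - tr) / (1 + (params$alpha * abs(matric_potential))^params$n_shape)^m
}

#' Synthetic experiment configuration
#'
#' Defines the study conditions the generator reproduces: two structures,
#' six packed bulk-density levels, five matric potentials, 22 Field and 18
#' Packed columns per potential (110 + 90 = 200 samples), true Busscher and
#' surface parameters per structure, and additive noise on measured
#' resistance and relative elongation.
#'
#' @param structures Character subset of `c("Field", "Packed")`.
#' @param packed_bd_levels Packed bulk-density levels (Mg m^-3).
#' @param field_bd Field bulk-density distribution: list with `mean`, `sd`,
#'   `bounds` for a truncated-normal draw.
#' @param potentials Matric potentials (hPa, negative).
#' @param field_reps,packed_reps Columns per potential for each structure.
#' @param truth_busscher,truth_surface Named lists (`Field`, `Packed`) of
#'   true parameter objects; defaults are the reference parameter sets.
#' @param retention A [retention_params()] object (shared by both
#'   structures; per-structure retention offsets default to zero).
#' @param noise_re_sd Additive Gaussian noise SD on relative elongation
#'   (truncated at 0).
#' @param noise_qp_sd Additive Gaussian noise SD on measured resistance
#'   (MPa; floored at 0.01 MPa, an instrument-resolution limit).
#' @param reference_rate Reference elongation rate (cm d^-1) converting
#'   relative elongation to a rate; 4.83 is implied by paired rate/relative
#'   values in the reference dataset (inferred, not measured).
#' @param particle_density,proctor_max_bd,growth_duration Soil constants.
#' @param seed Integer seed; every random draw in the generator flows
#'   through it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(structures = c("Field", "Packed"),
                             packed_bd_levels = c(1.02, 1.10, 1.18, 1.26, 1.34, 1.42),
                             field_bd = list(mean = 1.18, sd = 0.10,
                                             bounds = c(1.00, 1.45)),
                             potentials = c(-10, -60, -100, -1000, -5000),
                             field_reps = 22, packed_reps = 18,
                             truth_busscher = list(
                               Field = reference_busscher_params("Field"),
                               Packed = reference_busscher_params("Packed")),
                             truth_surface = list(
                               Field = reference_surface_params("Field"),
                               Packed = reference_surface_params("Packed")),
                             retention = retention_params(),
                             noise_re_sd = 0.05, noise_qp_sd = 0.1,
                             reference_rate = 4.83,
                             particle_density = 2.96, proctor_max_bd = 1.53,
                             growth_duration = 87, seed = 1) {
  structures <- match.arg(structures, several.ok = TRUE)
  stopifnot(field_reps >= 1, packed_reps >= 1, noise_re_sd >= 0,
            noise_qp_sd >= 0, reference_rate > 0, length(potentials) >= 1,
            all(potentials <= 0), is.numeric(seed))
  for (s in structures) {
    if (is.null(truth_busscher[[s]]) || is.null(truth_surface[[s]]))
      stop(errorCondition(
        paste0("truth parameters missing for structure '", s, "'"),
        class = c("rootstress_config_error", "error")))
  }
  structure(list(structures = structures, packed_bd_levels = packed_bd_levels,
                 field_bd = field_bd, potentials = potentials,
                 field_reps = field_reps, packed_reps = packed_reps,
                 truth_busscher = truth_busscher, truth_surface = truth_surface,
                 retention = retention, noise_re_sd = noise_re_sd,
                 noise_qp_sd = noise_qp_sd, reference_rate = reference_rate,
                 particle_density = particle_density,
                 proctor_max_bd = proctor_max_bd,
                 growth_duration = growth_duration, seed = seed),
            class = "synthetic_config")
}

rtruncnorm1 <- function(n, mean, sd, bounds) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2 * n, mean, sd)
    out <- c(out, draw[draw >= bounds[1] & draw <= bounds[2]])
  }
  out[seq_len(n)]
}

#' Generate a synthetic root-elongation experiment
#'
#' Produces one row per soil column following the emulated design: Packed
#' columns cycle the configured bulk-density levels within each matric
#' potential; Field columns draw bulk density from a truncated normal.
#' Water content comes from the retention curve with the per-row saturated
#' content capped at total porosity (so saturation degree never exceeds
#' 100 %); resistance from the true Busscher model plus measurement noise;
#' relative elongation from the true surface, evaluated at the row's own
#' true resistance and saturation, plus noise truncated at zero.
#'
#' @param config A [synthetic_config()] object.
#' @return Data frame with one row per sample: identifiers, physical state,
#'   true and measured resistance, true and noisy relative elongation, and
#'   the implied elongation rate and root length.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    rows <- lapply(config$structures, function(str) {
      reps <- if (str == "Field") config$field_reps else config$packed_reps
      per_pot <- lapply(config$potentials, function(psi) {
        bd <- if (str == "Field") {
          rtruncnorm1(reps, config$field_bd$mean, config$field_bd$sd,
                      config$field_bd$bounds)
        } else {
          rep_len(rep(config$packed_bd_levels,
                      each = ceiling(reps / length(config$packed_bd_levels))),
                  reps)
        }
        data.frame(structure = str, matric_potential = psi, bulk_density = bd)
      })
      do.call(rbind, per_pot)
    })
    tab <- do.call(rbind, rows)
    tab$sample_id <- sprintf("%s%03d", substr(tab$structure, 1, 1),
                             stats::ave(seq_len(nrow(tab)), tab$structure,
                                        FUN = seq_along))
    tp <- total_porosity_from_density(tab$bulk_density, config$particle_density)
    theta <- retention_theta(config$retention, tab$matric_potential,
                             theta_s_cap = tp)
    tab$total_porosity <- tp
    tab$theta_v <- theta
    tab$gravimetric_wc <- theta / tab$bulk_density
    tab$saturation_pct <- degree_of_saturation(theta, tp)
    tab$compactness_pct <- degree_of_compactness(tab$bulk_density,
                                                 config$proctor_max_bd)
    qp_true <- re_true <- numeric(nrow(tab))
    for (str in config$structures) {
      i <- tab$structure == str
      qp_true[i] <- predict_qp(config$truth_busscher[[str]],
                               tab$bulk_density[i], tab$gravimetric_wc[i])
      re_true[i] <- relative_elongation(config$truth_surface[[str]],
                                        qp_true[i], tab$saturation_pct[i])
    }
    tab$qp_true <- qp_true
    tab$measured_qp <- pmax(qp_true + rnorm(nrow(tab), 0, config$noise_qp_sd),
                            0.01)
    tab$re <- pmax(re_true + rnorm(nrow(tab), 0, config$noise_re_sd), 0)
    tab$re_true <- re_true
    tab$rate_cm_d <- tab$re * config$reference_rate
    tab$root_length <- tab$rate_cm_d * config$growth_duration / 24
    tab$growth_duration <- config$growth_duration
    rownames(tab) <- NULL
    tab[, c("sample_id", "structure", "matric_potential", "bulk_density",
            "gravimetric_wc", "theta_v", "total_porosity", "saturation_pct",
            "compactness_pct", "qp_true", "measured_qp", "re_true", "re",
            "rate_cm_d", "root_length", "growth_duration")]
  })
}

# Fit both models for one structure of a generated table and evaluate the
# surface on the held-out set. Internal workhorse for recovery_experiment()
# and run_pipeline().
fit_structure <- function(tab, str, fit_fraction = 0.7, n_starts = 20,
                          seed = 1) {
  sub <- tab[tab$structure == str, , drop = FALSE]
  parts <- split_fit_validate(sub, fit_fraction, "matric_potential", seed)
  bus_in <- function(d) data.frame(bulk_density = d$bulk_density,
                                   water_content = d$gravimetric_wc,
                                   measured_qp = d$measured_qp)
  bus <- fit_busscher(bus_in(parts$fit), structure = str)
  surf_in <- function(d) data.frame(
    re = d$re, s = d$saturation_pct,
    qp = predict_qp(bus, d$bulk_density, d$gravimetric_wc))
  surf <- fit_gaussian_surface(surf_in(parts$fit), n_starts = n_starts,
                               seed = seed, structure = str)
  list(structure = str, split = parts, busscher = bus, surface = surf,
       busscher_eval = evaluate_model(bus, bus_in(parts$validation)),
       surface_eval = evaluate_model(surf, surf_in(parts$validation)))
}

#' Parameter-recovery experiment
#'
#' Runs the full pipeline closure `generate -> split 70/30 -> fit Busscher
#' and surface -> evaluate` for `n_reps` independently seeded replicates,
#' and reports, per replicate and structure, the fitted parameters, their
#' deviation from truth, the validation metrics, and the maximum absolute
#' deviation between fitted and true surfaces over the replicate's own
#' (Qp, S) data hull (the robust recovery measure when the amplitude is
#' weakly identified).
#'
#' @param config A [synthetic_config()] object; replicate `k` uses seed
#'   `config$seed + k`.
#' @param n_reps Number of replicates, >= 1.
#' @param n_starts Multi-start count for the surface fits.
#' @return List with `reps` (data frame, one row per replicate x structure)
#'   and `summary` (per-structure means of validation RMSE and surface
#'   deviation).
#' @export
recovery_experiment <- function(config, n_reps, n_starts = 20) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.numeric(n_reps) || n_reps < 1) stop_invalid("`n_reps` must be >= 1")
  rows <- list()
  for (k in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + k
    tab <- generate_experiment(cfg)
    for (str in cfg$structures) {
      fs <- fit_structure(tab, str, seed = cfg$seed, n_starts = n_starts)
      truth <- cfg$truth_surface[[str]]
      sub <- tab[tab$structure == str, ]
      dre <- max(abs(
        relative_elongation(fs$surface, sub$qp_true, sub$saturation_pct) -
        relative_elongation(truth, sub$qp_true, sub$saturation_pct)))
      se <- fs$surface$se
      rows[[length(rows) + 1]] <- data.frame(
        rep = k, structure = str,
        a = fs$surface$a, b = fs$surface$b, c = fs$surface$c,
        x0 = fs$surface$x0, y0 = fs$surface$y0,
        bias_x0 = fs$surface$x0 - truth$x0,
        bias_y0 = fs$surface$y0 - truth$y0,
        se_x0 = if (!is.null(se)) se[["x0"]] else NA_real_,
        se_y0 = if (!is.null(se)) se[["y0"]] else NA_real_,
        val_rmse = fs$surface_eval$rmse, val_crm = fs$surface_eval$crm,
        val_r = fs$surface_eval$r, val_d = fs$surface_eval$d,
        max_dre = dre)
    }
  }
  reps <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(reps, reps$structure), function(d) {
    data.frame(structure = d$structure[1],
               mean_val_rmse = mean(d$val_rmse),
               mean_max_dre = mean(d$max_dre),
               mean_bias_x0 = mean(d$bias_x0),
               mean_bias_y0 = mean(d$bias_y0))
  }))
  rownames(summary) <- NULL
  list(reps = reps, summary = summary)
}
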