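#' Pipeline configuration
#'
#' Bundles the constants, column mapping, solver settings and reporting
#' conventions shared by every pipeline stage.
#'
#' @param columns Named mapping canonical column name -> input CSV column
#'   name (see [read_samples_csv()]); `NULL` when the input already uses
#'   canonical names.
#' @param particle_density,proctor_max_bd,growth_duration Soil constants
#'   (Mg m^-3, Mg m^-3, hours).
#' @param fit_fraction Fraction of samples used for fitting (remainder for
#'   validation).
#' @param n_starts Multi-start count for surface fits.
#' @param seed Integer seed driving every stochastic stage.
#' @param theta_tolerance Saturation-excess tolerance (m^3 m^-3) passed to
#'   [derive_soil_state()].
#' @param clamp Clamp surface predictions to `[0, 1]`?
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(columns = NULL, particle_density = 2.96,
                            proctor_max_bd = 1.53, growth_duration = 87,
                            fit_fraction = 0.7, n_starts = 20, seed = 1,
                            theta_tolerance = 0.02, clamp = FALSE) {
  stopifnot(particle_density > 0, proctor_max_bd > 0, growth_duration > 0,
            fit_fraction > 0, fit_fraction < 1, n_starts >= 1,
            is.numeric(seed))
  structure(list(columns = columns, particle_density = particle_density,
                 proctor_max_bd = proctor_max_bd,
                 growth_duration = growth_duration,
                 fit_fraction = fit_fraction, n_starts = n_starts,
                 seed = seed, theta_tolerance = theta_tolerance,
                 clamp = clamp),
            class = "pipeline_config")
}

#' Run the full elongation-modelling pipeline
#'
#' Chains every stage end to end: read (or simulate) the sample table,
#' derive the soil physical state, split fit/validation stratified by
#' matric potential, fit the Busscher model and the Gaussian elongation
#' surface per structure, evaluate both on the held-out set, and contrast
#' the structures over the studied stress window. When `out_dir` is given,
#' the bundle is written out (derived-state CSV, per-structure parameter
#' JSONs, evaluation JSONs, contrast CSV and a run log recording the seed,
#' package version and configuration hash); rerunning with the same config
#' and input reproduces the bundle exactly.
#'
#' @param config A [pipeline_config()] object.
#' @param input Path to a samples CSV, an in-memory sample data frame, or a
#'   [synthetic_config()] to simulate from.
#' @param out_dir Optional output directory.
#' @return List with `samples` (derived state joined), per-structure `fits`
#'   (each holding `busscher`, `surface`, `busscher_eval`, `surface_eval`
#'   and the split), and `contrast` when both structures are present.
#' @export
run_pipeline <- function(config = pipeline_config(), input, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  tab <- if (inherits(input, "synthetic_config")) {
    generate_experiment(input)
  } else if (is.character(input)) {
    read_samples_csv(input, config$columns)
  } else if (is.data.frame(input)) {
    input
  } else {
    stop_invalid("`input` must be a CSV path, data frame or synthetic_config")
  }
  check_columns(tab, c("structure", "bulk_density", "gravimetric_wc",
                       "matric_potential", "measured_qp"),
                "pipeline input")
  derived <- derive_soil_state(tab, config$particle_density,
                               config$proctor_max_bd, config$theta_tolerance)
  if (!"re" %in% names(derived)) {
    # relative elongation from measured rates, normalised within structure
    check_columns(derived, "rate_cm_d", "pipeline input")
    derived$re <- stats::ave(derived$rate_cm_d, derived$structure,
                             FUN = normalize_elongation)
  }
  structures <- intersect(c("Field", "Packed"), unique(derived$structure))
  fits <- lapply(structures, function(str) {
    res <- tryCatch(
      fit_structure(derived, str, config$fit_fraction, config$n_starts,
                    config$seed),
      error = function(e) stop("stage [fit:", str, "]: ",
                               conditionMessage(e), call. = FALSE))
    res
  })
  names(fits) <- structures
  contrast <- if (all(c("Field", "Packed") %in% structures)) {
    compare_structures(fits$Field$surface, fits$Packed$surface)
  }
  result <- list(samples = derived, fits = fits, contrast = contrast)
  if (!is.null(out_dir)) write_pipeline_bundle(result, config, out_dir)
  result
}

write_pipeline_bundle <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(result$samples, file.path(out_dir, "derived_state.csv"))
  for (str in names(result$fits)) {
    f <- result$fits[[str]]
    low <- tolower(str)
    write_params_json(f$busscher,
                      file.path(out_dir, paste0("busscher_", low, ".json")))
    write_params_json(f$surface,
                      file.path(out_dir, paste0("surface_", low, ".json")))
    write_params_json(f$surface_eval,
                      file.path(out_dir, paste0("evaluation_", low, ".json")))
  }
  if (!is.null(result$contrast)) {
    write_table_csv(result$contrast$grid, file.path(out_dir, "contrast.csv"))
  }
  cfg_flat <- unlist(config[order(names(config))])
  log <- c(paste0("rootstress ", as.character(utils::packageVersion("rootstress"))),
           paste0("seed: ", config$seed),
           paste0("config: ", paste(names(cfg_flat), cfg_flat, sep = "=",
                                    collapse = " ")))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
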