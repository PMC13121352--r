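#' Soil physical-state derivations
#'
#' Functions that turn raw per-sample measurements (masses, bulk density,
#' gravimetric water content) into the derived physical quantities the root
#' elongation models are driven by: total porosity, volumetric water content,
#' air-filled porosity, degree of water saturation and degree of compactness.
#'
#' Water density is taken as 1 g cm^-3 (1 Mg m^-3) throughout, so gravimetric
#' water mass converts directly to water volume.
#'
#' @name soil_state
NULL

#' Total porosity from saturation masses
#'
#' Total porosity (m^3 m^-3) as the mass of water held at saturation divided
#' by the sample volume: `(saturated_mass - dry_mass) / volume` with water
#' density 1 g cm^-3.
#'
#' @param saturated_mass Mass of the saturated sample (g), soil plus water.
#' @param dry_mass Oven-dry soil mass (g).
#' @param volume Sample (cylinder) volume (cm^3).
#' @return Total porosity, a fraction in `[0, 1)`.
#' @seealso [total_porosity_from_density()] for the particle-density route
#'   used when saturation masses were not recorded.
#' @examples
#' total_porosity(500, 350, 298.6)
#' @export
total_porosity <- function(saturated_mass, dry_mass, volume) {
  check_finite(saturated_mass, "saturated_mass")
  check_finite(dry_mass, "dry_mass")
  check_finite(volume, "volume")
  if (any(dry_mass <= 0)) stop_invalid("`dry_mass` must be positive")
  if (any(volume <= 0)) stop_invalid("`volume` must be positive")
  if (any(saturated_mass < dry_mass))
    stop_invalid("`saturated_mass` must be >= `dry_mass`")
  tp <- (saturated_mass - dry_mass) / volume
  if (any(tp >= 1)) stop_invalid("computed porosity >= 1; check units")
  tp
}

#' Total porosity from bulk and particle density
#'
#' The particle-density route `1 - BD/PD`, used as a cross-check or when
#' saturation masses are absent.
#'
#' @param bulk_density Dry bulk density (Mg m^-3).
#' @param particle_density Particle density (Mg m^-3); 2.96 for the very
#'   clayey Oxisol the reference parameter sets describe.
#' @return Total porosity, a fraction in `(0, 1)`.
#' @export
total_porosity_from_density <- function(bulk_density, particle_density = 2.96) {
  check_finite(bulk_density, "bulk_density")
  check_finite(particle_density, "particle_density")
  if (any(bulk_density <= 0)) stop_invalid("`bulk_density` must be positive")
  if (any(particle_density <= 0)) stop_invalid("`particle_density` must be positive")
  if (any(bulk_density >= particle_density))
    stop_invalid("`bulk_density` must be below `particle_density`")
  1 - bulk_density / particle_density
}

#' Volumetric water content
#'
#' Converts gravimetric water content (kg kg^-1) to volumetric (m^3 m^-3) as
#' `theta_v = w * BD`, with water density 1 Mg m^-3.
#'
#' @param gravimetric_wc Gravimetric water content (kg kg^-1).
#' @param bulk_density Dry bulk density (Mg m^-3).
#' @return Volumetric water content (m^3 m^-3).
#' @export
volumetric_water_content <- function(gravimetric_wc, bulk_density) {
  check_finite(gravimetric_wc, "gravimetric_wc")
  check_finite(bulk_density, "bulk_density")
  if (any(gravimetric_wc < 0)) stop_invalid("`gravimetric_wc` must be >= 0")
  if (any(bulk_density < 0)) stop_invalid("`bulk_density` must be >= 0")
  gravimetric_wc * bulk_density
}

#' Degree of water saturation
#'
#' The hydric-stress variable S: volumetric water content as a percentage of
#' total porosity. Values above 100 are possible with noisy measurements and
#' are returned as-is; table-level derivation flags them (see
#' [derive_soil_state()]).
#'
#' @param theta_v Volumetric water content (m^3 m^-3).
#' @param total_porosity Total porosity (m^3 m^-3).
#' @return Saturation degree in percent.
#' @export
degree_of_saturation <- function(theta_v, total_porosity) {
  check_finite(theta_v, "theta_v")
  check_finite(total_porosity, "total_porosity")
  if (any(total_porosity <= 0)) stop_invalid("`total_porosity` must be positive")
  if (any(theta_v < 0)) stop_invalid("`theta_v` must be >= 0")
  100 * theta_v / total_porosity
}

#' Degree of compactness
#'
#' Bulk density as a percentage of the Proctor-test maximum bulk density:
#' `DC = 100 * BD / BD_proctor`.
#'
#' @param bulk_density Dry bulk density (Mg m^-3).
#' @param proctor_max_bd Proctor maximum bulk density (Mg m^-3); 1.53 for the
#'   reference Oxisol.
#' @return Degree of compactness in percent.
#' @examples
#' degree_of_compactness(1.10)  # ~72 %
#' degree_of_compactness(1.26)  # ~82 %
#' @export
degree_of_compactness <- function(bulk_density, proctor_max_bd = 1.53) {
  check_finite(bulk_density, "bulk_density")
  check_finite(proctor_max_bd, "proctor_max_bd")
  if (any(bulk_density <= 0)) stop_invalid("`bulk_density` must be positive")
  if (any(proctor_max_bd <= 0)) stop_invalid("`proctor_max_bd` must be positive")
  100 * bulk_density / proctor_max_bd
}

#' Root elongation rate
#'
#' Primary-root length divided by growth duration, expressed in cm per day.
#' When several seedling lengths are supplied (two seedlings per column in
#' the reference design) the per-sample rate is the mean length over
#' seedlings divided by the duration.
#'
#' @param root_length Primary-root length(s) in cm; one value per seedling.
#' @param duration_h Growth duration in hours (default 87, the standard
#'   seedling growth window).
#' @return Elongation rate in cm d^-1.
#' @examples
#' elongation_rate(14.5)                 # 4 cm/d over 87 h
#' elongation_rate(c(10.875, 10.875))    # mean over two seedlings
#' @export
elongation_rate <- function(root_length, duration_h = 87) {
  if (length(root_length) == 0) stop_invalid("`root_length` must be non-empty")
  check_finite(root_length, "root_length")
  check_finite(duration_h, "duration_h")
  if (any(root_length < 0)) stop_invalid("`root_length` must be >= 0")
  if (duration_h <= 0) stop_invalid("`duration_h` must be positive")
  mean(root_length) / (duration_h / 24)
}

#' Derive soil physical state for a sample table
#'
#' Computes, row-wise, total porosity (mass route when `saturated_mass` and
#' `dry_mass` columns are present, otherwise the particle-density route),
#' volumetric water content, air-filled porosity, saturation degree and
#' degree of compactness, and joins them to the sample table.
#'
#' `theta_v` exceeding total porosity by more than `theta_tolerance` (i.e.
#' apparent saturation beyond 100 %) is flagged in `saturation_flag`, not
#' rejected: small excesses are routine measurement noise in saturation
#' tables.
#'
#' @param samples Data frame with at least `bulk_density` and
#'   `gravimetric_wc`; optionally `saturated_mass`, `dry_mass`, `volume`
#'   (mass-route porosity) and `root_length` / `growth_duration`.
#' @param particle_density Particle density (Mg m^-3).
#' @param proctor_max_bd Proctor maximum bulk density (Mg m^-3).
#' @param theta_tolerance Tolerance (m^3 m^-3) on `theta_v` exceeding total
#'   porosity before a row is flagged.
#' @return The input with columns `total_porosity`, `porosity_route`,
#'   `theta_v`, `air_porosity`, `saturation_pct`, `compactness_pct`,
#'   `saturation_flag` appended (and `rate_cm_d` when root lengths are
#'   present).
#' @export
derive_soil_state <- function(samples, particle_density = 2.96,
                              proctor_max_bd = 1.53, theta_tolerance = 0.02) {
  check_columns(samples, c("bulk_density", "gravimetric_wc"), "sample table")
  mass_route <- all(c("saturated_mass", "dry_mass", "volume") %in% names(samples))
  tp <- if (mass_route) {
    total_porosity(samples$saturated_mass, samples$dry_mass, samples$volume)
  } else {
    total_porosity_from_density(samples$bulk_density, particle_density)
  }
  theta <- volumetric_water_content(samples$gravimetric_wc, samples$bulk_density)
  out <- samples
  out$total_porosity <- tp
  out$porosity_route <- if (mass_route) "mass" else "particle_density"
  out$theta_v <- theta
  out$air_porosity <- tp - theta
  out$saturation_pct <- degree_of_saturation(theta, tp)
  out$compactness_pct <- degree_of_compactness(samples$bulk_density, proctor_max_bd)
  out$saturation_flag <- theta > tp + theta_tolerance
  if ("root_length" %in% names(samples)) {
    dur <- if ("growth_duration" %in% names(samples)) samples$growth_duration else 87
    out$rate_cm_d <- mapply(elongation_rate, samples$root_length,
                            if (length(dur) == 1) rep(dur, nrow(samples)) else dur)
  }
  out
}
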