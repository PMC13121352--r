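#' 3D Gaussian relative-elongation surface parameters
#'
#' Container for the five-parameter bivariate Gaussian
#' `Re(Qp, S) = a * exp(-1/2 * (((S - x0)/b)^2 + ((Qp - y0)/c)^2))`
#' describing relative root elongation as a function of the degree of water
#' saturation `S` (%) and calculated penetration resistance `Qp` (MPa).
#'
#' `x0` and `y0` locate the stress optimum and are unconstrained in sign:
#' the re-packed structure's optimum resistance sits well below zero, i.e.
#' outside the physically reachable domain, which is what lets the surface
#' decay monotonically over the observed Qp range. The amplitude `a` is then
#' only weakly identified (it trades off against `y0` and `c`), so fitted
#' surfaces should be compared by their predictions, not their raw
#' parameters.
#'
#' @param a Peak amplitude (relative-elongation units), positive.
#' @param b Saturation width (%), positive.
#' @param c Resistance width (MPa), positive.
#' @param x0 Saturation optimum (%).
#' @param y0 Resistance optimum (MPa), may be negative.
#' @param structure Optional structure label.
#' @param se Optional named standard errors.
#' @param r2 Optional `1 - SS_error/SS_total`.
#' @return An object of class `gaussian_surface_params`.
#' @export
gaussian_surface_params <- function(a, b, c, x0, y0,
                                    structure = NA_character_, se = NULL,
                                    r2 = NA_real_) {
  for (nm in c("a", "b", "c", "x0", "y0")) check_finite(get(nm), nm)
  if (a <= 0) stop_invalid("`a` must be positive")
  if (b <= 0 || c <= 0) stop_invalid("widths `b` and `c` must be positive")
  structure(list(a = a, b = b, c = c, x0 = x0, y0 = y0,
                 structure = structure, se = se, r2 = r2),
            class = "gaussian_surface_params")
}

#' @export
print.gaussian_surface_params <- function(x, ...) {
  cat("3D Gaussian relative-elongation surface",
      if (!is.na(x$structure)) paste0("(", x$structure, ")"), "\n")
  cat(sprintf("  Re(Qp,S) = %.4g * exp(-1/2*(((S - %.4g)/%.4g)^2 + ((Qp - %.4g)/%.4g)^2))\n",
              x$a, x$x0, x$b, x$y0, x$c))
  if (!is.na(x$r2)) cat(sprintf("  R2 = %.3f\n", x$r2))
  invisible(x)
}

#' Reference elongation-surface parameter sets
#'
#' Fitted surface parameters for soybean primary roots in the intact
#' ("Field") and re-packed ("Packed") structures of a very clayey Rhodic
#' Eutrudox. Both optima `y0` are negative: relative elongation declines
#' monotonically with penetration resistance over the studied range
#' (0.5-4 MPa), faster in the Packed structure.
#'
#' @param structure `"Field"` or `"Packed"`.
#' @return A [gaussian_surface_params()] object.
#' @examples
#' relative_elongation(reference_surface_params("Field"), qp = 0.3, s = 60)
#' @export
reference_surface_params <- function(structure = c("Field", "Packed")) {
  structure <- match.arg(structure)
  switch(structure,
    Field  = gaussian_surface_params(a = 2.520, b = 47.583, c = 6.116,
                                     x0 = 33.763, y0 = -8.659,
                                     structure = "Field", r2 = 0.96),
    Packed = gaussian_surface_params(a = 994.145, b = 25.88, c = 7.398,
                                     x0 = 52.327, y0 = -27.157,
                                     structure = "Packed", r2 = 0.92))
}

#' Evaluate the relative-elongation surface
#'
#' @param params A [gaussian_surface_params()] object.
#' @param qp Calculated penetration resistance (MPa).
#' @param s Degree of water saturation (%).
#' @param clamp Truncate predictions to `[0, 1]`? Off by default: the Packed
#'   reference surface legitimately exceeds 1 near its (extrapolated) peak.
#' @return Relative elongation (dimensionless), vectorised over `qp`/`s`.
#' @export
relative_elongation <- function(params, qp, s, clamp = FALSE) {
  stopifnot(inherits(params, "gaussian_surface_params"))
  check_finite(qp, "qp")
  check_finite(s, "s")
  re <- params$a * exp(-0.5 * (((s - params$x0) / params$b)^2 +
                               ((qp - params$y0) / params$c)^2))
  if (clamp) re <- pmin(pmax(re, 0), 1)
  re
}

#' Normalise elongation rates to relative elongation
#'
#' Default mode divides by the maximum observed rate (so the maximum of the
#' output is exactly 1, within the group the rates came from); reference
#' mode divides by a supplied reference rate in cm d^-1.
#'
#' @param rates Elongation rates (cm d^-1), non-negative.
#' @param reference Optional positive reference rate (cm d^-1).
#' @return Dimensionless relative elongations.
#' @examples
#' normalize_elongation(c(2, 4))          # 0.5, 1
#' normalize_elongation(3.33, reference = 4.8261)
#' @export
normalize_elongation <- function(rates, reference = NULL) {
  if (length(rates) == 0) stop_invalid("`rates` must be non-empty")
  check_finite(rates, "rates")
  if (any(rates < 0)) stop_invalid("`rates` must be >= 0")
  if (is.null(reference)) {
    m <- max(rates)
    if (m == 0)
      stop_degenerate("all rates are zero and no `reference` was supplied")
    rates / m
  } else {
    check_finite(reference, "reference")
    if (reference <= 0) stop_invalid("`reference` must be positive")
    rates / reference
  }
}

# log Re is an exact quadratic in (s, qp), so OLS on logs inverts the model
# analytically for noise-free data and gives a strong start otherwise.
# Returns NULL when the quadratic opens the wrong way.
log_quadratic_start <- function(obs) {
  d <- obs[obs$re > 1e-12, , drop = FALSE]
  if (nrow(d) < 6) return(NULL)
  fit <- tryCatch(lm(log(re) ~ s + I(s^2) + qp + I(qp^2), data = d),
                  error = function(e) NULL)
  if (is.null(fit) || anyNA(coef(fit))) return(NULL)
  cf <- coef(fit)
  if (cf[["I(s^2)"]] >= 0 || cf[["I(qp^2)"]] >= 0) return(NULL)
  b <- sqrt(-1 / (2 * cf[["I(s^2)"]]))
  c_ <- sqrt(-1 / (2 * cf[["I(qp^2)"]]))
  x0 <- cf[["s"]] * b^2
  y0 <- cf[["qp"]] * c_^2
  a <- exp(cf[[1]] + x0^2 / (2 * b^2) + y0^2 / (2 * c_^2))
  if (!all(is.finite(c(a, b, c_, x0, y0))) || a <= 0) return(NULL)
  list(a = a, b = b, c = c_, x0 = x0, y0 = y0)
}

# Deterministic multi-start draws for the surface fit; box follows the data
# spread, with y0 allowed far below the observed Qp range (the optimum can
# lie outside the physical domain). Half the random draws match the
# amplitude to the highest observed point so that far-off optima still start
# on the data's scale.
surface_starts <- function(obs, n_starts, seed) {
  rng_s <- max(diff(range(obs$s)), 1); rng_q <- max(diff(range(obs$qp)), 0.1)
  i_max <- which.max(obs$re)
  a_max <- obs$re[i_max]
  heur <- list(a = a_max, b = rng_s / 2, c = rng_q / 2,
               x0 = obs$s[i_max], y0 = min(obs$qp))
  lq <- log_quadratic_start(obs)
  n_rand <- max(n_starts - 1 - !is.null(lq), 0)
  draws <- with_seed(seed, lapply(seq_len(n_rand), function(i) {
    st <- list(a = a_max * exp(runif(1, 0, log(10))),
               b = runif(1, 0.25, 2) * rng_s,
               c = runif(1, 0.25, 2) * rng_q,
               x0 = runif(1, min(obs$s) - rng_s, max(obs$s) + rng_s),
               y0 = runif(1, min(obs$qp) - 3 * rng_q, max(obs$qp)))
    if (i %% 2 == 0) {
      gh <- exp(-0.5 * (((obs$s[i_max] - st$x0) / st$b)^2 +
                        ((obs$qp[i_max] - st$y0) / st$c)^2))
      st$a <- min(a_max / max(gh, 1e-12), a_max * 1e6)
    }
    st
  }))
  c(list(heur), if (!is.null(lq)) list(lq), draws)
}

#' Fit the 3D Gaussian elongation surface
#'
#' Five-parameter nonlinear least squares by Levenberg-Marquardt with
#' multi-start: one data-driven heuristic start plus `n_starts - 1` random
#' starts drawn (deterministically for a given `seed`) from boxes scaled to
#' the data spread. The best converged start by residual sum of squares
#' wins. Widths and amplitude are bounded positive; `x0` and `y0` are
#' unconstrained in sign.
#'
#' @param obs Data frame with columns `re` (relative elongation), `qp` (MPa)
#'   and `s` (saturation %). At least 10 rows spanning at least 3 distinct
#'   `s` and 3 distinct `qp` values.
#' @param init Optional named list/vector `(a, b, c, x0, y0)` used as the
#'   only start.
#' @param n_starts Number of starts (default 20).
#' @param seed Seed for the random starts; the fit is deterministic given
#'   `(obs, init or n_starts, seed)`.
#' @param structure Optional structure label stored in the result.
#' @return A [gaussian_surface_params()] object with standard errors and
#'   `r2 = 1 - SS_error/SS_total`.
#' @export
fit_gaussian_surface <- function(obs, init = NULL, n_starts = 20, seed = 1,
                                 structure = NA_character_) {
  check_columns(obs, c("re", "qp", "s"), "surface fit input")
  obs <- obs[stats::complete.cases(obs[c("re", "qp", "s")]), , drop = FALSE]
  if (nrow(obs) < 10)
    stop_degenerate("need at least 10 observations; got ", nrow(obs))
  if (length(unique(obs$s)) < 3 || length(unique(obs$qp)) < 3)
    stop_degenerate("degenerate design: need >= 3 distinct saturation and ",
                    "resistance values")

  starts <- if (!is.null(init)) {
    stopifnot(length(init) == 5)
    list(setNames(as.list(as.numeric(init)), c("a", "b", "c", "x0", "y0")))
  } else {
    surface_starts(obs, n_starts, seed)
  }

  best <- NULL; best_sse <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        re ~ a * exp(-0.5 * (((s - x0) / b)^2 + ((qp - y0) / c)^2)),
        data = obs, start = st,
        lower = c(a = 1e-9, b = 1e-3, c = 1e-3, x0 = -Inf, y0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (sse < best_sse) { best <- fit; best_sse <- sse }
  }
  if (is.null(best))
    stop(errorCondition(
      paste0("no start converged out of ", length(starts), " tried"),
      class = c("rootstress_convergence_error", "error")))

  est <- coef(best)
  sst <- sum((obs$re - mean(obs$re))^2)
  se <- tryCatch(sqrt(diag(vcov(best))), error = function(e) NULL)
  gaussian_surface_params(est[["a"]], est[["b"]], est[["c"]],
                          est[["x0"]], est[["y0"]], structure = structure,
                          se = se,
                          r2 = if (sst > 0) 1 - best_sse / sst else NA_real_)
}

#' Relative-elongation reduction between two stress levels
#'
#' Percent reduction `100 * (1 - Re(to) / Re(from))` when one stress
#' coordinate moves from `from` to `to` while the other is held fixed.
#' Negative values indicate an increase.
#'
#' @param params A [gaussian_surface_params()] object.
#' @param fixed Which coordinate is held fixed: `"s"` (saturation) or
#'   `"qp"` (resistance).
#' @param at Value of the fixed coordinate.
#' @param from,to Values of the varying coordinate.
#' @return Reduction in percent.
#' @examples
#' # resistance rising 1 -> 3.5 MPa at 60 % saturation
#' stress_reduction(reference_surface_params("Field"), "s", 60, 1, 3.5)
#' @export
stress_reduction <- function(params, fixed = c("s", "qp"), at, from, to) {
  fixed <- match.arg(fixed)
  ev <- function(v) if (fixed == "s") relative_elongation(params, v, at)
                    else relative_elongation(params, at, v)
  re_from <- ev(from)
  if (re_from < .Machine$double.xmin)
    stop_degenerate("Re at `from` underflows to zero; reduction undefined")
  100 * (1 - ev(to) / re_from)
}

#' Contrast two fitted surfaces over a stress grid
#'
#' Evaluates both surfaces on a regular (Qp, S) grid and reports per-node
#' predictions, the Field/Packed ratio, and the grid-mean percent difference
#' `100 * mean(Re_field/Re_packed - 1)`. Default grid bounds cover the
#' studied window Qp 0.5-4 MPa, S 50-90 %.
#'
#' @param field,packed [gaussian_surface_params()] objects.
#' @param qp_range,s_range Numeric length-2 grid bounds.
#' @param steps Integer length-2: number of grid nodes along Qp and S.
#' @return List with `grid` (data frame `qp, s, re_field, re_packed, ratio`,
#'   plus `flag_gt1` marking nodes where either surface exceeds 1) and
#'   `mean_pct_diff`.
#' @export
compare_structures <- function(field, packed, qp_range = c(0.5, 4),
                               s_range = c(50, 90), steps = c(36, 41)) {
  stopifnot(inherits(field, "gaussian_surface_params"),
            inherits(packed, "gaussian_surface_params"))
  if (any(steps < 1)) stop_invalid("`steps` must be >= 1")
  grid <- expand.grid(qp = seq(qp_range[1], qp_range[2], length.out = steps[1]),
                      s = seq(s_range[1], s_range[2], length.out = steps[2]))
  grid$re_field <- relative_elongation(field, grid$qp, grid$s)
  grid$re_packed <- relative_elongation(packed, grid$qp, grid$s)
  grid$ratio <- grid$re_field / grid$re_packed
  grid$flag_gt1 <- grid$re_field > 1 | grid$re_packed > 1
  list(grid = grid, mean_pct_diff = 100 * mean(grid$ratio - 1))
}
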