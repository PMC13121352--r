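#' Busscher penetration-resistance parameter set
#'
#' Container for the power-law model `Qp = a * BD^b * w^c` relating soil
#' penetration resistance (MPa) to dry bulk density (Mg m^-3) and water
#' content. On sensible soils `b > 0` (denser soil is harder) and `c < 0`
#' (wetter soil is softer); a warning is emitted otherwise.
#'
#' @param a Multiplicative coefficient (MPa scale); must be positive.
#' @param b Bulk-density exponent (dimensionless).
#' @param c Water-content exponent (dimensionless).
#' @param structure Optional structure label, e.g. `"Field"` or `"Packed"`.
#' @param se Optional named numeric vector of standard errors (`a`, `b`, `c`).
#' @param r2 Optional coefficient of determination,
#'   `1 - SS_residual / SS_regression` (the ratio convention used for this
#'   model family).
#' @param r2_sst Optional conventional `1 - SSE/SST`.
#' @param rmse Optional fit RMSE (MPa).
#' @return An object of class `busscher_params`.
#' @export
busscher_params <- function(a, b, c, structure = NA_character_,
                            se = NULL, r2 = NA_real_, r2_sst = NA_real_,
                            rmse = NA_real_) {
  check_finite(a, "a"); check_finite(b, "b"); check_finite(c, "c")
  if (a <= 0) stop_invalid("`a` must be positive")
  if (b <= 0 || c >= 0)
    warning("unusual Busscher exponents: expected b > 0 and c < 0",
            call. = FALSE)
  structure(list(a = a, b = b, c = c, structure = structure, se = se,
                 r2 = r2, r2_sst = r2_sst, rmse = rmse),
            class = "busscher_params")
}

#' @export
print.busscher_params <- function(x, ...) {
  cat("Busscher penetration-resistance model",
      if (!is.na(x$structure)) paste0("(", x$structure, ")"), "\n")
  cat(sprintf("  Qp = %.4g * BD^%.4g * w^%.4g   [MPa]\n", x$a, x$b, x$c))
  if (!is.na(x$r2)) cat(sprintf("  R2 (ratio) = %.3f", x$r2))
  if (!is.na(x$r2_sst)) cat(sprintf("  R2 (1-SSE/SST) = %.3f", x$r2_sst))
  if (!is.na(x$rmse)) cat(sprintf("  RMSE = %.3f MPa", x$rmse))
  cat("\n")
  invisible(x)
}

#' Reference Busscher parameter sets
#'
#' Fitted coefficients for a very clayey Rhodic Eutrudox under no-tillage:
#' intact cores ("Field") and sieved, re-packed columns ("Packed"). Water
#' content enters gravimetrically (kg kg^-1).
#'
#' @param structure `"Field"` or `"Packed"`.
#' @return A [busscher_params()] object.
#' @examples
#' predict_qp(reference_busscher_params("Field"), 1.3, 0.29)
#' @export
reference_busscher_params <- function(structure = c("Field", "Packed")) {
  structure <- match.arg(structure)
  switch(structure,
    Field  = busscher_params(0.0201, 4.5602, -3.3804, "Field",
                             se = c(a = 0.0056, b = 0.6398, c = 0.2291),
                             r2 = 0.95, rmse = 0.504),
    Packed = busscher_params(0.0286, 2.8134, -3.2738, "Packed",
                             se = c(a = 0.0083, b = 0.2603, c = 0.2796),
                             r2 = 0.97, rmse = 0.353))
}

#' Predict penetration resistance
#'
#' Evaluates `Qp = a * BD^b * w^c` (MPa). With `c < 0` the model is singular
#' at zero water content, so `water_content` must be strictly positive.
#'
#' @param params A [busscher_params()] object.
#' @param bulk_density Dry bulk density (Mg m^-3), positive.
#' @param water_content Water content (kg kg^-1 in the default gravimetric
#'   convention), strictly positive.
#' @return Predicted penetration resistance (MPa), vectorised over inputs.
#' @export
predict_qp <- function(params, bulk_density, water_content) {
  stopifnot(inherits(params, "busscher_params"))
  check_finite(bulk_density, "bulk_density")
  check_finite(water_content, "water_content")
  if (any(bulk_density <= 0)) stop_invalid("`bulk_density` must be positive")
  if (any(water_content <= 0))
    stop_invalid("`water_content` must be strictly positive: ",
                 "the power law with c < 0 is singular at w = 0")
  params$a * bulk_density^params$b * water_content^params$c
}

#' Fit the Busscher model
#'
#' Nonlinear least squares on the original MPa scale via Levenberg-Marquardt,
#' initialised from the ordinary-least-squares solution of the log-linear
#' form `log Qp = log a + b log BD + c log w` (which is the exact solution
#' for noise-free data). The fit is deterministic given the data and
#' initialisation.
#'
#' @param data Data frame with columns `bulk_density`, `water_content` and
#'   `measured_qp` (MPa). All `measured_qp` must be positive for the
#'   log-linear initialisation.
#' @param init Optional numeric triple `c(a, b, c)` overriding the log-OLS
#'   start.
#' @param structure Optional structure label stored in the result.
#' @param control A [minpack.lm::nls.lm.control()] list.
#' @return A [busscher_params()] object with standard errors, RMSE, the
#'   ratio-convention R2 (`1 - SS_res/SS_reg`) and the conventional
#'   `1 - SSE/SST` (`r2_sst`).
#' @export
fit_busscher <- function(data, init = NULL, structure = NA_character_,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)) {
  check_columns(data, c("bulk_density", "water_content", "measured_qp"),
                "Busscher fit input")
  data <- data[stats::complete.cases(
    data[c("bulk_density", "water_content", "measured_qp")]), , drop = FALSE]
  if (nrow(data) < 6)
    stop_degenerate("need at least 6 complete samples to fit; got ", nrow(data))
  if (length(unique(data$bulk_density)) < 2 ||
      length(unique(data$water_content)) < 2)
    stop_degenerate("degenerate design: need >= 2 distinct bulk densities ",
                    "and water contents")
  if (any(data$measured_qp <= 0) || any(data$water_content <= 0) ||
      any(data$bulk_density <= 0))
    stop_invalid("bulk density, water content and measured Qp must be positive")

  if (is.null(init)) {
    ols <- lm(log(measured_qp) ~ log(bulk_density) + log(water_content),
              data = data)
    init <- c(a = exp(coef(ols)[[1]]), b = coef(ols)[[2]], c = coef(ols)[[3]])
  } else {
    stopifnot(length(init) == 3)
    init <- setNames(as.numeric(init), c("a", "b", "c"))
  }

  fit <- minpack.lm::nlsLM(
    measured_qp ~ a * bulk_density^b * water_content^c,
    data = data, start = as.list(init), control = control,
    lower = c(a = 1e-12, b = -Inf, c = -Inf))
  est <- coef(fit)
  resid <- data$measured_qp - predict_qp(
    busscher_params(est[["a"]], est[["b"]], est[["c"]]),
    data$bulk_density, data$water_content)
  sse <- sum(resid^2)
  ss_reg <- sum((data$measured_qp - resid - mean(data$measured_qp))^2)
  sst <- sum((data$measured_qp - mean(data$measured_qp))^2)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  busscher_params(est[["a"]], est[["b"]], est[["c"]], structure,
                  se = setNames(se, c("a", "b", "c")),
                  r2 = if (ss_reg > 0) 1 - sse / ss_reg else NA_real_,
                  r2_sst = if (sst > 0) 1 - sse / sst else NA_real_,
                  rmse = sqrt(mean(resid^2)))
}
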