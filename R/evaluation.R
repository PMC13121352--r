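#' Model agreement metrics
#'
#' Root mean square error, coefficient of residual mass, Pearson correlation
#' and the Willmott index of agreement, plus the stratified fit/validation
#' split protocol used to assess the elongation models on held-out samples.
#'
#' @name evaluation
NULL

check_pair <- function(observed, predicted) {
  if (length(observed) == 0 || length(observed) != length(predicted))
    stop_invalid("`observed` and `predicted` must be non-empty and of equal length")
  check_finite(observed, "observed")
  check_finite(predicted, "predicted")
}

#' Root mean square error
#'
#' `sqrt(mean((P - O)^2))`, in the units of the response; ideal value 0.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return RMSE.
#' @export
rmse <- function(observed, predicted) {
  check_pair(observed, predicted)
  sqrt(mean((predicted - observed)^2))
}

#' Coefficient of residual mass
#'
#' `CRM = (sum(O) - sum(P)) / sum(O)`; 0 is ideal, positive values indicate
#' a tendency to under-predict, negative values over-prediction.
#'
#' @param observed,predicted Equal-length numeric vectors; `sum(observed)`
#'   must be non-zero.
#' @return CRM (dimensionless).
#' @export
crm <- function(observed, predicted) {
  check_pair(observed, predicted)
  so <- sum(observed)
  if (so == 0) stop_undefined_metric("CRM undefined: sum(observed) is zero")
  (so - sum(predicted)) / so
}

#' Pearson correlation between observed and predicted
#'
#' Covariance over the product of standard deviations (the ratio is the same
#' under the 1/n and 1/(n-1) conventions); ideal value 1.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2) with
#'   non-zero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(observed, predicted) {
  check_pair(observed, predicted)
  if (length(observed) < 2)
    stop_invalid("need at least 2 pairs for a correlation")
  if (sd(observed) == 0 || sd(predicted) == 0)
    stop_undefined_metric("correlation undefined: zero variance")
  cor(observed, predicted)
}

#' Willmott index of agreement
#'
#' `d = 1 - sum((P - O)^2) / sum((|P - mean(O)| + |O - mean(O)|)^2)`;
#' bounded above by 1, attained iff predictions equal observations.
#'
#' @param observed,predicted Equal-length numeric vectors; the potential
#'   error denominator must be non-zero (i.e. not all values identical).
#' @return Index of agreement.
#' @export
willmott_d <- function(observed, predicted) {
  check_pair(observed, predicted)
  obar <- mean(observed)
  denom <- sum((abs(predicted - obar) + abs(observed - obar))^2)
  if (denom == 0)
    stop_undefined_metric("Willmott d undefined: zero potential error")
  1 - sum((predicted - observed)^2) / denom
}

#' Stratified fit/validation split
#'
#' Partitions a sample table into a fit set and a validation set,
#' stratifying by a grouping column (matric potential by default, so every
#' hydric level stays represented in both sets). Within each stratum the fit
#' count is `fit_fraction` of the stratum size; counts are allocated by
#' largest remainder so the overall split matches `round(n * fit_fraction)`
#' while each stratum stays within one sample of its target. Deterministic
#' for a fixed seed. Strata with fewer than 2 samples go entirely to the fit
#' set, with a warning.
#'
#' @param samples Data frame.
#' @param fit_fraction Fraction assigned to the fit set, in (0, 1).
#' @param stratify_by Name of the stratification column.
#' @param seed Integer seed.
#' @return List with data frames `fit` and `validation`; together they are a
#'   disjoint, exhaustive partition of `samples`.
#' @export
split_fit_validate <- function(samples, fit_fraction = 0.7,
                               stratify_by = "matric_potential", seed = 1) {
  if (fit_fraction <= 0 || fit_fraction >= 1)
    stop_invalid("`fit_fraction` must be in (0, 1)")
  check_columns(samples, stratify_by, "split input")
  strata <- split(seq_len(nrow(samples)), samples[[stratify_by]])
  targets <- vapply(strata, length, 1L) * fit_fraction
  n_fit <- floor(targets)
  remainder <- round(sum(targets)) - sum(n_fit)
  if (remainder > 0) {
    order_frac <- order(targets - floor(targets), decreasing = TRUE)
    n_fit[order_frac[seq_len(remainder)]] <- n_fit[order_frac[seq_len(remainder)]] + 1L
  }
  fit_idx <- with_seed(seed, unlist(lapply(seq_along(strata), function(i) {
    idx <- strata[[i]]
    if (length(idx) < 2) {
      warning("stratum '", names(strata)[i],
              "' has fewer than 2 samples; assigned entirely to the fit set",
              call. = FALSE)
      return(idx)
    }
    sample(idx, min(n_fit[i], length(idx)))
  })))
  list(fit = samples[sort(fit_idx), , drop = FALSE],
       validation = samples[setdiff(seq_len(nrow(samples)), fit_idx), , drop = FALSE])
}

#' Evaluate a fitted model on held-out samples
#'
#' Computes predictions from a fitted parameter object on a validation table
#' and reports RMSE, CRM, Pearson r and Willmott d. Metrics whose
#' preconditions fail (e.g. constant predictions for r) are reported as `NA`
#' with the reason recorded in `flags`, never silently as 0.
#'
#' @param params A [busscher_params()] object (predicts `measured_qp` from
#'   `bulk_density` and `water_content`) or a [gaussian_surface_params()]
#'   object (predicts `re` from `qp` and `s`).
#' @param validation Non-empty data frame with the columns the model needs.
#' @return An object of class `evaluation_report`: list with `n`, `rmse`,
#'   `crm`, `r`, `d` and a character vector `flags`.
#' @export
evaluate_model <- function(params, validation) {
  if (nrow(validation) == 0) stop_invalid("`validation` must be non-empty")
  if (inherits(params, "busscher_params")) {
    check_columns(validation, c("bulk_density", "water_content", "measured_qp"),
                  "validation table")
    obs <- validation$measured_qp
    pred <- predict_qp(params, validation$bulk_density, validation$water_content)
  } else if (inherits(params, "gaussian_surface_params")) {
    check_columns(validation, c("re", "qp", "s"), "validation table")
    obs <- validation$re
    pred <- relative_elongation(params, validation$qp, validation$s)
  } else {
    stop_invalid("unsupported model class: ", paste(class(params), collapse = "/"))
  }
  flags <- character()
  metric <- function(f, name) {
    tryCatch(f(obs, pred), error = function(e) {
      flags <<- c(flags, paste0(name, ": ", conditionMessage(e)))
      NA_real_
    })
  }
  structure(list(n = length(obs),
                 rmse = metric(rmse, "rmse"),
                 crm = metric(crm, "crm"),
                 r = metric(pearson_r, "r"),
                 d = metric(willmott_d, "d"),
                 flags = flags),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Model evaluation on n = %d held-out samples\n", x$n))
  cat(sprintf("  RMSE = %.4g  CRM = %.4g  r = %.4g  d = %.4g\n",
              x$rmse, x$crm, x$r, x$d))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
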