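# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never perturb user code.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("rootstress_invalid_input", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("rootstress_degenerate_design", "error")))
}

stop_undefined_metric <- function(...) {
  stop(errorCondition(paste0(...), class = c("rootstress_undefined_metric", "error")))
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_invalid("`", name, "` must be finite numeric")
  invisible(x)
}

check_columns <- function(data, required, context = "input") {
  missing <- setdiff(required, names(data))
  if (length(missing))
    stop(errorCondition(
      paste0(context, " is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = c("rootstress_schema_error", "error")))
  invisible(data)
}
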