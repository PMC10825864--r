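#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dist dnorm lm rbinom rnorm rpois runif sd t.test coef predict
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library calls never perturb user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed and a label
#'
#' Every stochastic stage of the pipeline draws from its own stream, whose
#' seed is a deterministic hash of the master seed and a human-readable
#' label (e.g. `"footprint/t=24/rep=2/cell=3"`). Logging the label is enough
#' to re-simulate any single stage in isolation.
#'
#' @param master integer master seed.
#' @param ... label components, concatenated with `"/"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "footprint", "rep", 2)
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  label <- paste(vapply(list(...), function(x) paste(format(x, trim = TRUE), collapse = ","),
                        character(1)), collapse = "/")
  m <- 2147483647  # 2^31 - 1, prime
  s <- (abs(as.numeric(master)) %% m)
  for (b in utf8ToInt(label)) s <- (s * 31 + b) %% m
  as.integer(s %% (m - 1) + 1)
}

# Scalar validation helpers: terse on purpose, used everywhere.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("`%s` = %g is outside its allowed range %s%g, %g%s", name, x,
                 if (lower_open) "(" else "[", lower, upper,
                 if (upper_open) ")" else "]"), call. = FALSE)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x))
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}
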