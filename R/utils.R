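`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (strict_lower && x <= lower) stop_field(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower) stop_field(field, sprintf("must be >= %g", lower))
  if (strict_upper && x >= upper) stop_field(field, sprintf("must be < %g", upper))
  if (!strict_upper && x > upper) stop_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}
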