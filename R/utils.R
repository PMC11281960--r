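# internal argument checks -----------------------------------------------

.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

.check_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L)
    stop(sprintf("`%s` must be a non-empty numeric vector", name),
         call. = FALSE)
  if (finite && !all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  invisible(x)
}

.check_pair <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || !all(is.finite(x)))
    stop(sprintf("`%s` must be a numeric pair", name), call. = FALSE)
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Independent per-component seeds derived from one root seed, so changing
# one component's parameters never perturbs another component's draws.
derive_seeds <- function(seed, components) {
  .check_scalar(seed, "seed")
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                  length(components)))
  names(s) <- components
  s
}
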