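# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards.  All randomness in the package goes through
# this so that bundles and cross-validation splits are reproducible from an
# integer seed alone (Mersenne-Twister, R's default generator).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Split whitespace-delimited lines into token lists; used by the flat-file
# readers so that tab- and space-separated inputs are handled alike.
split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")

# Condition constructors: data-format problems raise dcsim_parse_error (CLI
# exit code 3), bad invocations raise dcsim_usage_error (exit code 2).
parse_error <- function(msg) {
  stop(structure(class = c("dcsim_parse_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

usage_error <- function(msg) {
  stop(structure(class = c("dcsim_usage_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# sample() that never interprets a length-1 x as 1:x
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
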