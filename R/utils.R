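## Internal helpers: condition classes and seeded evaluation.

fd_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "fdnet_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

fd_warn <- function(class, msg) {
  warning(structure(
    class = c(class, "fdnet_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## Evaluate `code` under a fixed RNG state, restoring the caller's stream.
local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a top-level seed
#'
#' All randomness in the package flows from one user-supplied seed; stages
#' that need an independent stream (e.g. per-permutation module detection)
#' derive sub-seeds through this fixed integer recurrence, so partial re-runs
#' of a pipeline stay consistent with full runs.
#'
#' @param seed Integer top-level seed.
#' @param offset Integer stage/index offset.
#' @return A positive integer below 2^31 - 1.
#' @export
#' @examples
#' derive_seed(1, 1)
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), is.numeric(offset))
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(offset) * 110351 + 7) %% 2147483629) + 1L
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}
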