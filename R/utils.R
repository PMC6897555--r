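#' Derive a reproducible sub-stream seed
#'
#' Fans a master seed out into per-object seeds so that any stimulus,
#' schedule, subject or network is reproducible in isolation. The derivation
#' is a small multiplicative hash over the master seed and an arbitrary key;
#' results always fit in a 32-bit signed integer.
#'
#' @param seed Master seed (non-negative integer).
#' @param ... Further integer or character key components (e.g. a stimulus
#'   index, a phase tag).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 3, "texture")
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  key <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in key) {
    if (is.character(k)) k <- utf8ToInt(paste(k, collapse = ""))
    for (v in as.numeric(k)) {
      h <- (h * 69069 + abs(v) + 1) %% 2147483647
    }
  }
  as.integer(h)
}

# Run code under a local RNG stream, restoring the caller's stream after.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
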