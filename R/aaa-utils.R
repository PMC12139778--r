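#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Derive a reproducible per-stage seed from a global seed
#'
#' A single global seed drives every stochastic stage of a run; each stage
#' receives its own deterministic child seed so stages can also be rerun
#' standalone with identical results.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage index (>= 0).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  ((as.numeric(seed) %% 2147483646) * 7919 + as.numeric(stage) * 104729) %% 2147483646 + 1
}

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Population standard deviation (divides by n, not n - 1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

## Small deterministic string hash (FNV-1a, 32-bit) for run manifests.
string_hash <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stop_if_not_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
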