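# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the previous
#' RNG state so callers never perturb the session stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit seed derived from a base seed plus stage tags, so each
# stochastic stage (split / init / epoch shuffle / ...) of each iteration gets
# its own reproducible stream.
derive_seed <- function(seed, ...) {
  parts <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                 collapse = "/")
  h <- 17
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Consistent scalar validation
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must be a single number strictly between 0 and 1", name),
         call. = FALSE)
  }
  as.numeric(x)
}
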