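#' @keywords internal
"_PACKAGE"

# deterministic child-seed derivation: fold arbitrary tags into [1, 2^31-2]
# via a rolling polynomial hash so that independent pipeline stages draw from
# non-colliding streams derived from one user-facing seed.
derive_seed <- function(seed, ...) {
  tags <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(seed) %% 2147483647
  for (tag in tags) {
    for (code in utf8ToInt(tag)) {
      h <- (h * 31 + code) %% 2147483647
    }
  }
  as.integer(h %% 2147483646 + 1)
}

# local RNG scope: evaluates expr with the given seed without disturbing the
# caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_hw <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_hw("'%s' must be a single finite number", name)
  }
  if (positive && x <= 0) stop_hw("'%s' must be > 0", name)
  invisible(x)
}

rms <- function(x) sqrt(mean(x^2))
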