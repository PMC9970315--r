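#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Locale-independent lexicographic ordering; all deterministic orderings in
# the package go through this so results do not depend on the platform locale.
lex_order <- function(...) order(..., method = "radix")

lex_sort <- function(x) sort(x, method = "radix")

# Stable lexicographic key for a node sequence (the \\x01 separator never
# occurs in identifiers).
chain_key <- function(nodes) paste(nodes, collapse = "\u0001")

assert_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  as.numeric(x)
}

assert_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != floor(seed)) {
    abort("`seed` must be a single integer")
  }
  as.integer(seed)
}

# Set the RNG for the duration of the calling function only.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
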