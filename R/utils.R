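#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Single positive integer check with a readable error.
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name))
  }
  as.numeric(x)
}

#' Number of possible unordered protein pairs
#'
#' For `n` distinct proteins there are `n (n - 1) / 2` possible undirected,
#' self-loop-free interactions. This count is the population of the binary
#' enrichment test.
#'
#' @param n Number of nodes (non-negative integer, vectorized).
#' @return Numeric vector of pair counts.
#' @examples
#' n_possible_pairs(16272) # 132380856
#' @export
n_possible_pairs <- function(n) {
  if (!is.numeric(n) || any(is.na(n)) || any(n < 0)) {
    abort("`n` must be non-negative.")
  }
  n * (n - 1) / 2
}

# Canonical unordered pair key "a|b" with a < b; used for edge dedup.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
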