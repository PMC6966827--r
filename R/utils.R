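# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a stream-specific seed from a base seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

stop_input <- function(...) stop(..., call. = FALSE)

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_input(sprintf("'%s' must be a single proportion in [0, 1]", name))
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_input(sprintf("'%s' must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}

# Logit with the (x + 0.5) / (n + 1) continuity correction, used for
# proportions that can hit 0 or 1 at small n.
logit_cc <- function(x, n) {
  p <- (x + 0.5) / (n + 1)
  log(p / (1 - p))
}

# sample() that never falls into the 1:n trap when x has length 1.
sample_safe <- function(x, size, replace = FALSE, prob = NULL) {
  if (length(x) == 1L) {
    if (replace) return(rep(x, size))
    if (size > 1L) stop_input("cannot sample more elements than available")
    return(x)
  }
  sample(x, size, replace = replace, prob = prob)
}

# Dirichlet draws via normalized gammas; alpha recycled per row.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}
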