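#' @useDynLib lungrecon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames sd
#' @importFrom utils head modifyList
NULL

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a stream of child seeds from one global seed
#'
#' All stochastic entry points draw their seeds from the global seed through
#' this single rule, so an end-to-end run is reproducible from one integer.
#'
#' @param seed Integer global seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || (strict_lower && x <= lower))
    stopf("`%s` must be %s %s", name, if (strict_lower) ">" else ">=", lower)
  if (x > upper || (strict_upper && x >= upper))
    stopf("`%s` must be %s %s", name, if (strict_upper) "<" else "<=", upper)
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Apply `f` elementwise over two parallel nested lists of arrays.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(f, x, y), a, b)
    return(out)
  }
  f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, tree_map, f = f))
  f(a)
}

# Maximum absolute difference between two parallel parameter trees.
tree_max_abs_diff <- function(a, b) {
  if (is.list(a)) return(max(vapply(seq_along(a), function(i)
    tree_max_abs_diff(a[[i]], b[[i]]), numeric(1))))
  if (length(a) == 0) return(0)
  max(abs(a - b))
}

# sample() treats a scalar first argument as 1:n; this always samples from
# the vector's elements.
sample_vec <- function(x, n) {
  if (length(x) == 0 || n <= 0) return(x[0])
  x[sample.int(length(x), min(n, length(x)))]
}
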