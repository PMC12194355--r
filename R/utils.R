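#' @useDynLib scintiden, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois rbinom runif rnorm lm pt sd t.test quantile setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  force(code)
}

#' Derive a reproducible child seed from a base seed and indices
#'
#' All stochastic operations in the package draw their seeds through this
#' mixer so that every image, subject and training run is reproducible from a
#' single integer. The arithmetic stays below 2^53 so the result is exact in
#' double precision on every platform; the returned seed is in `[0, 2^31 - 2]`.
#'
#' @param base integer base seed.
#' @param ... further integer indices (subject, region, view, ... ).
#' @return a single integer seed.
#' @export
derive_seed <- function(base, ...) {
  v <- c(as.double(base), as.double(unlist(list(...))))
  s <- 0
  for (x in v) {
    s <- (s * 7919 + x * 104729 + 12345) %% 2147483647
  }
  as.integer(s)
}

# Recursively apply f over two parallel trees of numeric arrays.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(f, a[[i]])
    out
  } else {
    f(a)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
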