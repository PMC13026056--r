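#' Derive a reproducible child seed
#'
#' Folds one or more integer or character tags into a base seed with a
#' multiplicative-congruential mix. Every source of randomness in the package
#' (parameter initialisation, fold assignment, per-epoch shuffles, per-teacher
#' seeds) draws its seed through this function so that a whole run is
#' replayable from a single integer. Results always lie in [1, 2^31 - 2].
#'
#' @param seed base integer seed.
#' @param ... integer or character tags identifying the consumer.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  xs <- list(...)
  h <- (abs(as.double(seed)) + 1) %% 2147483647
  for (x in xs) {
    if (is.character(x)) x <- sum(utf8ToInt(paste(x, collapse = "")))
    h <- (h * 69069 + as.double(x) + 12345) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# recursive map over nested parameter lists (leaves are numeric arrays)
param_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) param_map(f, x)) else f(a)
}

param_map2 <- function(f, a, b) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- param_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

# flatten nested parameter list to one numeric vector (fixed order)
param_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, param_flatten), use.names = FALSE)
  else as.numeric(a)
}

param_count <- function(a) length(param_flatten(a))

# shapes (names + dims) of two nested parameter lists agree
param_shapes_match <- function(a, b) {
  fa <- param_structure(a); fb <- param_structure(b)
  identical(fa, fb)
}

param_structure <- function(a) {
  if (is.list(a)) lapply(a, param_structure)
  else c(dim(a), length(a))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
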