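#' @useDynLib eegtopoclass, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd fft pt qt var predict
#' @importFrom utils head tail
NULL

# Internal: stop with a classed condition so callers can test error contracts.
stop_input <- function(msg, class = "eegtopoclass_input_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
}

#' Derive a reproducible child seed
#'
#' Hashes a base seed together with one or more tags (subject ids, fold
#' indices, stage names) into a new seed in `[1, 2^31 - 2]`.  Used so that
#' every subject / fold / stage gets an independent but reproducible RNG
#' stream from a single pipeline seed.
#'
#' @param seed integer base seed.
#' @param ... scalars (numbers or strings) mixed into the hash.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483629  # largest prime < 2^31
  h <- as.numeric(seed) %% m
  for (tag in list(...)) {
    bytes <- utf8ToInt(paste0(as.character(tag), "|"))
    for (b in bytes) h <- (h * 131 + b) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
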