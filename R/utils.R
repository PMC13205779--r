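# Internal helpers shared across modules.

#' Derive a reproducible child seed from a run seed and string labels
#'
#' Stage- and pair-level random draws are seeded independently so that any
#' subset of the pipeline can be recomputed without replaying the whole run.
#' The derivation is a deterministic polynomial hash of the run seed and the
#' labels, reduced modulo 2^31 - 1 (R seeds are 32-bit integers).
#'
#' @param seed integer run seed.
#' @param ... character or numeric labels identifying the stage/unit.
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  labels <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                  collapse = "\r")
  h <- 0
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Center rows, then scale each to unit Euclidean norm; rows must be
# non-constant (caller's responsibility). crossprod of two such matrices
# gives Pearson correlations directly.
unit_rows <- function(m) {
  m <- m - rowMeans(m)
  m / sqrt(rowSums(m * m))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
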