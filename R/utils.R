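# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library calls do not disturb the
#' caller's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# deterministic fan-out of a master seed into per-purpose substreams;
# kept below 2^31 so the result is a valid R integer seed
derive_seed <- function(master, stream) {
  offsets <- c(split = 104729L, init = 224737L, dropout = 350377L,
               negative = 479909L, corpus = 611953L, kg = 746773L,
               order = 882377L)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  (as.integer(master) %% 1000000000L) + offsets[[stream]]
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# row-wise softmax with optional logical key mask (FALSE = excluded)
softmax_rows <- function(S, key_mask = NULL) {
  if (!is.null(key_mask) && any(!key_mask)) S[, !key_mask] <- -Inf
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

l2norm <- function(v) sqrt(sum(v * v))

cosine_sim <- function(a, b) {
  na <- l2norm(a); nb <- l2norm(b)
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}
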