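#' Concatenate the sentence representation with KG relation vectors
#'
#' Builds the classifier input `[B ; R_drug_gene ; R_drug_mutation]`.
#' Absent relation slots are zero-filled with `k` entries, so an instance
#' whose entities are outside the KG (or a run without a KG) degrades to
#' the text-only feature vector padded with zeros.
#'
#' @param B pooled sentence representation (length `d`).
#' @param r_dg drug-gene relation vector or `NULL`.
#' @param r_dm drug-mutation relation vector or `NULL`.
#' @param k relation-vector dimension used for zero fill (default 50).
#' @return numeric vector of length `d + 2k`.
#' @export
concat_features <- function(B, r_dg = NULL, r_dm = NULL, k = 50L) {
  r_dg <- r_dg %||% numeric(k)
  r_dm <- r_dm %||% numeric(k)
  c(as.numeric(B), as.numeric(r_dg), as.numeric(r_dm))
}

#' Initialize softmax classifier parameters
#' @param input_dim feature dimension `d + 2k`.
#' @param n_classes class count.
#' @param scale uniform init half-width.
#' @param seed integer seed.
#' @return list with weight `W` (`input_dim x n_classes`) and bias `b`.
#' @export
classifier_params <- function(input_dim, n_classes, scale = 0.08, seed = 1L) {
  with_seed(derive_seed(seed, "init"), {
    list(W = matrix(stats::runif(input_dim * n_classes, -scale, scale),
                    input_dim, n_classes),
         b = numeric(n_classes))
  })
}

#' Class probabilities of a feature vector
#'
#' `softmax(W' x + b)`: entries are positive and sum to one; adding a
#' constant to all logits leaves the output unchanged.
#'
#' @param x feature vector.
#' @param params a [classifier_params()] list.
#' @return probability vector over classes.
#' @export
predict_probs <- function(x, params) {
  if (length(x) != nrow(params$W))
    stop(sprintf("feature length %d does not match classifier input %d",
                 length(x), nrow(params$W)))
  softmax_vec(drop(x %*% params$W) + params$b)
}

#' Cross-entropy loss of predicted probabilities
#'
#' `-log p(gold)`, averaged when given a batch (list of probability
#' vectors and a vector of gold indices). Probabilities are clamped at
#' `1e-12` before the log.
#'
#' @param probabilities probability vector, or list of them.
#' @param gold integer gold class index (1-based), vectorized for a batch.
#' @return nonnegative scalar.
#' @export
cross_entropy <- function(probabilities, gold) {
  if (is.list(probabilities)) {
    return(mean(mapply(function(p, g) -log(max(p[g], 1e-12)),
                       probabilities, gold)))
  }
  -log(max(probabilities[gold], 1e-12))
}
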