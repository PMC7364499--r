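#' Scaled dot-product attention
#'
#' `softmax(Q K' / scale) V`, with the softmax taken row-wise over the
#' unmasked keys; masked keys receive zero weight. The default scale is
#' `sqrt(ncol(K))`.
#'
#' @param Q,K,V numeric matrices; `K` and `V` row-aligned, `Q` and `K`
#'   with equal column count.
#' @param mask logical vector over keys (`NULL` = all valid).
#' @param scale positive scalar divisor of the logits.
#' @return matrix with `nrow(Q)` rows and `ncol(V)` columns.
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL, scale = sqrt(ncol(K))) {
  Q <- rbind(Q); K <- rbind(K); V <- rbind(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must share their column dimension")
  if (nrow(K) != nrow(V)) stop("K and V must be row-aligned")
  A <- softmax_rows(tcrossprod(Q, K) / scale, key_mask = mask)
  A %*% V
}

# forward keeping the weight matrix for backprop
attention_forward <- function(Q, K, V, mask = NULL, scale = sqrt(ncol(K))) {
  A <- softmax_rows(tcrossprod(Q, K) / scale, key_mask = mask)
  list(O = A %*% V, A = A, scale = scale)
}

attention_backward <- function(dO, fwd, Q, K, V) {
  A <- fwd$A
  dV <- crossprod(A, dO)
  dA <- tcrossprod(dO, V)
  dS <- A * (dA - rowSums(dA * A))     # softmax Jacobian, row-wise
  dS <- dS / fwd$scale
  list(dQ = dS %*% K, dK = crossprod(dS, Q), dV = dV)
}

#' Initialize multihead attention parameters
#'
#' Per-head query/key/value projections of shape `d x (d/h)` are stored
#' column-blocked in full `d x d` matrices `Wq`, `Wk`, `Wv`; `Wo` is the
#' `d x d` output mix applied to the concatenated heads.
#'
#' @param d model dimension (default 400); must be divisible by `heads`.
#' @param heads head count (default 4).
#' @param scale uniform init half-width.
#' @param seed integer seed.
#' @param softmax_scale `"per_head"` (divide logits by `sqrt(d/h)`) or
#'   `"model_dim"` (divide by `sqrt(d)`).
#' @return object of class `multihead_params`.
#' @export
multihead_params <- function(d = 400L, heads = 4L, scale = 0.08, seed = 1L,
                             softmax_scale = c("per_head", "model_dim")) {
  d <- stopifnot_scalar_int(d, "d")
  heads <- stopifnot_scalar_int(heads, "heads")
  if (d %% heads != 0L) stop("model dim d must be divisible by the head count")
  softmax_scale <- match.arg(softmax_scale)
  with_seed(derive_seed(seed, "init"), {
    mat <- function() matrix(stats::runif(d * d, -scale, scale), d, d)
    structure(list(d = d, heads = heads, Wq = mat(), Wk = mat(), Wv = mat(),
                   Wo = mat(), softmax_scale = softmax_scale),
              class = "multihead_params")
  })
}

head_cols <- function(params, i) {
  dh <- params$d %/% params$heads
  ((i - 1L) * dh + 1L):(i * dh)
}

attn_scale <- function(params) {
  if (params$softmax_scale == "model_dim") sqrt(params$d)
  else sqrt(params$d / params$heads)
}

# forward with caches for backprop; X is n x d (valid rows only)
multihead_forward <- function(X, params, mask = NULL) {
  Q <- X %*% params$Wq; K <- X %*% params$Wk; V <- X %*% params$Wv
  sc <- attn_scale(params)
  heads <- vector("list", params$heads)
  M <- matrix(0, nrow(X), params$d)
  for (i in seq_len(params$heads)) {
    cols <- head_cols(params, i)
    heads[[i]] <- attention_forward(Q[, cols, drop = FALSE],
                                    K[, cols, drop = FALSE],
                                    V[, cols, drop = FALSE],
                                    mask = mask, scale = sc)
    M[, cols] <- heads[[i]]$O
  }
  list(Y = M %*% params$Wo, M = M, Q = Q, K = K, V = V, heads = heads)
}

multihead_backward <- function(dY, fwd, X, params) {
  dM <- dY %*% t(params$Wo)
  gWo <- crossprod(fwd$M, dY)
  dQ <- matrix(0, nrow(X), params$d)
  dK <- dQ; dV <- dQ
  for (i in seq_len(params$heads)) {
    cols <- head_cols(params, i)
    bk <- attention_backward(dM[, cols, drop = FALSE], fwd$heads[[i]],
                             fwd$Q[, cols, drop = FALSE],
                             fwd$K[, cols, drop = FALSE],
                             fwd$V[, cols, drop = FALSE])
    dQ[, cols] <- bk$dQ; dK[, cols] <- bk$dK; dV[, cols] <- bk$dV
  }
  dX <- dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv)
  list(dX = dX,
       grads = list(Wq = crossprod(X, dQ), Wk = crossprod(X, dK),
                    Wv = crossprod(X, dV), Wo = gWo))
}

#' Multihead self-attention over an encoded sequence
#'
#' Each head attends in its own `d/h`-dimensional projected subspace; the
#' head outputs are concatenated and linearly mixed. Masked positions take
#' no part as queries or keys and stay zero in the output.
#'
#' @param X an `encoded_sequence` from [encode_bilstm()], or a plain
#'   numeric matrix `n x d`.
#' @param params a [multihead_params()] object.
#' @return numeric matrix `n x d`.
#' @export
multihead <- function(X, params) {
  mask <- NULL
  if (inherits(X, "encoded_sequence")) { mask <- X$mask; X <- X$H }
  if (ncol(X) != params$d)
    stop(sprintf("input dim %d does not match model dim %d", ncol(X), params$d))
  n <- nrow(X)
  mask <- mask %||% rep(TRUE, n)
  nv <- sum(mask)
  Xv <- X[seq_len(nv), , drop = FALSE]
  out <- matrix(0, n, params$d)
  out[seq_len(nv), ] <- multihead_forward(Xv, params)$Y
  out
}

#' Pool token vectors to a fixed sentence representation
#'
#' Elementwise max (default) or mean over the unmasked rows.
#'
#' @param Y numeric matrix `n x d`.
#' @param mask logical vector of valid rows (`NULL` = all).
#' @param mode `"max"` or `"mean"`.
#' @return numeric vector of length `d` with attribute `pooling`.
#' @export
pool <- function(Y, mask = NULL, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  Y <- rbind(Y)
  mask <- mask %||% rep(TRUE, nrow(Y))
  if (!any(mask)) stop("cannot pool a fully masked sequence")
  Yv <- Y[mask, , drop = FALSE]
  v <- if (mode == "max") apply(Yv, 2L, max) else colMeans(Yv)
  structure(v, pooling = mode)
}

# pooling backward: route dv to contributing valid rows
pool_backward <- function(dv, Yv, mode) {
  n <- nrow(Yv)
  dY <- matrix(0, n, ncol(Yv))
  if (mode == "max") {
    amax <- max.col(t(Yv), ties.method = "first")
    dY[cbind(amax, seq_len(ncol(Yv)))] <- dv
  } else {
    dY <- matrix(rep(dv / n, each = n), n, ncol(Yv))
  }
  dY
}
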