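# shared fixtures and independent reference implementations used as
# oracles against the vectorized package code

tiny_instance <- function(tokens = c("a", "b", "c", "d", "e"),
                          drug = 1L, gene = 5L, mutation = 3L,
                          label = "response", breaks = 0L) {
  mk <- function(pos, id) list(entity_id = id, start = pos - 1L, end = pos)
  relation_instance("tiny", tokens, breaks,
                    list(drug = mk(drug, "drug_1"), gene = mk(gene, "gene_1"),
                         mutation = mk(mutation, "mut_1")),
                    label)
}

# brute-force scaled dot-product attention: explicit index loops
ref_attention <- function(Q, K, V, scale) {
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K)))
      s[j] <- sum(Q[i, ] * K[j, ]) / scale
    a <- exp(s - max(s)); a <- a / sum(a)
    for (j in seq_len(nrow(K)))
      out[i, ] <- out[i, ] + a[j] * V[j, ]
  }
  out
}

# per-head looped multihead reference
ref_multihead <- function(X, params) {
  dh <- params$d / params$heads
  sc <- nrekg:::attn_scale(params)
  M <- NULL
  for (i in seq_len(params$heads)) {
    cols <- ((i - 1) * dh + 1):(i * dh)
    Qi <- X %*% params$Wq[, cols]; Ki <- X %*% params$Wk[, cols]
    Vi <- X %*% params$Wv[, cols]
    M <- cbind(M, ref_attention(Qi, Ki, Vi, sc))
  }
  M %*% params$Wo
}

# finite-difference gradient check of the LSTM against backprop; returns
# the worst relative error over all weight matrices, biases and inputs
lstm_grad_check <- function(variant, n = 4L, din = 3L, hidden = 5L,
                            seed = 42L, eps = 1e-5) {
  set.seed(seed)
  p <- lstm_params(din, hidden, seed = seed)
  for (nm in c("b_i", "b_f", "b_o", "b_g"))
    p[[nm]] <- runif(hidden, -0.1, 0.1)
  X <- matrix(runif(n * din, -1, 1), n, din)
  w <- matrix(runif(n * hidden, -1, 1), n, hidden)
  loss <- function(pp, XX = X) sum(w * nrekg:::lstm_forward(XX, pp, variant)$H)
  fwd <- nrekg:::lstm_forward(X, p, variant)
  bk <- nrekg:::lstm_backward(w, fwd, p, variant)
  worst <- 0
  for (nm in names(bk$grads)) {
    num <- p[[nm]] * 0
    for (j in seq_along(p[[nm]])) {
      pp <- p; pp[[nm]][j] <- pp[[nm]][j] + eps; up <- loss(pp)
      pp[[nm]][j] <- pp[[nm]][j] - 2 * eps; dn <- loss(pp)
      num[j] <- (up - dn) / (2 * eps)
    }
    denom <- max(abs(num), 1e-6)
    worst <- max(worst, max(abs(num - bk$grads[[nm]])) / denom)
  }
  numX <- X * 0
  for (j in seq_along(X)) {
    Xp <- X; Xp[j] <- Xp[j] + eps; up <- loss(p, Xp)
    Xp[j] <- Xp[j] - 2 * eps; dn <- loss(p, Xp)
    numX[j] <- (up - dn) / (2 * eps)
  }
  max(worst, max(abs(numX - bk$dX)) / max(abs(numX), 1e-6))
}

# desk-scale model configuration shared by the end-to-end tests
small_config <- function(...) {
  base <- list(d_w = 32L, d_p = 8L, hidden = 32L, heads = 2L, k = 16L,
               seed = 4L)
  do.call(train_config, utils::modifyList(base, list(...)))
}
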