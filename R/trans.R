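#' Initialize translation-model parameters
#'
#' Entity and relation vectors start uniform in `[-6/sqrt(k), 6/sqrt(k)]`
#' (the classic TransE recipe). TransH relation normals are drawn then
#' normalized to unit length; TransR projection matrices start at the
#' identity; TransD projection vectors start small and dense so their
#' gradients are non-degenerate.
#'
#' @param kg a [knowledge_graph()].
#' @param variant one of `"TransE"`, `"TransH"`, `"TransR"`, `"TransD"`.
#' @param k embedding dimension (default 50).
#' @param gamma margin of the ranking loss (default 1).
#' @param p norm order, 1 or 2 (default 2).
#' @param seed integer seed.
#' @return object of class `kg_embeddings`.
#' @export
init_embeddings <- function(kg, variant = c("TransE", "TransH", "TransR", "TransD"),
                            k = 50L, gamma = 1, p = 2L, seed = 1L) {
  variant <- match.arg(variant)
  k <- stopifnot_scalar_int(k, "k")
  if (!p %in% c(1L, 2L)) stop("norm order p must be 1 or 2")
  ne <- length(kg$entities); nr <- length(kg$relations)
  with_seed(derive_seed(seed, "init"), {
    b <- 6 / sqrt(k)
    E <- matrix(stats::runif(ne * k, -b, b), ne, k)
    R <- matrix(stats::runif(nr * k, -b, b), nr, k)
    extras <- switch(variant,
      TransE = list(),
      TransH = {
        W <- matrix(stats::runif(nr * k, -b, b), nr, k)
        W <- W / sqrt(rowSums(W^2))
        list(normal = W, d = matrix(stats::runif(nr * k, -b, b), nr, k))
      },
      TransR = list(M = replicate(nr, diag(k), simplify = FALSE)),
      TransD = list(Ep = matrix(stats::runif(ne * k, -0.5, 0.5) / sqrt(k), ne, k),
                    Rp = matrix(stats::runif(nr * k, -0.5, 0.5) / sqrt(k), nr, k)))
    structure(c(list(variant = variant, k = k, gamma = gamma, p = as.integer(p),
                     entities = kg$entities, relations = kg$relations,
                     E = E, R = R, loss_history = numeric(0)),
                extras),
              class = "kg_embeddings")
  })
}

#' @export
print.kg_embeddings <- function(x, ...) {
  cat(sprintf("<kg_embeddings %s> k=%d, gamma=%g, p=%d; %d entities, %d relations\n",
              x$variant, x$k, x$gamma, x$p, nrow(x$E), nrow(x$R)))
  if (length(x$loss_history))
    cat(sprintf("  trained %d epochs, final margin loss %.4f\n",
                length(x$loss_history), utils::tail(x$loss_history, 1)))
  invisible(x)
}

lp_norm <- function(v, p) if (p == 1L) sum(abs(v)) else sqrt(sum(v * v))

# difference vector h~ + r - t~ in the variant's scoring space
translation_residual <- function(params, h, r, t) {
  E <- params$E; R <- params$R
  switch(params$variant,
    TransE = E[h, ] + R[r, ] - E[t, ],
    TransH = {
      w <- params$normal[r, ]
      hp <- E[h, ] - sum(w * E[h, ]) * w
      tp <- E[t, ] - sum(w * E[t, ]) * w
      hp + params$d[r, ] - tp
    },
    TransR = {
      M <- params$M[[r]]
      drop(E[h, ] %*% M) + R[r, ] - drop(E[t, ] %*% M)
    },
    TransD = {
      rp <- params$Rp[r, ]
      hproj <- E[h, ] + sum(params$Ep[h, ] * E[h, ]) * rp
      tproj <- E[t, ] + sum(params$Ep[t, ] * E[t, ]) * rp
      hproj + R[r, ] - tproj
    })
}

#' Dissimilarity score of a knowledge-graph triple
#'
#' Scores `||h~ + r - t~||_p` in the variant's projection space; lower
#' means more plausible. With TransR and identity projection matrices the
#' score coincides with TransE on the same vectors.
#'
#' @param params a [kg_embeddings()] object.
#' @param h,r,t indices into the entity/relation vocabularies, or a single
#'   length-3 integer vector passed as `h`.
#' @return nonnegative scalar.
#' @export
score_triple <- function(params, h, r = NULL, t = NULL) {
  if (is.null(r)) { r <- h[2L]; t <- h[3L]; h <- h[1L] }
  ne <- nrow(params$E); nr <- nrow(params$R)
  if (h < 1L || h > ne || t < 1L || t > ne || r < 1L || r > nr)
    stop("triple index out of range")
  lp_norm(translation_residual(params, h, r, t), params$p)
}

# scores of (h, r, t') for every candidate tail t' (vectorized over tails)
score_all_tails <- function(params, h, r) {
  E <- params$E; R <- params$R; p <- params$p
  D <- switch(params$variant,
    TransE = sweep(-E, 2L, E[h, ] + R[r, ], `+`),
    TransH = {
      w <- params$normal[r, ]
      hp <- E[h, ] - sum(w * E[h, ]) * w
      Tp <- E - tcrossprod(drop(E %*% w), w)
      sweep(-Tp, 2L, hp + params$d[r, ], `+`)
    },
    TransR = {
      M <- params$M[[r]]
      sweep(-(E %*% M), 2L, drop(E[h, ] %*% M) + R[r, ], `+`)
    },
    TransD = {
      rp <- params$Rp[r, ]
      hproj <- E[h, ] + sum(params$Ep[h, ] * E[h, ]) * rp
      Tproj <- E + tcrossprod(rowSums(params$Ep * E), rp)
      sweep(-Tproj, 2L, hproj + R[r, ], `+`)
    })
  if (p == 1L) rowSums(abs(D)) else sqrt(rowSums(D * D))
}

#' Sample a filtered negative triple
#'
#' Corrupts either the head or the tail (each side with probability 1/2)
#' with an entity drawn uniformly, rejecting corruptions that are known
#' facts; after `max_retries` rejected draws both sides are scanned
#' exhaustively.
#'
#' @param kg a [knowledge_graph()].
#' @param triple length-3 integer vector `(h, r, t)`.
#' @param max_retries bounded rejection-sampling budget (default 100).
#' @return length-3 integer vector, guaranteed not in the fact set.
#' @export
sample_negative <- function(kg, triple, max_retries = 100L) {
  ne <- length(kg$entities)
  if (ne < 2L) stop("need at least 2 entities to corrupt a triple")
  triple <- unname(triple)
  h <- triple[1L]; r <- triple[2L]; t <- triple[3L]
  side <- if (stats::runif(1) < 0.5) "head" else "tail"
  for (i in seq_len(max_retries)) {
    e <- sample.int(ne, 1L)
    if (side == "head" && e != h && !has_triple(kg, e, r, t))
      return(c(e, r, t))
    if (side == "tail" && e != t && !has_triple(kg, h, r, e))
      return(c(h, r, e))
  }
  # exhaustive fallback over both sides, randomized order
  for (e in sample.int(ne)) {
    if (e != h && !has_triple(kg, e, r, t)) return(c(e, r, t))
    if (e != t && !has_triple(kg, h, r, e)) return(c(h, r, e))
  }
  stop("no valid corruption exists for this triple (complete KG)")
}

#' Margin ranking loss over matched positive/negative triples
#'
#' `mean(max(0, gamma + d(pos) - d(neg)))`: the hinge is satisfied once a
#' corrupted triple scores worse than its fact by at least the margin.
#'
#' @param params a [kg_embeddings()] object.
#' @param positives,negatives integer matrices with columns `(h, r, t)`,
#'   row-aligned.
#' @param gamma margin; defaults to the margin stored in `params`.
#' @return nonnegative scalar.
#' @export
margin_loss <- function(params, positives, negatives, gamma = params$gamma) {
  positives <- rbind(positives); negatives <- rbind(negatives)
  if (nrow(positives) != nrow(negatives))
    stop("positives and negatives must be matched row for row")
  d_pos <- vapply(seq_len(nrow(positives)),
                  function(i) score_triple(params, positives[i, ]), numeric(1))
  d_neg <- vapply(seq_len(nrow(negatives)),
                  function(i) score_triple(params, negatives[i, ]), numeric(1))
  mean(pmax(0, gamma + d_pos - d_neg))
}

# gradient of ||v||_p wrt v
norm_grad <- function(v, p) {
  if (p == 1L) return(sign(v))
  nv <- sqrt(sum(v * v))
  if (nv < 1e-12) return(v * 0)
  v / nv
}

# apply the gradient of d(h,r,t) (coefficient `coef` = +1 for the positive
# triple, -1 for the negative) to the parameter tables in `env`
apply_triple_grad <- function(env, h, r, t, coef, lr) {
  p <- env$params
  u <- norm_grad(translation_residual(p, h, r, t), p$p) * coef * lr
  switch(p$variant,
    TransE = {
      env$params$E[h, ] <- p$E[h, ] - u
      env$params$E[t, ] <- p$E[t, ] + u
      env$params$R[r, ] <- p$R[r, ] - u
    },
    TransH = {
      w <- p$normal[r, ]
      uh <- u - sum(w * u) * w          # chain through (I - w w^T)
      env$params$E[h, ] <- p$E[h, ] - uh
      env$params$E[t, ] <- p$E[t, ] + uh
      env$params$d[r, ] <- p$d[r, ] - u
      # d/dw of (w.x)w is x w^T + (w.x) I; transpose-times-u per entity
      gw <- -(sum(u * w) * p$E[h, ] + sum(w * p$E[h, ]) * u) +
             (sum(u * w) * p$E[t, ] + sum(w * p$E[t, ]) * u)
      wn <- w - gw
      env$params$normal[r, ] <- wn / max(1e-12, sqrt(sum(wn^2)))
    },
    TransR = {
      M <- p$M[[r]]
      env$params$E[h, ] <- p$E[h, ] - drop(M %*% u)
      env$params$E[t, ] <- p$E[t, ] + drop(M %*% u)
      env$params$R[r, ] <- p$R[r, ] - u
      env$params$M[[r]] <- M - outer(p$E[h, ] - p$E[t, ], u)
    },
    TransD = {
      rp <- p$Rp[r, ]; urp <- sum(u * rp)
      env$params$E[h, ] <- p$E[h, ] - (u + urp * p$Ep[h, ])
      env$params$E[t, ] <- p$E[t, ] + (u + urp * p$Ep[t, ])
      env$params$R[r, ] <- p$R[r, ] - u
      env$params$Ep[h, ] <- p$Ep[h, ] - urp * p$E[h, ]
      env$params$Ep[t, ] <- p$Ep[t, ] + urp * p$E[t, ]
      env$params$Rp[r, ] <- p$Rp[r, ] -
        (sum(p$Ep[h, ] * p$E[h, ]) - sum(p$Ep[t, ] * p$E[t, ])) * u
    })
  invisible(NULL)
}

#' Train knowledge-graph embeddings under the margin ranking loss
#'
#' Minibatch stochastic gradient descent: each fact is paired with one
#' filtered negative per pass, the hinge `[gamma + d(pos) - d(neg)]+` is
#' minimized, and entity vectors are projected back onto the unit ball at
#' the end of every epoch. Deterministic given the seed.
#'
#' @param kg a [knowledge_graph()].
#' @param variant translation variant, see [init_embeddings()].
#' @param k embedding dimension.
#' @param gamma margin.
#' @param p norm order (1 or 2).
#' @param epochs number of passes over the fact set.
#' @param batch_size minibatch size (negatives are resampled per pass).
#' @param learning_rate SGD step size.
#' @param lr_decay hyperbolic decay rate: epoch `e` uses
#'   `learning_rate / (1 + lr_decay * (e - 1))`. Default 0 (constant).
#' @param seed integer seed.
#' @return a trained [init_embeddings()] object with `loss_history`
#'   (mean margin loss per epoch).
#' @export
train_embeddings <- function(kg, variant = "TransE", k = 50L, gamma = 1,
                             p = 2L, epochs = 100L, batch_size = 32L,
                             learning_rate = 0.01, lr_decay = 0, seed = 1L) {
  epochs <- stopifnot_scalar_int(epochs, "epochs", min = 0L)
  batch_size <- stopifnot_scalar_int(batch_size, "batch_size")
  params <- init_embeddings(kg, variant, k = k, gamma = gamma, p = p,
                            seed = seed)
  if (epochs == 0L) return(params)
  trip <- kg$triples
  m <- nrow(trip)
  env <- new.env(parent = emptyenv())
  env$params <- params
  with_seed(derive_seed(seed, "negative"), {
    losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      lr <- learning_rate / (1 + lr_decay * (ep - 1))
      ord <- sample.int(m)
      ep_loss <- 0
      for (start in seq(1L, m, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, m)]
        for (i in idx) {
          pos <- trip[i, ]
          neg <- sample_negative(kg, pos)
          d_pos <- score_triple(env$params, pos)
          d_neg <- score_triple(env$params, neg)
          hinge <- env$params$gamma + d_pos - d_neg
          ep_loss <- ep_loss + max(0, hinge)
          if (hinge > 0) {
            apply_triple_grad(env, pos[1L], pos[2L], pos[3L], +1, lr)
            apply_triple_grad(env, neg[1L], neg[2L], neg[3L], -1, lr)
          }
        }
      }
      # project entities back onto the unit ball
      en <- sqrt(rowSums(env$params$E^2))
      scale <- pmin(1, 1 / pmax(en, 1e-12))
      env$params$E <- env$params$E * scale
      losses[ep] <- ep_loss / m
    }
    env$params$loss_history <- losses
  })
  env$params
}

#' Relation vector between two entities
#'
#' The side information consumed by the relation classifier: the
#' difference `E_tail - E_head` of the learned entity embeddings (for the
#' drug-gene slot, gene minus drug; for drug-mutation, mutation minus
#' drug). Entities absent from the KG contribute a zero vector, which is
#' equivalent to running without side information for that instance.
#'
#' @param params a [kg_embeddings()] object, or `NULL` (returns zeros of
#'   length `k`).
#' @param head_entity_id,tail_entity_id entity identifiers (names).
#' @param k dimension used when `params` is `NULL` (default 50).
#' @return numeric vector of length `params$k`.
#' @export
relation_vector <- function(params, head_entity_id, tail_entity_id, k = 50L) {
  if (is.null(params)) return(numeric(k))
  hi <- match(head_entity_id, params$entities)
  ti <- match(tail_entity_id, params$entities)
  if (is.na(hi) || is.na(ti)) return(numeric(params$k))
  params$E[ti, ] - params$E[hi, ]
}

#' Filtered link-prediction diagnostics
#'
#' For each held-out triple the true tail is ranked among all entities by
#' dissimilarity; competitors that are themselves known facts are filtered
#' out. Reports mean rank, hits@1 and hits@10.
#'
#' @param params a [kg_embeddings()] object.
#' @param kg the [knowledge_graph()] providing the filter set.
#' @param heldout integer matrix with columns `(h, r, t)`.
#' @return list with `mean_rank`, `hits1`, `hits10`.
#' @export
evaluate_link_prediction <- function(params, kg, heldout) {
  heldout <- rbind(heldout)
  if (nrow(heldout) == 0L) stop("empty held-out set")
  ranks <- vapply(seq_len(nrow(heldout)), function(i) {
    h <- heldout[i, 1L]; r <- heldout[i, 2L]; t <- heldout[i, 3L]
    sc <- score_all_tails(params, h, r)
    keep <- rep(TRUE, length(sc))
    for (e in seq_along(sc))
      if (e != t && has_triple(kg, h, r, e)) keep[e] <- FALSE
    sum(sc[keep] < sc[t]) + 1
  }, numeric(1))
  list(mean_rank = mean(ranks), hits1 = mean(ranks <= 1),
       hits10 = mean(ranks <= 10))
}

#' Save trained embeddings as a JSON manifest with inline arrays
#' @param params a [kg_embeddings()] object.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(params, path) {
  obj <- list(variant = params$variant, k = params$k, gamma = params$gamma,
              p = params$p, entities = params$entities,
              relations = params$relations, E = params$E, R = params$R)
  for (fld in intersect(c("normal", "d", "M", "Ep", "Rp"), names(params)))
    obj[[fld]] <- params[[fld]]
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load embeddings written by [write_embeddings()]
#' @param path `.json` path.
#' @return a [kg_embeddings()] object.
#' @export
read_embeddings <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  obj$E <- as.matrix(obj$E); obj$R <- as.matrix(obj$R)
  for (fld in intersect(c("normal", "d", "Ep", "Rp"), names(obj)))
    obj[[fld]] <- as.matrix(obj[[fld]])
  if (!is.null(obj$M)) obj$M <- lapply(seq_len(dim(obj$M)[1]),
                                       function(i) matrix(obj$M[i, , ], obj$k, obj$k))
  obj$p <- as.integer(obj$p); obj$k <- as.integer(obj$k)
  obj$loss_history <- numeric(0)
  structure(obj, class = "kg_embeddings")
}
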