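# End-to-end training of the relation classifier: embeddings -> Bi-LSTM
# -> multihead attention -> pooling -> [sentence ; KG relation vectors]
# -> softmax, optimized by Adam on minibatches with analytic gradients.

# ---- parameter store ------------------------------------------------------

# all trainable arrays live in one flat named list `theta`; helper views
# rebuild the per-component parameter lists expected by the layer code
lstm_view <- function(theta, prefix, input_dim, hidden) {
  p <- list(input_dim = input_dim, hidden = hidden)
  for (nm in c("W_xi", "W_hi", "W_xf", "W_hf", "W_xo", "W_ho", "W_xg", "W_hg",
               "b_i", "b_f", "b_o", "b_g"))
    p[[nm]] <- theta[[paste0(prefix, nm)]]
  class(p) <- "lstm_params"
  p
}

attn_view <- function(theta, d, heads, softmax_scale) {
  structure(list(d = d, heads = heads, Wq = theta$at_Wq, Wk = theta$at_Wk,
                 Wv = theta$at_Wv, Wo = theta$at_Wo,
                 softmax_scale = softmax_scale),
            class = "multihead_params")
}

init_theta <- function(vocab, n_classes, cfg, word_vectors = NULL) {
  tables <- embedding_tables(vocab, d_w = cfg$d_w, d_p = cfg$d_p,
                             max_distance = cfg$max_distance,
                             word_vectors = word_vectors,
                             seed = cfg$seed)
  input_dim <- cfg$d_w + 3L * cfg$d_p
  d <- 2L * cfg$hidden
  lf <- lstm_params(input_dim, cfg$hidden, seed = cfg$seed)
  lb <- lstm_params(input_dim, cfg$hidden, seed = cfg$seed + 1L)
  at <- multihead_params(d, cfg$heads, seed = cfg$seed,
                         softmax_scale = cfg$softmax_scale)
  cl <- classifier_params(d + 2L * cfg$k, n_classes, seed = cfg$seed)
  theta <- list(word = tables$word, pos_drug = tables$pos$drug,
                pos_gene = tables$pos$gene, pos_mutation = tables$pos$mutation)
  for (nm in setdiff(names(lf), c("input_dim", "hidden")))
    theta[[paste0("lf_", nm)]] <- lf[[nm]]
  for (nm in setdiff(names(lb), c("input_dim", "hidden")))
    theta[[paste0("lb_", nm)]] <- lb[[nm]]
  theta$at_Wq <- at$Wq; theta$at_Wk <- at$Wk
  theta$at_Wv <- at$Wv; theta$at_Wo <- at$Wo
  theta$cl_W <- cl$W; theta$cl_b <- cl$b
  list(theta = theta, vocab = tables$vocab)
}

zero_grads <- function(theta) lapply(theta, function(x) x * 0)

# ---- per-instance forward/backward ---------------------------------------

# static (table-independent) description of one instance
prepare_instance <- function(inst, vocab, cfg, kg_params, use_kg) {
  feats <- compute_position_features(inst, cfg$max_distance)
  wr <- match(inst$tokens, vocab)
  wr[is.na(wr)] <- length(vocab) + 1L
  off <- cfg$max_distance + 1L
  m <- inst$mentions
  k <- cfg$k
  r_dg <- numeric(k); r_dm <- numeric(k)
  if (use_kg) {
    if (!is.null(m$gene))
      r_dg <- relation_vector(kg_params, m$drug$entity_id, m$gene$entity_id)
    r_dm <- relation_vector(kg_params, m$drug$entity_id, m$mutation$entity_id)
  }
  list(word_rows = wr,
       pos_rows = list(drug = feats[, "drug"] + off,
                       gene = feats[, "gene"] + off,
                       mutation = feats[, "mutation"] + off),
       side = c(r_dg, r_dm), n = length(inst$tokens),
       label = inst$label)
}

forward_instance <- function(theta, prep, cfg, drop = NULL, keep_cache = FALSE) {
  X <- cbind(theta$word[prep$word_rows, , drop = FALSE],
             theta$pos_drug[prep$pos_rows$drug, , drop = FALSE],
             theta$pos_gene[prep$pos_rows$gene, , drop = FALSE],
             theta$pos_mutation[prep$pos_rows$mutation, , drop = FALSE])
  input_dim <- ncol(X); hidden <- cfg$hidden; d <- 2L * hidden
  lf <- lstm_view(theta, "lf_", input_dim, hidden)
  lb <- lstm_view(theta, "lb_", input_dim, hidden)
  fwd <- lstm_forward(X, lf, cfg$gate_variant, h_drop = drop$fwd)
  rev_idx <- rev(seq_len(prep$n))
  bwd <- lstm_forward(X[rev_idx, , drop = FALSE], lb, cfg$gate_variant,
                      h_drop = drop$bwd)
  Hbi <- cbind(fwd$H, bwd$H[rev_idx, , drop = FALSE])
  at <- attn_view(theta, d, cfg$heads, cfg$softmax_scale)
  af <- multihead_forward(Hbi, at)
  B <- pool(af$Y, mode = cfg$pooling)
  Bdrop <- if (is.null(drop$out)) as.numeric(B) else as.numeric(B) * drop$out
  feat <- c(Bdrop, prep$side)
  probs <- softmax_vec(drop(feat %*% theta$cl_W) + theta$cl_b)
  out <- list(probs = probs)
  if (keep_cache)
    out$cache <- list(X = X, lf = lf, lb = lb, fwd = fwd, bwd = bwd,
                      Hbi = Hbi, at = at, af = af, B = as.numeric(B),
                      feat = feat, rev_idx = rev_idx)
  out
}

backward_instance <- function(theta, grads, prep, cfg, fw, gold_idx, drop,
                              weight = 1) {
  cc <- fw$cache
  dz <- fw$probs
  dz[gold_idx] <- dz[gold_idx] - 1
  dz <- dz * weight
  grads$cl_W <- grads$cl_W + outer(cc$feat, dz)
  grads$cl_b <- grads$cl_b + dz
  dfeat <- drop(theta$cl_W %*% dz)
  d <- 2L * cfg$hidden
  dB <- dfeat[seq_len(d)]
  if (!is.null(drop$out)) dB <- dB * drop$out
  dY <- pool_backward(dB, cc$af$Y, cfg$pooling)
  ab <- multihead_backward(dY, cc$af, cc$Hbi, cc$at)
  grads$at_Wq <- grads$at_Wq + ab$grads$Wq
  grads$at_Wk <- grads$at_Wk + ab$grads$Wk
  grads$at_Wv <- grads$at_Wv + ab$grads$Wv
  grads$at_Wo <- grads$at_Wo + ab$grads$Wo
  dHf <- ab$dX[, seq_len(cfg$hidden), drop = FALSE]
  dHb <- ab$dX[, cfg$hidden + seq_len(cfg$hidden), drop = FALSE]
  bkf <- lstm_backward(dHf, cc$fwd, cc$lf, cfg$gate_variant, h_drop = drop$fwd)
  bkb <- lstm_backward(dHb[cc$rev_idx, , drop = FALSE], cc$bwd, cc$lb,
                       cfg$gate_variant, h_drop = drop$bwd)
  for (nm in names(bkf$grads)) {
    grads[[paste0("lf_", nm)]] <- grads[[paste0("lf_", nm)]] + bkf$grads[[nm]]
    grads[[paste0("lb_", nm)]] <- grads[[paste0("lb_", nm)]] + bkb$grads[[nm]]
  }
  dX <- bkf$dX + bkb$dX[cc$rev_idx, , drop = FALSE]
  d_w <- cfg$d_w; d_p <- cfg$d_p
  if (cfg$train_word_embeddings) {
    gw <- rowsum(dX[, seq_len(d_w), drop = FALSE], prep$word_rows)
    rows <- as.integer(rownames(gw))
    grads$word[rows, ] <- grads$word[rows, , drop = FALSE] + gw
  }
  col0 <- d_w
  for (role in c("drug", "gene", "mutation")) {
    gp <- rowsum(dX[, col0 + seq_len(d_p), drop = FALSE], prep$pos_rows[[role]])
    rows <- as.integer(rownames(gp))
    nm <- paste0("pos_", role)
    grads[[nm]][rows, ] <- grads[[nm]][rows, , drop = FALSE] + gp
    col0 <- col0 + d_p
  }
  grads
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(theta)
  list(m = zero_grads(theta), v = zero_grads(theta), t = 0L)

adam_step <- function(theta, grads, state, lr, clip = 5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(clip) && gn > clip)
    grads <- lapply(grads, function(g) g * (clip / gn))
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(theta)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    theta[[nm]] <- theta[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(theta = theta, state = state)
}

# ---- training loop --------------------------------------------------------

#' Train the relation-extraction model
#'
#' End-to-end Adam training of the word/position embedding tables, the
#' bidirectional LSTM, the multihead attention and the softmax classifier
#' on minibatches, with cross-entropy loss. Knowledge-graph relation
#' vectors (differences of trained entity embeddings) enter as frozen
#' side information. After every epoch the model is scored on the
#' validation set and the snapshot with the best validation accuracy is
#' returned; without a validation set the final epoch wins.
#'
#' For binary (drug-mutation) corpora the KG is switched off by default,
#' since a relation-typed KG vector would hand the classifier the label;
#' set `allow_binary_kg = TRUE` in the config to override.
#'
#' @param train an [nre_dataset()].
#' @param val optional validation [nre_dataset()] (may be `NULL`).
#' @param kg_params optional trained [kg_embeddings()].
#' @param config a [train_config()].
#' @param word_vectors optional [read_word_vectors()] result.
#' @param vocab optional vocabulary; defaults to the training tokens.
#' @param quiet suppress per-epoch progress lines.
#' @return object of class `nre_model`.
#' @export
train_model <- function(train, val = NULL, kg_params = NULL,
                        config = train_config(), word_vectors = NULL,
                        vocab = NULL, quiet = TRUE) {
  if (!inherits(train, "nre_dataset")) stop("train must be an nre_dataset")
  cfg <- config
  scheme <- train$scheme
  use_kg <- !is.null(kg_params)
  if (use_kg && scheme$mode == "binary" && !cfg$allow_binary_kg) {
    message("binary scheme: ignoring KG side information (see ?train_model)")
    use_kg <- FALSE
  }
  if (use_kg && kg_params$k != cfg$k)
    stop(sprintf("config k=%d but kg_params k=%d", cfg$k, kg_params$k))
  classes <- scheme$classes
  vocab <- vocab %||% unique(unlist(lapply(train$instances, `[[`, "tokens")))
  ini <- init_theta(vocab, length(classes), cfg, word_vectors)
  theta <- ini$theta; vocab <- ini$vocab
  preps <- lapply(train$instances, prepare_instance, vocab = vocab, cfg = cfg,
                  kg_params = kg_params, use_kg = use_kg)
  golds <- match(vapply(train$instances, `[[`, character(1), "label"), classes)
  val_preps <- NULL; val_golds <- NULL
  if (!is.null(val) && length(val$instances)) {
    val_preps <- lapply(val$instances, prepare_instance, vocab = vocab,
                        cfg = cfg, kg_params = kg_params, use_kg = use_kg)
    val_golds <- match(vapply(val$instances, `[[`, character(1), "label"),
                       classes)
  }
  opt <- adam_init(theta)
  n <- length(preps)
  H <- cfg$hidden; d <- 2L * H
  keep_r <- 1 - cfg$recurrent_dropout
  keep_o <- 1 - cfg$output_dropout
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_accuracy = numeric(0))
  best <- list(theta = theta, acc = -Inf, epoch = 0L)
  with_seed(derive_seed(cfg$seed, "dropout"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        grads <- zero_grads(theta)
        w <- 1 / length(idx)
        for (i in idx) {
          drop_masks <- list(
            fwd = if (keep_r < 1) stats::rbinom(H, 1L, keep_r) / keep_r,
            bwd = if (keep_r < 1) stats::rbinom(H, 1L, keep_r) / keep_r,
            out = if (keep_o < 1) stats::rbinom(d, 1L, keep_o) / keep_o)
          fw <- forward_instance(theta, preps[[i]], cfg, drop = drop_masks,
                                 keep_cache = TRUE)
          ep_loss <- ep_loss + cross_entropy(fw$probs, golds[i])
          grads <- backward_instance(theta, grads, preps[[i]], cfg, fw,
                                     golds[i], drop_masks, weight = w)
        }
        st <- adam_step(theta, grads, opt, cfg$learning_rate, cfg$grad_clip)
        theta <- st$theta; opt <- st$state
      }
      ep_loss <- ep_loss / n
      val_acc <- NA_real_
      if (!is.null(val_preps)) {
        pred <- vapply(val_preps, function(p)
          which.max(forward_instance(theta, p, cfg)$probs), integer(1))
        val_acc <- mean(pred == val_golds)
        if (val_acc > best$acc)
          best <- list(theta = theta, acc = val_acc, epoch = ep)
      }
      history[ep, ] <- list(ep, ep_loss, val_acc)
      if (!quiet)
        message(sprintf("epoch %d: train loss %.4f, val accuracy %s", ep,
                        ep_loss, ifelse(is.na(val_acc), "-",
                                        sprintf("%.3f", val_acc))))
    }
  })
  if (is.finite(best$acc)) theta <- best$theta
  structure(list(theta = theta, vocab = vocab, config = cfg, scheme = scheme,
                 classes = classes, kg_params = if (use_kg) kg_params,
                 use_kg = use_kg, history = history,
                 best_epoch = if (is.finite(best$acc)) best$epoch
                              else cfg$epochs),
            class = "nre_model")
}

#' @export
print.nre_model <- function(x, ...) {
  cat(sprintf("<nre_model> %s scheme (%d classes), %s%s\n", x$scheme$mode,
              length(x$classes),
              if (x$use_kg) paste0("with ", x$kg_params$variant, " KG")
              else "no KG",
              sprintf(", hidden %d x2, %d heads", x$config$hidden,
                      x$config$heads)))
  if (nrow(x$history))
    cat(sprintf("  trained %d epochs, kept epoch %d\n", nrow(x$history),
                x$best_epoch))
  invisible(x)
}

#' @export
summary.nre_model <- function(object, ...) {
  print(object)
  cat("training history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' Predict relation labels for new instances
#'
#' @param object an `nre_model`.
#' @param newdata an [nre_dataset()] or a single [relation_instance()].
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param ... unused.
#' @return character vector of labels or a numeric probability matrix with
#'   one row per instance. Argmax ties break toward the lowest class index.
#' @export
predict.nre_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "relation_instance"))
    newdata <- nre_dataset(list(newdata), object$scheme)
  cfg <- object$config
  preps <- lapply(newdata$instances, prepare_instance, vocab = object$vocab,
                  cfg = cfg, kg_params = object$kg_params,
                  use_kg = object$use_kg)
  P <- t(vapply(preps, function(p)
    forward_instance(object$theta, p, cfg)$probs,
    numeric(length(object$classes))))
  colnames(P) <- object$classes
  if (type == "prob") P else object$classes[max.col(P, ties.method = "first")]
}

#' Evaluate a trained model on a test set
#'
#' @param model an `nre_model`.
#' @param test an [nre_dataset()] sharing the model's scheme.
#' @return an [eval_report()] with length-bucket accuracies.
#' @export
evaluate_model <- function(model, test) {
  if (!identical(test$scheme$mode, model$scheme$mode))
    stop("test set scheme does not match the model")
  gold <- vapply(test$instances, `[[`, character(1), "label")
  pred <- predict(model, test)
  eval_report(gold, pred, model$classes, lengths = instance_lengths(test))
}

#' Five-fold cross-validation of the full pipeline
#'
#' Splits the corpus with [split_folds()], trains one model per fold
#' (validation used for best-epoch selection) and reports per-fold test
#' evaluations plus their arithmetic mean accuracy.
#'
#' @param dataset an [nre_dataset()].
#' @param kg_params optional [kg_embeddings()].
#' @param config a [train_config()].
#' @param k folds (default 5).
#' @param validation_size requested per-fold validation size (default 200,
#'   scaled down on small corpora; see [split_folds()]).
#' @param quiet passed to [train_model()].
#' @return list with `mean_accuracy`, `fold_reports`, `folds`.
#' @export
cross_validate <- function(dataset, kg_params = NULL, config = train_config(),
                           k = 5L, validation_size = 200L, quiet = TRUE) {
  folds <- split_folds(dataset, k = k, validation_size = validation_size,
                       seed = config$seed)
  reports <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    model <- train_model(dataset[f$train],
                         val = if (length(f$validation)) dataset[f$validation],
                         kg_params = kg_params, config = config, quiet = quiet)
    reports[[i]] <- evaluate_model(model, dataset[f$test])
  }
  list(mean_accuracy = mean(vapply(reports, `[[`, numeric(1), "accuracy")),
       fold_reports = reports, folds = folds)
}
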