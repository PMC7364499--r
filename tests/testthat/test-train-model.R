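test_that("a tiny separable corpus is learned and training is deterministic", {
  ds <- generate_corpus(corpus_spec(n_instances = 48L, vocab_size = 40L,
                                    sentence_length = c(5L, 8L),
                                    signal_strength = 1, seed = 21L))
  cfg <- small_config(epochs = 8L, learning_rate = 0.01,
                      recurrent_dropout = 0, output_dropout = 0)
  m <- train_model(ds, config = cfg)
  expect_s3_class(m, "nre_model")
  expect_lt(utils::tail(m$history$train_loss, 1L), m$history$train_loss[1L])
  expect_gt(evaluate_model(m, ds)$accuracy, 0.8)   # fits its own train set
  m2 <- train_model(ds, config = cfg)
  expect_identical(predict(m, ds), predict(m2, ds))
  P <- predict(m, ds, type = "prob")
  expect_equal(rowSums(P), rep(1, 48L), tolerance = 1e-9)
  expect_equal(colnames(P), ds$scheme$classes)
})

test_that("validation-based snapshot selection returns the best epoch", {
  ds <- generate_corpus(corpus_spec(n_instances = 40L, vocab_size = 40L,
                                    sentence_length = c(5L, 8L),
                                    signal_strength = 1, seed = 22L))
  cfg <- small_config(epochs = 2L, recurrent_dropout = 0, output_dropout = 0)
  m <- train_model(ds[1:30], val = ds[31:40], config = cfg)
  expect_true(m$best_epoch %in% 1:2)
  expect_equal(nrow(m$history), 2L)
  expect_false(anyNA(m$history$val_accuracy))
})

test_that("binary corpora drop KG side information by default", {
  gen <- generate_kg(kg_spec(seed = 3L))
  kgp <- train_embeddings(gen$kg, "TransE", k = 16L, epochs = 2L, seed = 1L)
  ds <- generate_corpus(corpus_spec(n_instances = 12L, scheme_mode = "binary",
                                    sentence_length = c(5L, 8L), seed = 5L))
  cfg <- small_config(epochs = 1L)
  expect_message(m <- train_model(ds, kg_params = kgp, config = cfg),
                 "ignoring KG")
  expect_false(m$use_kg)
  expect_error(train_model(ds, kg_params = kgp,
                           config = small_config(epochs = 1L, k = 8L,
                                                 allow_binary_kg = TRUE)),
               "kg_params k")
})

test_that("zeroed KG coordinates reproduce the no-KG logits exactly", {
  ds <- generate_corpus(corpus_spec(n_instances = 10L, vocab_size = 40L,
                                    sentence_length = c(5L, 8L), seed = 23L))
  gen <- generate_kg(kg_spec(seed = 3L))
  kgp <- train_embeddings(gen$kg, "TransE", k = 16L, epochs = 2L, seed = 1L)
  cfg <- small_config(epochs = 1L, recurrent_dropout = 0, output_dropout = 0)
  m <- train_model(ds, kg_params = kgp, config = cfg)
  d <- 2L * cfg$hidden
  # zero the classifier rows that read the relation-vector coordinates:
  # predictions must coincide with zeroing the KG vectors themselves
  m_zero_w <- m
  m_zero_w$theta$cl_W[(d + 1L):nrow(m$theta$cl_W), ] <- 0
  m_zero_kg <- m_zero_w
  m_zero_kg$use_kg <- FALSE
  m_zero_kg$kg_params <- NULL
  expect_equal(predict(m_zero_w, ds, type = "prob"),
               predict(m_zero_kg, ds, type = "prob"), tolerance = 1e-12)
})

test_that("cross-validation averages per-fold accuracies over a partition", {
  ds <- generate_corpus(corpus_spec(n_instances = 40L, vocab_size = 40L,
                                    sentence_length = c(5L, 8L),
                                    signal_strength = 1, seed = 24L))
  cfg <- small_config(epochs = 2L, recurrent_dropout = 0, output_dropout = 0)
  cv <- cross_validate(ds, config = cfg, k = 2L, validation_size = 0L)
  expect_length(cv$fold_reports, 2L)
  accs <- vapply(cv$fold_reports, `[[`, numeric(1), "accuracy")
  expect_equal(cv$mean_accuracy, mean(accs))
  expect_equal(sort(c(cv$folds[[1]]$test, cv$folds[[2]]$test)), 1:40)
  expect_identical(split_folds(40L, 2L, 0L, seed = cfg$seed), cv$folds)
})

test_that("evaluation rejects a scheme mismatch", {
  ds <- generate_corpus(corpus_spec(n_instances = 10L,
                                    sentence_length = c(5L, 8L), seed = 25L))
  bin <- generate_corpus(corpus_spec(n_instances = 10L, scheme_mode = "binary",
                                     sentence_length = c(5L, 8L), seed = 25L))
  cfg <- small_config(epochs = 1L)
  m <- train_model(ds, config = cfg)
  expect_error(evaluate_model(m, bin), "scheme")
})
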