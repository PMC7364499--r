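test_that("triple files parse with set semantics and first-seen vocabularies", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gefitinib\tsensitivity\tEGFR", f)
  kg <- read_triples(f)
  expect_length(kg$entities, 2L)
  expect_length(kg$relations, 1L)
  expect_equal(nrow(kg$triples), 1L)
  writeLines(rep("gefitinib\tsensitivity\tEGFR", 2L), f)
  expect_equal(nrow(read_triples(f)$triples), 1L)
  gen <- generate_kg(kg_spec(n_drug = 20L, n_gene = 30L, n_mutation = 30L,
                             relations = c("sensitivity", "response",
                                           "resistance"),
                             triples_per_relation = 20L, seed = 2L))
  expect_equal(nrow(gen$manifest$planted), 60L)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_triples(gen$kg, f2)
  back <- read_triples(f2)
  expect_equal(length(back$entities), length(gen$kg$entities))
  expect_equal(nrow(back$triples), nrow(gen$kg$triples))
  writeLines("a\tb", f)
  expect_error(read_triples(f), "3 tab-separated columns")
  writeLines("a\tfrobnicates\tb", f)
  expect_error(read_triples(f), "unknown relation")
  expect_silent(read_triples(f, allowed_relations = NULL))
})

test_that("triple scores follow the translation geometry", {
  kg <- knowledge_graph(c("a", "b"), c("sensitivity", "response"),
                        c("b", "a"))
  p <- init_embeddings(kg, "TransE", k = 2L, seed = 1L)
  p$E[1, ] <- c(1, 0); p$R[1, ] <- c(0, 1); p$E[2, ] <- c(1, 1)
  expect_equal(score_triple(p, 1L, 1L, 2L), 0)
  p$E[2, ] <- c(0, 0)
  expect_equal(score_triple(p, 1L, 1L, 2L), sqrt(2))
  p$p <- 1L
  expect_equal(score_triple(p, 1L, 1L, 2L), 2)
  expect_error(score_triple(p, 5L, 1L, 1L), "out of range")
})

test_that("TransR with identity projections reproduces TransE exactly", {
  gen <- generate_kg(kg_spec(seed = 3L))
  pe <- init_embeddings(gen$kg, "TransE", k = 8L, seed = 9L)
  pr <- init_embeddings(gen$kg, "TransR", k = 8L, seed = 9L)
  for (i in seq_len(nrow(gen$kg$triples)))
    expect_identical(score_triple(pe, gen$kg$triples[i, ]),
                     score_triple(pr, gen$kg$triples[i, ]))
})

test_that("TransE L2 scores are invariant under a global rotation", {
  gen <- generate_kg(kg_spec(seed = 5L))
  p <- init_embeddings(gen$kg, "TransE", k = 8L, seed = 2L)
  rot <- qr.Q(qr(matrix(rnorm(64), 8L, 8L)))
  q <- p
  q$E <- p$E %*% rot; q$R <- p$R %*% rot
  for (i in seq_len(10L))
    expect_equal(score_triple(q, gen$kg$triples[i, ]),
                 score_triple(p, gen$kg$triples[i, ]))
})

test_that("negative sampling corrupts one side and filters known facts", {
  kg2 <- knowledge_graph("a", "sensitivity", "b")
  set.seed(1)
  for (i in 1:50) {
    neg <- sample_negative(kg2, kg2$triples[1, ])
    expect_true(identical(neg, c(2L, 1L, 2L)) || identical(neg, c(1L, 1L, 1L)))
  }
  gen <- generate_kg(kg_spec(seed = 3L))
  trip <- gen$kg$triples
  set.seed(7)
  sides <- logical(10000L)
  for (i in seq_len(10000L)) {
    pos <- trip[((i - 1L) %% nrow(trip)) + 1L, ]
    neg <- sample_negative(gen$kg, pos)
    expect_false(nrekg:::has_triple(gen$kg, neg[1], neg[2], neg[3]))
    changed_head <- neg[1] != pos[1]
    changed_tail <- neg[3] != pos[3]
    expect_true(xor(changed_head, changed_tail))
    sides[i] <- changed_head
  }
  expect_gt(mean(sides), 0.45)
  expect_lt(mean(sides), 0.55)
})

test_that("the margin ranking loss follows the hinge arithmetic", {
  kg <- knowledge_graph(c("a", "b", "c"), rep("response", 3L),
                        c("b", "c", "a"))
  p <- init_embeddings(kg, "TransE", k = 2L, gamma = 1, seed = 1L)
  p$E[1, ] <- c(0, 0); p$R[1, ] <- c(1, 0)
  p$E[2, ] <- c(1, 0)          # (a, r, b) scores 0
  p$E[3, ] <- c(3, 0)          # (a, r, c) scores 2 >= gamma
  pos <- matrix(c(1L, 1L, 2L), 1L)
  expect_equal(margin_loss(p, pos, matrix(c(1L, 1L, 3L), 1L)), 0)
  expect_equal(margin_loss(p, pos, pos), 1)      # tie costs gamma
  p$E[2, ] <- c(1.4, 0)        # d_pos = |h + r - t| = 0.4
  p$E[3, ] <- c(1.9, 0)        # d_neg = 0.9
  expect_equal(margin_loss(p, matrix(c(1L, 1L, 2L), 1L),
                           matrix(c(1L, 1L, 3L), 1L)), 0.5)
  expect_error(margin_loss(p, rbind(pos, pos), pos), "matched")
  set.seed(2)
  for (i in 1:20) {
    a <- trunc(runif(3, 1, 3.99)); a[2] <- 1
    b <- trunc(runif(3, 1, 3.99)); b[2] <- 1
    expect_gte(margin_loss(p, matrix(as.integer(a), 1L),
                           matrix(as.integer(b), 1L)), 0)
  }
})

test_that("relation vectors are entity differences with zero for unknowns", {
  kg <- knowledge_graph("drugA", "sensitivity", "geneB")
  p <- init_embeddings(kg, "TransE", k = 2L, seed = 1L)
  p$E[1, ] <- c(0, 1); p$E[2, ] <- c(1, 2)
  expect_equal(relation_vector(p, "drugA", "geneB"), c(1, 1))
  expect_equal(relation_vector(p, "drugA", "drugA"), c(0, 0))
  expect_equal(relation_vector(p, "drugA", "unseen"), c(0, 0))
  expect_equal(relation_vector(NULL, "x", "y", k = 3L), numeric(3))
})

test_that("link prediction ranks perfectly-scoring tails first", {
  gen <- generate_kg(kg_spec(seed = 3L))
  p <- init_embeddings(gen$kg, "TransE", k = 8L, seed = 1L)
  trip <- gen$kg$triples
  # plant an exact fit for five triples and rank them
  for (i in 1:5) {
    p$E[trip[i, 3L], ] <- p$E[trip[i, 1L], ] + p$R[trip[i, 2L], ]
  }
  lp <- evaluate_link_prediction(p, gen$kg, trip[1:5, ])
  expect_equal(lp$hits1, 1)
  expect_equal(lp$mean_rank, 1)
  single <- knowledge_graph("a", "none", "a")
  ps <- init_embeddings(single, "TransE", k = 2L, seed = 1L)
  expect_equal(evaluate_link_prediction(ps, single,
                                        single$triples)$mean_rank, 1)
  expect_error(evaluate_link_prediction(p, gen$kg,
                                        trip[integer(0), , drop = FALSE]),
               "empty")
  # random embeddings rank the truth near the middle of 60 entities
  mr <- vapply(1:3, function(s) {
    pr <- init_embeddings(gen$kg, "TransE", k = 8L, seed = 100L + s)
    evaluate_link_prediction(pr, gen$kg, trip)$mean_rank
  }, numeric(1))
  expect_gt(mean(mr), 30 * 0.6)
  expect_lt(mean(mr), 30 * 1.4)
})

test_that("embeddings survive a JSON round trip", {
  gen <- generate_kg(kg_spec(seed = 3L))
  p <- train_embeddings(gen$kg, "TransR", k = 4L, epochs = 3L, seed = 2L)
  f <- withr::local_tempfile(fileext = ".json")
  write_embeddings(p, f)
  q <- read_embeddings(f)
  expect_equal(q$variant, "TransR")
  expect_equal(q$E, p$E, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(q$M[[2]], p$M[[2]], tolerance = 1e-12)
  expect_equal(score_triple(q, gen$kg$triples[1, ]),
               score_triple(p, gen$kg$triples[1, ]))
})
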