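test_that("normalize_tokens strips edge punctuation and is idempotent", {
  got <- normalize_tokens("treated with gefitinib and showed a partial response.")
  expect_equal(got[[1]],
               c("treated", "with", "gefitinib", "and", "showed", "a",
                 "partial", "response"))
  expect_equal(normalize_tokens("")[[1]], character(0))
  expect_equal(normalize_tokens("  ,  . ! ")[[1]], character(0))
  # internal punctuation survives (identifiers like CL-387,785)
  expect_equal(normalize_tokens("with CL-387,785, (see)")[[1]],
               c("with", "CL-387,785", "see"))
  set.seed(1)
  raw <- c("The L858E point mutation, was noted in 10.",
           "odd tokens: 'quoted' (parens) trailing...")
  once <- normalize_tokens(raw)
  twice <- normalize_tokens(vapply(once, paste, character(1), collapse = " "))
  expect_identical(once, twice)
})

test_that("the worked passage tokenizes with 'treated' at flat index 30", {
  inst <- worked_example_fixture()
  expect_length(inst$tokens, 38L)
  expect_equal(which(inst$tokens == "treated") - 1L, 30L)
  expect_equal(inst$sentence_breaks, c(0L, 27L))
})

test_that("position features match the worked example and toy enumerations", {
  inst <- worked_example_fixture()
  pf <- compute_position_features(inst)
  at_treated <- pf[which(inst$tokens == "treated"), ]
  expect_equal(at_treated[["gene"]], 22L)
  expect_equal(at_treated[["mutation"]], 13L)
  expect_equal(at_treated[["drug"]], -2L)
  # zero at each mention head
  for (role in c("drug", "gene", "mutation"))
    expect_equal(unname(pf[inst$mentions[[role]]$start + 1L, role]), 0L)
  toy <- tiny_instance(drug = 1L, gene = 5L, mutation = 3L)
  tf <- compute_position_features(toy)
  expect_equal(tf[, "drug"], 0:4)
  expect_equal(tf[, "gene"], -4:0)
})

test_that("position features clip and have one zero crossing before clipping", {
  inst <- tiny_instance(tokens = sprintf("t%02d", 1:30), drug = 2L,
                        gene = 15L, mutation = 29L)
  pf <- compute_position_features(inst, max_distance = 5L)
  expect_true(all(pf >= -5L & pf <= 5L))
  pf_raw <- compute_position_features(inst, max_distance = 1000L)
  for (role in c("drug", "gene", "mutation"))
    expect_equal(sum(pf_raw[, role] == 0L), 1L)
  noge <- tiny_instance()
  noge$mentions$gene <- NULL
  expect_equal(compute_position_features(noge)[, "gene"], rep(0L, 5L))
  expect_error(compute_position_features(noge, roles = c("drug", "gene")),
               "lacks required role")
})

test_that("instances round-trip through the JSON-lines format", {
  ds <- generate_corpus(corpus_spec(n_instances = 12L, seed = 8L))
  expect_length(ds$instances, 12L)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_instances(ds, f)
  back <- read_instances(f)
  expect_length(back$instances, 12L)
  expect_identical(lapply(back$instances, unclass),
                   lapply(ds$instances, unclass))
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_instances(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("flat spans recover their sentence-local coordinates exactly", {
  ds <- generate_corpus(corpus_spec(n_instances = 20L, seed = 9L))
  for (inst in ds$instances) {
    brk <- inst$sentence_breaks
    for (m in inst$mentions) {
      loc <- nrekg:::unflatten_span(brk, m$start, m$end)
      sp <- nrekg:::flatten_span(brk, loc$sentence_index, loc$token_start,
                                 loc$token_end)
      expect_equal(unname(sp), c(m$start, m$end))
    }
  }
})

test_that("reading rejects malformed or invalid input with line numbers", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), f)
  expect_error(read_instances(f), "empty dataset")
  ok <- paste0('{"doc_id":"d1","sentences":[["x","y","z"]],"mentions":',
               '[{"role":"drug","entity_id":"e1","sentence_index":0,',
               '"token_start":0,"token_end":1},{"role":"mutation",',
               '"entity_id":"e2","sentence_index":0,"token_start":2,',
               '"token_end":3}],"label":"none"}')
  writeLines(c(ok, "{not json"), f)
  expect_error(read_instances(f), "line 2")
  writeLines(sub('"label":"none"', '"label":"bogus"', ok), f)
  expect_error(read_instances(f), "unknown label")
  writeLines(sub('"role":"drug"', '"role":"protein"', ok), f)
  expect_error(read_instances(f), "unknown mention role")
  writeLines(sub('"token_end":3', '"token_end":9', ok), f)
  expect_error(read_instances(f), "out of range")
})

test_that("binary scheme remaps fine-grained labels on read", {
  sc <- label_scheme("binary")
  expect_equal(map_label("sensitivity", sc), "yes")
  expect_equal(map_label("none", sc), "no")
  expect_equal(required_roles(sc), c("drug", "mutation"))
  tmpl <- paste0('{"doc_id":"d%d","sentences":[["x","y"]],"mentions":',
                 '[{"role":"drug","entity_id":"e1","sentence_index":0,',
                 '"token_start":0,"token_end":1},{"role":"mutation",',
                 '"entity_id":"e2","sentence_index":0,"token_start":1,',
                 '"token_end":2}],"label":"%s"}')
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(sprintf(tmpl, 1, "resistance"), sprintf(tmpl, 2, "none")), f)
  ds <- read_instances(f, sc)
  expect_equal(vapply(ds$instances, `[[`, character(1), "label"),
               c("yes", "no"))
})

test_that("fold splits partition the data and stay disjoint from validation", {
  folds <- split_folds(10L, k = 5L, validation_size = 0L, seed = 3L)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(lengths(tests), rep(2L, 5L))
  expect_equal(sort(unlist(tests)), 1:10)
  expect_identical(folds, split_folds(10L, k = 5L, validation_size = 0L,
                                      seed = 3L))
  expect_false(identical(folds, split_folds(10L, k = 5L,
                                            validation_size = 0L, seed = 4L)))
  big <- split_folds(1000L, k = 5L, validation_size = 200L, seed = 3L)
  for (f in big) {
    expect_length(f$validation, 40L)   # min(200, 0.05 * 800)
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$validation, f$test), 0L)
    expect_length(intersect(f$train, f$validation), 0L)
    expect_equal(sort(c(f$train, f$validation, f$test)), 1:1000)
  }
  expect_error(split_folds(3L, k = 5L), "cannot be split")
})
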