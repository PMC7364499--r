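test_that("planted KGs satisfy the exact translation identity at zero noise", {
  gen <- generate_kg(kg_spec(noise_sd = 0, seed = 7L))
  man <- gen$manifest
  for (i in seq_len(nrow(man$planted))) {
    h <- man$entity_vectors[man$planted$head[i], ]
    r <- man$relation_vectors[man$planted$relation[i], ]
    t <- man$entity_vectors[man$planted$tail[i], ]
    expect_equal(sqrt(sum((h + r - t)^2)), 0, tolerance = 1e-12)
  }
  expect_true(all(startsWith(names(man$roles)[man$roles == "drug"], "drug_")))
  expect_identical(generate_kg(kg_spec(seed = 7L))$kg$triples,
                   gen$kg$triples)
  expect_error(kg_spec(n_drug = 4L, triples_per_relation = 10L),
               "cannot exceed")
  # tails stay inside the unit ball the trainer projects onto
  expect_true(all(sqrt(rowSums(man$entity_vectors^2)) <= 1))
})

test_that("trigger corpora are perfectly classified by a trigger-word rule", {
  ds <- generate_corpus(corpus_spec(n_instances = 150L, signal_strength = 1,
                                    seed = 31L))
  triggers <- vapply(ds$scheme$classes, nrekg:::trigger_word, character(1))
  hits <- 0L
  for (inst in ds$instances) {
    found <- triggers[triggers %in% inst$tokens]
    expect_length(found, 1L)
    if (names(found) == inst$label) hits <- hits + 1L
  }
  expect_equal(hits, 150L)
  # trigger lands within 5 tokens of the drug mention
  for (inst in ds$instances[1:30]) {
    pos <- which(inst$tokens %in% triggers) - 1L
    expect_lte(abs(pos - inst$mentions$drug$start), 5L)
  }
})

test_that("null corpora carry no lexical label signal", {
  ds <- generate_corpus(corpus_spec(n_instances = 400L, signal_strength = 0,
                                    seed = 32L))
  triggers <- vapply(ds$scheme$classes, nrekg:::trigger_word, character(1))
  all_tokens <- unlist(lapply(ds$instances, `[[`, "tokens"))
  expect_false(any(triggers %in% all_tokens))
  # token/label contingency is consistent with independence
  labels <- vapply(ds$instances, `[[`, character(1), "label")
  top <- names(sort(table(all_tokens), decreasing = TRUE))[1:15]
  counts <- vapply(top, function(w)
    vapply(split(ds$instances, labels), function(grp)
      sum(vapply(grp, function(i) w %in% i$tokens, logical(1))),
      numeric(1)), numeric(length(unique(labels))))
  suppressWarnings(p <- stats::chisq.test(counts)$p.value)
  expect_gt(p, 0.001)
})

test_that("label marginals approach uniform and structure matches the spec", {
  ds <- generate_corpus(corpus_spec(n_instances = 2000L, seed = 33L))
  labels <- vapply(ds$instances, `[[`, character(1), "label")
  freq <- table(labels) / length(labels)
  expect_true(all(abs(freq - 0.2) <= 0.03))
  nsent <- vapply(ds$instances, function(i) length(i$sentence_breaks),
                  numeric(1))
  expect_gt(mean(nsent == 2L), 0.6)     # cross-sentence probability 0.7
  expect_lt(mean(nsent == 2L), 0.8)
  expect_identical(
    lapply(generate_corpus(corpus_spec(n_instances = 25L, seed = 33L))$instances,
           unclass),
    lapply(ds$instances[1:25], unclass))
})

test_that("KG-labeled corpora copy the relation of the sampled pair", {
  gen <- generate_kg(kg_spec(seed = 7L))
  ds <- generate_corpus(corpus_spec(n_instances = 60L, signal_strength = 0,
                                    kg_signal_strength = 1, seed = 34L),
                        gen$kg)
  ents <- gen$kg$entities
  for (inst in ds$instances) {
    hi <- match(inst$mentions$drug$entity_id, ents)
    ti <- match(inst$mentions$gene$entity_id, ents)
    ri <- match(inst$label, gen$kg$relations)
    expect_true(nrekg:::has_triple(gen$kg, hi, ri, ti))
  }
  expect_error(generate_corpus(corpus_spec(kg_signal_strength = 0.5)),
               "requires a knowledge graph")
})

test_that("the worked example fixture matches its shipped test asset", {
  inst <- worked_example_fixture()
  expect_length(inst$sentence_breaks, 2L)
  expect_equal(inst$mentions$gene$entity_id, "EGFR")
  expect_equal(inst$mentions$mutation$entity_id, "L858E")
  expect_equal(inst$mentions$drug$entity_id, "gefitinib")
  path <- system.file("extdata", "worked_example.jsonl", package = "nrekg")
  expect_true(nzchar(path))
  shipped <- read_instances(path)
  expect_identical(unclass(shipped$instances[[1]]), unclass(inst))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_instances(nre_dataset(list(inst), label_scheme("multiclass")), f)
  expect_identical(unclass(read_instances(f)$instances[[1]]), unclass(inst))
})

test_that("the simulator writes a coherent corpus/KG/manifest bundle", {
  dir <- withr::local_tempdir()
  write_synthetic(dir, corpus_spec(n_instances = 15L, seed = 41L),
                  kg_spec(seed = 41L))
  ds <- read_instances(file.path(dir, "instances.jsonl"))
  kg <- read_triples(file.path(dir, "triples.tsv"))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_length(ds$instances, man$n_instances)
  expect_equal(nrow(kg$triples), man$n_triples)
})
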