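# Simulators with planted ground truth: knowledge graphs whose triples
# follow an (approximately) additive translation structure, and corpora
# whose labels are carried by lexical triggers, by the KG, or by nothing.

#' Specification of a synthetic knowledge graph
#'
#' @param n_drug,n_gene,n_mutation entity counts per role.
#' @param relations relation names (subset of the five interaction types).
#' @param k_true dimension of the planted vectors.
#' @param noise_sd standard deviation of the Gaussian perturbation added
#'   to `h + r` before the tail is placed (0 = exact translation).
#' @param triples_per_relation planted facts per relation; at most
#'   `n_drug` (heads are drawn without replacement within a relation so
#'   facts are distinct).
#' @param seed integer seed.
#' @return object of class `kg_spec`.
#' @export
kg_spec <- function(n_drug = 12L, n_gene = 24L, n_mutation = 24L,
                    relations = c("resistance or nonresponse", "sensitivity",
                                  "response", "resistance"),
                    k_true = 8L, noise_sd = 0, triples_per_relation = 12L,
                    seed = 1L) {
  n_drug <- stopifnot_scalar_int(n_drug, "n_drug")
  n_gene <- stopifnot_scalar_int(n_gene, "n_gene")
  n_mutation <- stopifnot_scalar_int(n_mutation, "n_mutation")
  k_true <- stopifnot_scalar_int(k_true, "k_true")
  triples_per_relation <- stopifnot_scalar_int(triples_per_relation,
                                               "triples_per_relation")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(relations %in% label_scheme("multiclass")$classes))
    stop("relations must come from the five-type set")
  if (triples_per_relation > n_drug)
    stop("triples_per_relation cannot exceed n_drug (facts must be distinct)")
  structure(list(n_drug = n_drug, n_gene = n_gene, n_mutation = n_mutation,
                 relations = relations, k_true = k_true, noise_sd = noise_sd,
                 triples_per_relation = triples_per_relation, seed = seed),
            class = "kg_spec")
}

#' Generate a knowledge graph with planted translation structure
#'
#' Drug (head) vectors and relation vectors are drawn at random; each fact
#' `(h, r, t)` places its tail at `h + r + N(0, noise_sd)` — as a fresh
#' gene/mutation entity while role slots remain, afterwards as the nearest
#' existing tail of the role. Relations alternate between the drug-gene
#' and drug-mutation kind. At `noise_sd = 0` every planted fact satisfies
#' the translation identity exactly under the true vectors.
#'
#' @param spec a [kg_spec()].
#' @return list with `kg` (a [knowledge_graph()]) and `manifest` (true
#'   vectors, roles, and the planted triples as a data frame).
#' @export
generate_kg <- function(spec) {
  stopifnot(inherits(spec, "kg_spec"))
  with_seed(derive_seed(spec$seed, "kg"), {
    k <- spec$k_true
    rvec <- function(n, scale) matrix(stats::rnorm(n * k, 0, scale / sqrt(k)),
                                      n, k)
    # scales keep planted tails (h + r + noise) inside the unit ball that
    # training projects entities onto, so the exact solution is feasible
    drugs <- paste0("drug_", seq_len(spec$n_drug))
    E_true <- rvec(spec$n_drug, 0.3)
    rownames(E_true) <- drugs
    roles <- stats::setNames(rep("drug", spec$n_drug), drugs)
    R_true <- rvec(length(spec$relations), 0.5)
    rownames(R_true) <- spec$relations
    slots <- c(gene = spec$n_gene, mutation = spec$n_mutation)
    used <- c(gene = 0L, mutation = 0L)
    head_v <- character(0); rel_v <- character(0); tail_v <- character(0)
    for (ri in seq_along(spec$relations)) {
      role <- if (ri %% 2L == 1L) "gene" else "mutation"
      heads <- sample(drugs, spec$triples_per_relation)
      for (h in heads) {
        target <- E_true[h, ] + R_true[ri, ] +
          stats::rnorm(k, 0, spec$noise_sd)
        role_ents <- names(roles)[roles == role]
        if (used[[role]] < slots[[role]]) {
          used[[role]] <- used[[role]] + 1L
          t_id <- paste0(substr(role, 1L, 4L), "_", used[[role]])
          E_true <- rbind(E_true, target)
          rownames(E_true)[nrow(E_true)] <- t_id
          roles[t_id] <- role
        } else {
          cand <- E_true[role_ents, , drop = FALSE]
          d2 <- rowSums(sweep(cand, 2L, target)^2)
          t_id <- role_ents[which.min(d2)]
        }
        head_v <- c(head_v, h); rel_v <- c(rel_v, spec$relations[ri])
        tail_v <- c(tail_v, t_id)
      }
    }
    planted <- data.frame(head = head_v, relation = rel_v, tail = tail_v,
                          stringsAsFactors = FALSE)
    kg <- knowledge_graph(planted$head, planted$relation, planted$tail)
    list(kg = kg,
         manifest = list(spec = unclass(spec), roles = roles,
                         entity_vectors = E_true, relation_vectors = R_true,
                         planted = planted))
  })
}

#' Specification of a synthetic relation corpus
#'
#' @param n_instances number of instances.
#' @param vocab_size filler vocabulary size (on top of the reserved
#'   per-class trigger words); must exceed the class count.
#' @param cross_sentence_prob probability an instance spans two sentences
#'   (default 0.7, the cross-sentence share of the ternary corpus profile).
#' @param sentence_length integer range `c(min, max)` of filler tokens per
#'   sentence.
#' @param scheme_mode `"multiclass"` or `"binary"`.
#' @param signal_strength probability `s` that the label's reserved
#'   trigger word is planted within 5 tokens of the drug mention.
#' @param kg_signal_strength probability `g` that the label is set to the
#'   KG relation of the sampled drug-gene pair (text stays uninformative
#'   for those instances).
#' @param seed integer seed.
#' @return object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_instances = 600L, vocab_size = 120L,
                        cross_sentence_prob = 0.7,
                        sentence_length = c(8L, 20L),
                        scheme_mode = "multiclass",
                        signal_strength = 1.0, kg_signal_strength = 0,
                        seed = 1L) {
  n_instances <- stopifnot_scalar_int(n_instances, "n_instances")
  vocab_size <- stopifnot_scalar_int(vocab_size, "vocab_size")
  if (cross_sentence_prob < 0 || cross_sentence_prob > 1 ||
      signal_strength < 0 || signal_strength > 1 ||
      kg_signal_strength < 0 || kg_signal_strength > 1)
    stop("probabilities must lie in [0, 1]")
  if (length(sentence_length) != 2L || any(sentence_length < 3L) ||
      sentence_length[1L] > sentence_length[2L])
    stop("sentence_length must be an increasing range of counts >= 3")
  structure(list(n_instances = n_instances, vocab_size = vocab_size,
                 cross_sentence_prob = cross_sentence_prob,
                 sentence_length = as.integer(sentence_length),
                 scheme_mode = scheme_mode,
                 signal_strength = signal_strength,
                 kg_signal_strength = kg_signal_strength, seed = seed),
            class = "corpus_spec")
}

# Zipf(alpha) probabilities over ranked filler words: natural token skew
# so OOV/dropout paths see both frequent and rare words
zipf_probs <- function(n, alpha = 1.1) {
  p <- 1 / seq_len(n)^alpha
  p / sum(p)
}

trigger_word <- function(class) paste0("trg_", gsub("[^a-z]+", "_", class))

#' Generate a synthetic relation corpus with planted signal
#'
#' Each instance embeds one drug, gene and mutation entity token in one or
#' two sentences of Zipf-distributed filler. With probability
#' `signal_strength` the label's reserved trigger word is planted near the
#' drug mention (a bag-of-words rule reading only triggers then classifies
#' perfectly); with probability `kg_signal_strength` the label is copied
#' from the knowledge-graph relation linking the sampled drug-gene pair,
#' so for those instances only the KG carries the label. Remaining labels
#' are uniform, so at `s = 0, g = 0` the text carries no label
#' information.
#'
#' @param spec a [corpus_spec()].
#' @param kg optional [knowledge_graph()] (required when
#'   `kg_signal_strength > 0`); entity roles are read from the
#'   `drug_`/`gene_`/`mut_` name prefixes used by [generate_kg()].
#' @return an [nre_dataset()].
#' @export
generate_corpus <- function(spec, kg = NULL) {
  stopifnot(inherits(spec, "corpus_spec"))
  scheme <- label_scheme(spec$scheme_mode)
  if (spec$kg_signal_strength > 0 && is.null(kg))
    stop("kg_signal_strength > 0 requires a knowledge graph")
  if (spec$vocab_size <= length(scheme$classes) + 3L)
    stop("vocab too small to reserve trigger words")
  if (!is.null(kg)) {
    ents <- kg$entities
    drugs <- ents[startsWith(ents, "drug_")]
    genes <- ents[startsWith(ents, "gene_")]
    muts <- ents[startsWith(ents, "mut_")]
    if (!length(drugs) || !length(genes))
      stop("kg entities must use drug_/gene_/mut_ role prefixes")
    if (!length(muts)) muts <- paste0("mut_", 1:8)
    dg <- kg$triples[startsWith(ents[kg$triples[, 3L]], "gene_"), ,
                     drop = FALSE]
  } else {
    drugs <- paste0("drug_", 1:8); genes <- paste0("gene_", 1:8)
    muts <- paste0("mut_", 1:8)
    dg <- NULL
  }
  filler <- sprintf("w%03d", seq_len(spec$vocab_size))
  fp <- zipf_probs(spec$vocab_size)
  with_seed(derive_seed(spec$seed, "corpus"), {
    instances <- vector("list", spec$n_instances)
    for (i in seq_len(spec$n_instances)) {
      kg_label <- !is.null(dg) && nrow(dg) > 0L &&
        stats::runif(1) < spec$kg_signal_strength
      if (kg_label) {
        tr <- dg[sample.int(nrow(dg), 1L), ]
        drug <- kg$entities[tr[1L]]; gene <- kg$entities[tr[3L]]
        mut <- sample(muts, 1L)
        label <- map_label(kg$relations[tr[2L]], scheme)
      } else {
        drug <- sample(drugs, 1L); gene <- sample(genes, 1L)
        mut <- sample(muts, 1L)
        label <- sample(scheme$classes, 1L)
      }
      two <- stats::runif(1) < spec$cross_sentence_prob
      lens <- sample(spec$sentence_length[1L]:spec$sentence_length[2L],
                     if (two) 2L else 1L, replace = TRUE)
      tokens <- sample(filler, sum(lens), replace = TRUE, prob = fp)
      breaks <- if (two) c(0L, lens[1L]) else 0L
      n <- length(tokens)
      spots <- sample.int(n, 3L)
      tokens[spots] <- c(drug, gene, mut)
      if (!kg_label && stats::runif(1) < spec$signal_strength) {
        near <- setdiff(max(1L, spots[1L] - 5L):min(n, spots[1L] + 5L), spots)
        tokens[if (length(near) > 1L) sample(near, 1L) else near] <-
          trigger_word(label)
      }
      mentions <- list(
        drug = list(entity_id = drug, start = spots[1L] - 1L,
                    end = spots[1L]),
        gene = list(entity_id = gene, start = spots[2L] - 1L,
                    end = spots[2L]),
        mutation = list(entity_id = mut, start = spots[3L] - 1L,
                        end = spots[3L]))
      if (scheme$mode == "binary") mentions$gene <- NULL
      instances[[i]] <- relation_instance(sprintf("syn-%05d", i), tokens,
                                          breaks, mentions, label)
    }
    nre_dataset(instances, scheme)
  })
}

# the two-sentence EGFR/L858E/gefitinib passage used throughout the
# position-feature documentation
.worked_example_sentences <- c(
  paste("The deletion mutation on exon 19 of the EGFR gene was present in",
        "16 patients, while The L858E point mutation on exon 21 was noted",
        "in 10."),
  "All patients were treated with gefitinib and showed a partial response.")

#' The worked position-feature example instance
#'
#' The canonical two-sentence drug-gene-mutation passage (gene EGFR,
#' mutation L858E, drug gefitinib), tokenized under the package's
#' whitespace-plus-punctuation-stripping convention. At the token
#' `"treated"` the signed distances to the gene, mutation and drug
#' mentions are 22, 13 and -2.
#'
#' @return a [relation_instance()].
#' @examples
#' inst <- worked_example_fixture()
#' compute_position_features(inst)[which(inst$tokens == "treated"), ]
#' @export
worked_example_fixture <- function() {
  sents <- normalize_tokens(.worked_example_sentences)
  tokens <- unlist(sents)
  breaks <- c(0L, length(sents[[1L]]))
  at <- function(w) which(tokens == w)[1L] - 1L
  relation_instance(
    doc_id = "worked-example", tokens = tokens, sentence_breaks = breaks,
    mentions = list(
      drug = list(entity_id = "gefitinib", start = at("gefitinib"),
                  end = at("gefitinib") + 1L),
      gene = list(entity_id = "EGFR", start = at("EGFR"),
                  end = at("EGFR") + 1L),
      mutation = list(entity_id = "L858E", start = at("L858E"),
                      end = at("L858E") + 1L)),
    label = "response")
}

#' Write a synthetic corpus and knowledge graph to disk
#'
#' Emits `instances.jsonl`, `triples.tsv` and `manifest.json` under
#' `out_dir`.
#'
#' @param out_dir output directory (created if missing).
#' @param cspec a [corpus_spec()].
#' @param kspec a [kg_spec()] or `NULL` to skip the KG.
#' @return `out_dir`, invisibly.
#' @export
write_synthetic <- function(out_dir, cspec = corpus_spec(),
                            kspec = kg_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kg <- NULL
  manifest <- list(corpus_spec = unclass(cspec))
  if (!is.null(kspec)) {
    gen <- generate_kg(kspec)
    kg <- gen$kg
    write_triples(kg, file.path(out_dir, "triples.tsv"))
    manifest$kg_spec <- unclass(kspec)
    manifest$n_triples <- nrow(gen$manifest$planted)
    manifest$entity_roles <- as.list(gen$manifest$roles)
  }
  ds <- generate_corpus(cspec, kg)
  write_instances(ds, file.path(out_dir, "instances.jsonl"))
  manifest$n_instances <- length(ds$instances)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
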