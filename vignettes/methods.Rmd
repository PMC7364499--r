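---
title: "Knowledge-augmented cross-sentence n-ary relation extraction: methods"
author: "nrekg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-augmented cross-sentence n-ary relation extraction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrekg)
```

## The problem

Drug–gene–mutation interactions reported in the biomedical literature often
span sentence boundaries: the mutation is introduced in one sentence, the
drug and the clinical outcome in the next. `nrekg` classifies such
multi-sentence *relation instances* — a token sequence with one mention each
of a drug, a gene and a mutation — into five interaction types
(`"resistance or nonresponse"`, `"sensitivity"`, `"response"`,
`"resistance"`, `"none"`), or into a collapsed binary yes/no scheme for
drug–mutation pairs. The model operates directly on the token sequence; no
dependency parsing or document-graph construction is involved.

Two information sources are combined:

1. **Text**: each token is represented by a word embedding concatenated with
   three *position embeddings* — lookups of its signed distances to the
   drug, gene and mutation mentions. A bidirectional LSTM contextualizes the
   sequence, multihead scaled dot-product self-attention mixes information
   across all positions, and a pooling step reduces the sequence to one
   vector.
2. **Knowledge graph**: entities and the five relation types are embedded by
   a translation model (TransE, TransH, TransR or TransD) trained on
   `(head, relation, tail)` facts. For a given instance, the differences
   `E_gene - E_drug` and `E_mutation - E_drug` of the learned entity vectors
   are appended to the sentence vector as side information before the
   softmax classifier.

## Position features

For token index `i` and a mention whose span starts at token `e`, the
distance is `i - e`: zero at the mention head, negative left of it, positive
right of it. On the canonical worked passage (EGFR / L858E / gefitinib) the
token `"treated"` receives distances 22, 13 and −2 to the gene, mutation and
drug — the convention that fixes both the tokenizer (whitespace splitting,
edge punctuation stripped) and the sign (word index minus entity head
index). Multi-token mentions anchor at their first token; this is the
deterministic choice where the convention is otherwise underdetermined.
Distances are clipped to ±128 by default so the three position tables stay
bounded (257 rows each).

```{r}
inst <- worked_example_fixture()
compute_position_features(inst)[which(inst$tokens == "treated"), ]
```

## Translation models and the margin ranking loss

All four variants score a triple by `||h~ + r - t~||_p` (default `p = 2`) in
the variant's projection space: identity (TransE), projection onto a
relation hyperplane (TransH), a per-relation `k x k` matrix (TransR), or
rank-1-plus-identity dynamic matrices (TransD; entity and relation
dimensions are kept equal). Training minimizes the hinge

```
mean over facts of  [ gamma + d(positive) - d(corrupted) ]+
```

with one filtered corruption per fact per pass: head or tail is replaced
(probability 1/2 each) by a uniform entity, and corruptions that are
themselves known facts are rejected. Note the loss is written so that it
*decreases* when a fact scores better (smaller) than its corruption; a
transcription of the objective with the two distances exchanged cannot rank
facts above corruptions, so only the correct orientation is provided.

Numerical choices, stated once:

- Initialization is uniform in `[-6/sqrt(k), 6/sqrt(k)]` (the original
  TransE recipe); TransR matrices start at the identity, so TransR begins
  exactly at the TransE objective; TransD projection vectors start small but
  non-zero, since at exactly zero their gradients vanish jointly.
- Entity vectors are projected back onto the unit ball at the end of each
  epoch; TransH normals are renormalized after every update.
- The update is plain minibatch SGD. An optional hyperbolic learning-rate
  decay (`lr / (1 + lr_decay * (epoch - 1))`) is available: with a margin
  large enough that most hinges stay active, constant-rate SGD orbits the
  optimum at a noise floor proportional to the rate, and the decay is what
  lets recovery runs reach near-zero positive scores.
- Defaults: `k = 50`, `gamma = 1`, `p = 2`. The margin, norm and epoch count
  for KG training are not pinned by the reference parameter design and are
  exposed as arguments; the recovery analyses in the test suite use
  `gamma = 3` so that the hinge never deactivates on the unit ball
  (the maximum attainable corrupted-triple distance there is below 3),
  which turns the hinge into a pure distance objective.

The classifier consumes `E_tail - E_head` in *entity* space for every
variant, because the concatenation step subtracts entity representations
directly; projected (relation-space) differences would not be comparable
across relations. Entities missing from the KG contribute a zero vector,
which is exactly the no-side-information case.

## The recurrent cell: two gate wirings

The package implements two gate wirings, selected by
`train_config(gate_variant = ...)`:

- `"literal"` (default): the candidate gate reads `i ⊙ h_{t-1}`
  inside its recurrent product, and the next hidden state is the convex mix
  `h_t = (1 - f) ⊙ h_{t-1} + f ⊙ g`. The output gate `o` and the cell state
  `c_t` are computed but do not feed `h_t`. This is a functional gated
  unit (a GRU-like highway on `f`), and with the forget gate pinned shut it
  copies state exactly.
- `"standard"`: the textbook LSTM, `h_t = o ⊙ tanh(c_t)`.

The model family this package implements describes the first wiring;
whether it is intentional or a transcription artifact of the standard cell
is undecidable from the description alone, so both are first-class and
gradient-checked, and the default follows the description as written. The Bi-LSTM concatenates a forward and a
backward pass (zero initial states; the backward pass runs over the reversed
valid region only), giving `d = 2 * hidden` contextual dimensions.

## Attention

Each of `h` heads projects the encoded sequence into a `d/h`-dimensional
subspace with its own query/key/value matrices (`d x (d/h)`; the only shape
under which the projections type-check against an `n x d` input), applies
`softmax(QK'/scale) V`, and the concatenated heads are mixed by a `d x d`
output matrix. The softmax scale is `sqrt(d/h)` per head by default, with
`sqrt(d)` available via `softmax_scale = "model_dim"`; the model
description is ambiguous between the two, and the per-head scale follows the
attention literature the model builds on. Attention itself is
permutation-equivariant; order information enters only through the position
embeddings upstream.

The attention output is reduced to one vector by elementwise max over time
(default; `mean` available). The reduction is not pinned down by the model
description, and max pooling is the common choice for relation
classification — a planted trigger word anywhere in the sequence can
dominate the pooled vector, which is also why the synthetic benchmark is
learnable quickly.

## Classifier and training loop

The pooled sentence vector (dropout 0.5 during training) is concatenated
with the two relation vectors — `[B ; R_drug-gene ; R_drug-mutation]`, with
zeros for absent slots — and fed to a softmax layer; training minimizes
cross-entropy by Adam (learning rate 0.001, `beta = (0.9, 0.999)`,
minibatch 6) with global-norm gradient clipping at 5. All gradients are
analytic and hand-derived (embedding tables receive scattered updates;
backpropagation through time covers both gate variants); finite-difference
checks in the test suite hold them to relative error below `1e-4`. KG
relation vectors are *frozen* inputs: the translation model is trained
separately and its output consumed as side information.

Recurrent dropout (rate 0.5) uses one Bernoulli mask per sequence and
direction, applied where `h_{t-1}` enters a recurrent weight product
(variational style); the reference design names the rate but not the
mechanism. After each epoch the model is scored on a validation split and
the best-validation-accuracy snapshot is returned.

Binary drug–mutation corpora switch the KG off by default: a relation-typed
KG vector for the classified pair would effectively hand the classifier its
label. `allow_binary_kg = TRUE` overrides this deliberately.

Determinism: one master seed fans out via fixed offsets to the fold split,
parameter initialization, dropout and negative sampling, so a configuration
reproduces bit-identically on one machine (floating-point reduction order is
fixed in pure-R arithmetic).

Evaluation reports accuracy, macro-F1 (unweighted mean of per-class
`2PR/(P+R)`, zero where undefined), the gold-by-predicted confusion matrix,
and accuracy within token-length buckets `[0,45)`, `[45,75)`, `[75,∞)`.
Argmax ties break toward the lowest class index. Cross-validation uses five
folds with a 200-instance validation draw from each fold's training portion,
scaled as `min(200, floor(0.05 |train|))` so the protocol remains meaningful
on small corpora; the reported figure is the arithmetic mean of per-fold
test accuracies (pooling predictions across folds is the other defensible
reading; the per-fold mean is implemented).

## What the simulators emulate — and what they do not

`generate_kg()` plants an exact (or Gaussian-perturbed) additive translation
structure: drug vectors and relation vectors are drawn at random and each
fact's tail is placed at `h + r + N(0, noise_sd)`, as a fresh gene/mutation
entity while role slots remain. Planted scales keep every tail inside the
unit ball that training projects onto, so the noise-free structure is
exactly representable. Relations alternate between drug–gene and
drug–mutation kinds, mirroring the two triple families of the real KG.

`generate_corpus()` produces one- or two-sentence instances
(cross-sentence probability 0.7, matching the corpus profile in which about
70% of ternary instances cross sentences) of Zipf(1.1)-distributed filler —
natural token-frequency skew, so OOV and dropout paths see realistic rank
structure — with three single-token entity mentions at random positions.
Label signal is planted three ways:

- `signal_strength` (`s`): probability that a class-specific reserved
  trigger word lands within five tokens of the drug mention. At `s = 1` a
  bag-of-words rule is a perfect classifier.
- `kg_signal_strength` (`g`): probability that the label is copied from the
  KG relation of the sampled drug–gene pair, so those instances are
  unclassifiable from text statistics but perfectly predictable from the
  relation vector.
- residual labels are uniform; at `s = 0, g = 0` the corpus carries no
  lexical label information.

The simulators deliberately do *not* produce biomedical syntax, negation,
coreference, duplicate mentions, or multi-token entities (multi-token span
handling is unit-tested separately). A model that aces the synthetic
benchmarks has a correct architecture and optimizer — nothing more is
claimed about real-corpus accuracy, and full-corpus benchmark results
are out of the package's reproduction scope.

## Desk-scale study conditions

The end-to-end benchmarks in the test suite run on corpora of 600 instances
with a reduced model (word dim 32, position dim 8, hidden 32 per direction,
2 heads, relation dim 16) for at most 10 epochs — sizes at which the full
pipeline trains in about a minute on one CPU while leaving every mechanism
(dropout, attention, KG concatenation, snapshot selection) exercised. The
full-scale defaults (200/50/200/4/50, batch 6, Adam 0.001, 10 epochs) remain
the package defaults. KG recovery
analyses use roughly 60 entities, 4 relations and `k = 8`.

## Known limitations

- Pure-R training is practical at desk scale but not at the scale of the
  full real-world corpus (thousands of instances at 350-dimensional
  token representations).
- The literal LSTM wiring leaves `o` and `c_t` disconnected from
  the output; both wirings are provided, and neither is asserted to be the
  original authors' implementation.
- Entity mentions recorded in the input are authoritative: duplicate
  textual occurrences of an entity are not re-linked.
- The KG consumes pre-extracted triples; mining triples from literature is
  out of scope.
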