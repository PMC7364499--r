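#' Construct a relation instance
#'
#' A relation instance is a (possibly multi-sentence) token sequence with
#' role-tagged entity mentions and a gold label. Token coordinates are
#' 0-based and spans are half-open, matching the on-disk JSON-lines schema.
#'
#' @param doc_id opaque document identifier.
#' @param tokens character vector of word tokens (punctuation-free).
#' @param sentence_breaks integer vector of 0-based token indices at which
#'   each sentence starts; the first element is always 0.
#' @param mentions named list, one element per role in
#'   `c("drug","gene","mutation")` (gene optional for binary instances),
#'   each a list with `entity_id`, `start`, `end` (0-based half-open span
#'   into `tokens`).
#' @param label gold relation label.
#' @return object of class `relation_instance`.
#' @export
relation_instance <- function(doc_id, tokens, sentence_breaks = 0L,
                              mentions, label) {
  n <- length(tokens)
  if (n == 0L) stop("instance has no tokens")
  sentence_breaks <- as.integer(sentence_breaks)
  if (length(sentence_breaks) == 0L || sentence_breaks[1L] != 0L)
    stop("sentence_breaks must start at 0")
  if (is.unsorted(sentence_breaks, strictly = TRUE) || any(sentence_breaks >= n))
    stop("sentence_breaks must be strictly increasing token indices")
  roles <- names(mentions)
  if (is.null(roles) || anyDuplicated(roles) ||
      !all(roles %in% c("drug", "gene", "mutation")))
    stop("mentions must be uniquely named with roles drug/gene/mutation")
  for (role in roles) {
    m <- mentions[[role]]
    if (is.null(m$entity_id)) stop("mention for role ", role, " lacks entity_id")
    if (m$start < 0L || m$end > n || m$start >= m$end)
      stop(sprintf("mention span [%d,%d) out of range for role %s (n=%d)",
                   m$start, m$end, role, n))
    mentions[[role]] <- list(entity_id = as.character(m$entity_id),
                             start = as.integer(m$start),
                             end = as.integer(m$end))
  }
  structure(list(doc_id = as.character(doc_id), tokens = as.character(tokens),
                 sentence_breaks = sentence_breaks, mentions = mentions,
                 label = as.character(label)),
            class = "relation_instance")
}

#' @export
print.relation_instance <- function(x, ...) {
  cat(sprintf("<relation_instance %s> %d tokens, %d sentence(s), label=%s\n",
              x$doc_id, length(x$tokens), length(x$sentence_breaks),
              dQuote(x$label)))
  for (role in names(x$mentions)) {
    m <- x$mentions[[role]]
    cat(sprintf("  %-8s %s @ [%d,%d)\n", role, m$entity_id, m$start, m$end))
  }
  invisible(x)
}

#' Bundle instances with their label scheme
#' @param instances list of [relation_instance()] objects.
#' @param scheme a [label_scheme()].
#' @return object of class `nre_dataset`.
#' @export
nre_dataset <- function(instances, scheme) {
  if (length(instances) == 0L) stop("empty dataset")
  bad <- vapply(instances, function(x) !x$label %in% scheme$classes, logical(1))
  if (any(bad))
    stop("instance label outside the ", scheme$mode, " scheme: ",
         instances[[which(bad)[1L]]]$label)
  structure(list(instances = instances, scheme = scheme),
            class = "nre_dataset")
}

#' @export
print.nre_dataset <- function(x, ...) {
  labs <- vapply(x$instances, `[[`, character(1), "label")
  cat(sprintf("<nre_dataset> %d instances, scheme=%s\n", length(x$instances),
              x$scheme$mode))
  print(table(labs))
  invisible(x)
}

#' @export
length.nre_dataset <- function(x) length(x$instances)

#' Subset a dataset by instance index
#' @param x an `nre_dataset`.
#' @param i integer indices.
#' @param ... unused.
#' @export
`[.nre_dataset` <- function(x, i, ...) nre_dataset(x$instances[i], x$scheme)

# characters stripped from token edges; internal punctuation (hyphens,
# slashes, digits with commas inside identifiers) survives
.edge_punct <- "^[].,;:!?()\"'“”‘’[]+|[].,;:!?()\"'“”‘’[]+$"

#' Whitespace tokenization with edge punctuation stripped
#'
#' Sentences are split on whitespace; standalone punctuation tokens are
#' dropped and leading/trailing punctuation is stripped from the remaining
#' tokens. Case is preserved. This is the convention under which the
#' relative-distance worked example (22, 13, -2) is reproduced.
#'
#' @param raw_sentences character vector of raw sentence strings.
#' @return list of character vectors, one per input sentence (possibly
#'   empty for empty input strings).
#' @examples
#' normalize_tokens("treated with gefitinib and showed a partial response.")
#' @export
normalize_tokens <- function(raw_sentences) {
  lapply(as.character(raw_sentences), function(s) {
    s <- trimws(s)
    if (!nzchar(s)) return(character(0))
    toks <- strsplit(s, "[[:space:]]+")[[1L]]
    toks <- gsub(.edge_punct, "", toks)
    toks[nzchar(toks)]
  })
}

# sentence-local (sentence_index, token_start, token_end) -> flat span
flatten_span <- function(sentence_breaks, sentence_index, start, end) {
  off <- sentence_breaks[sentence_index + 1L]
  c(start = off + start, end = off + end)
}

# flat span -> sentence-local coordinates (exact inverse of flatten_span)
unflatten_span <- function(sentence_breaks, start, end) {
  si <- findInterval(start, sentence_breaks) - 1L
  off <- sentence_breaks[si + 1L]
  list(sentence_index = si, token_start = start - off, token_end = end - off)
}

#' Read relation instances from a JSON-lines file
#'
#' Each line holds one instance with keys `doc_id`, `sentences` (list of
#' token lists), `mentions` (role, entity_id, sentence_index, token_start,
#' token_end; all indices 0-based, spans half-open and sentence-local) and
#' `label`. Sentences are flattened to one token sequence, spans re-indexed
#' to the flat sequence and sentence starts recorded, so sentence-local
#' coordinates remain recoverable. Labels are remapped into `scheme`.
#'
#' @param path file path.
#' @param scheme a [label_scheme()]; defaults to multiclass.
#' @return an [nre_dataset()].
#' @export
read_instances <- function(path, scheme = label_scheme("multiclass")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty dataset: ", path)
  instances <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[ln], simplifyVector = FALSE),
                    error = function(e)
                      stop(sprintf("parse error at line %d of %s: %s",
                                   ln, path, conditionMessage(e)), call. = FALSE))
    sent_tokens <- lapply(rec$sentences, function(s) unlist(s, use.names = FALSE))
    lens <- vapply(sent_tokens, length, integer(1))
    breaks <- cumsum(c(0L, lens[-length(lens)]))
    tokens <- unlist(sent_tokens, use.names = FALSE)
    mentions <- list()
    for (m in rec$mentions) {
      if (!m$role %in% c("drug", "gene", "mutation"))
        stop(sprintf("line %d: unknown mention role %s", ln, dQuote(m$role)))
      sp <- flatten_span(breaks, m$sentence_index, m$token_start, m$token_end)
      mentions[[m$role]] <- list(entity_id = m$entity_id,
                                 start = sp[["start"]], end = sp[["end"]])
    }
    label <- tryCatch(map_label(rec$label, scheme),
                      error = function(e)
                        stop(sprintf("line %d: %s", ln, conditionMessage(e)),
                             call. = FALSE))
    instances[[ln]] <- tryCatch(
      relation_instance(rec$doc_id, tokens, breaks, mentions, label),
      error = function(e) stop(sprintf("line %d: %s", ln, conditionMessage(e)),
                               call. = FALSE))
  }
  nre_dataset(instances, scheme)
}

#' Write relation instances as JSON-lines
#'
#' Inverse of [read_instances()]: flat spans are converted back to
#' sentence-local coordinates.
#'
#' @param dataset an [nre_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_instances <- function(dataset, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (inst in dataset$instances) {
    brk <- inst$sentence_breaks
    ends <- c(brk[-1L], length(inst$tokens))
    sentences <- mapply(function(s, e) inst$tokens[(s + 1L):e],
                        brk, ends, SIMPLIFY = FALSE)
    mentions <- lapply(names(inst$mentions), function(role) {
      m <- inst$mentions[[role]]
      loc <- unflatten_span(brk, m$start, m$end)
      list(role = role, entity_id = m$entity_id,
           sentence_index = loc$sentence_index,
           token_start = loc$token_start, token_end = loc$token_end)
    })
    rec <- list(doc_id = inst$doc_id, sentences = sentences,
                mentions = mentions, label = inst$label)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Per-token signed distances to the three entity mentions
#'
#' For token index `i` and role with mention head index `e` (first token of
#' the span), the distance is `i - e`: 0 at the entity itself, positive to
#' its right, negative to its left. Values are clipped to
#' `[-max_distance, max_distance]`. Roles absent from the instance (the
#' gene slot of a binary drug-mutation instance) yield a zero column.
#'
#' @param instance a [relation_instance()].
#' @param max_distance clip radius for the distance, default 128.
#' @param roles roles that must be present; defaults to the roles carried
#'   by the instance's mentions plus `drug` and `mutation`.
#' @return integer matrix `n x 3` with columns `drug`, `gene`, `mutation`,
#'   of class `position_features`.
#' @export
compute_position_features <- function(instance, max_distance = 128L,
                                      roles = NULL) {
  max_distance <- stopifnot_scalar_int(max_distance, "max_distance")
  need <- roles %||% c("drug", "mutation")
  missing_roles <- setdiff(need, names(instance$mentions))
  if (length(missing_roles))
    stop("instance lacks required role(s): ",
         paste(missing_roles, collapse = ", "))
  n <- length(instance$tokens)
  out <- matrix(0L, n, 3L, dimnames = list(NULL, c("drug", "gene", "mutation")))
  for (role in intersect(colnames(out), names(instance$mentions))) {
    head_idx <- instance$mentions[[role]]$start
    d <- seq_len(n) - 1L - head_idx
    out[, role] <- pmax(-max_distance, pmin(max_distance, d))
  }
  structure(out, class = c("position_features", class(out)),
            max_distance = max_distance)
}

#' Cross-validation folds with a held-out validation split
#'
#' Partitions `1..n` into `k` disjoint test folds covering the data; for
#' each fold, a validation set is drawn uniformly at random from the
#' remaining training portion. The validation size is
#' `min(validation_size, floor(0.05 * |train|))` so the protocol stays
#' meaningful on small corpora. Partitions are a pure function of
#' `(n, k, seed)`.
#'
#' @param dataset an [nre_dataset()] or a single integer count.
#' @param k number of folds (default 5).
#' @param validation_size requested validation-set size (default 200).
#' @param seed integer seed.
#' @return list of `k` lists with integer index vectors `train`,
#'   `validation`, `test` (1-based).
#' @export
split_folds <- function(dataset, k = 5L, validation_size = 200L, seed = 1L) {
  n <- if (inherits(dataset, "nre_dataset")) length(dataset$instances)
       else stopifnot_scalar_int(dataset, "dataset")
  k <- stopifnot_scalar_int(k, "k", min = 2L)
  if (n < k) stop(sprintf("dataset of size %d cannot be split into %d folds", n, k))
  validation_size <- stopifnot_scalar_int(validation_size, "validation_size",
                                          min = 0L)
  with_seed(derive_seed(seed, "split"), {
    perm <- sample.int(n)
    folds <- split(perm, rep(seq_len(k), length.out = n))
    lapply(seq_len(k), function(i) {
      test <- sort(folds[[i]])
      pool <- sort(unlist(folds[-i], use.names = FALSE))
      vs <- min(validation_size, floor(0.05 * length(pool)))
      val <- if (vs > 0L) sort(sample(pool, vs)) else integer(0)
      list(train = setdiff(pool, val), validation = val, test = test)
    })
  })
}

#' Sequence lengths of a dataset's instances
#' @param dataset an [nre_dataset()].
#' @return integer vector of token counts.
#' @keywords internal
instance_lengths <- function(dataset)
  vapply(dataset$instances, function(x) length(x$tokens), integer(1))
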