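#' Construct a knowledge graph from triples
#'
#' The graph stores entity and relation vocabularies (first-seen order) and
#' a duplicate-free set of `(head, relation, tail)` facts. Triples of the
#' drug-gene and drug-mutation kind share one entity vocabulary.
#'
#' @param head,relation,tail character vectors of equal length.
#' @param allowed_relations optional allow-list of relation names; `NULL`
#'   disables the check. Defaults to the five interaction types.
#' @return object of class `knowledge_graph` with elements `entities`,
#'   `relations`, `triples` (integer matrix, columns `h`, `r`, `t`).
#' @export
knowledge_graph <- function(head, relation, tail,
                            allowed_relations = label_scheme("multiclass")$classes) {
  if (length(head) != length(relation) || length(head) != length(tail))
    stop("head, relation and tail must have equal length")
  if (length(head) == 0L) stop("a knowledge graph needs at least one triple")
  head <- as.character(head); relation <- as.character(relation)
  tail <- as.character(tail)
  if (!is.null(allowed_relations)) {
    bad <- setdiff(unique(relation), allowed_relations)
    if (length(bad))
      stop("unknown relation name(s): ", paste(dQuote(bad), collapse = ", "))
  }
  entities <- unique(c(rbind(head, tail)))   # first-seen order across columns
  relations <- unique(relation)
  trip <- cbind(h = match(head, entities), r = match(relation, relations),
                t = match(tail, entities))
  trip <- trip[!duplicated(paste(trip[, 1], trip[, 2], trip[, 3])), ,
               drop = FALSE]
  structure(list(entities = entities, relations = relations,
                 triples = trip,
                 triple_set = new_triple_set(trip)),
            class = "knowledge_graph")
}

# environment-backed hash set of "h|r|t" keys for filtered sampling/ranking
new_triple_set <- function(trip) {
  env <- new.env(parent = emptyenv(), size = max(16L, 2L * nrow(trip)))
  keys <- sprintf("%d|%d|%d", trip[, 1], trip[, 2], trip[, 3])
  for (k in keys) assign(k, TRUE, envir = env)
  env
}

has_triple <- function(kg, h, r, t)
  exists(sprintf("%d|%d|%d", h, r, t), envir = kg$triple_set, inherits = FALSE)

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d entities, %d relations, %d triples\n",
              length(x$entities), length(x$relations), nrow(x$triples)))
  invisible(x)
}

#' Read a knowledge graph from a 3-column TSV file
#'
#' Columns are `head_id`, `relation`, `tail_id` (no header). Duplicate
#' lines collapse to one fact.
#'
#' @param path file path.
#' @inheritParams knowledge_graph
#' @return a [knowledge_graph()].
#' @export
read_triples <- function(path,
                         allowed_relations = label_scheme("multiclass")$classes) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty triple file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: expected 3 tab-separated columns",
                 bad[1L], path))
  m <- do.call(rbind, parts)
  knowledge_graph(m[, 1], m[, 2], m[, 3], allowed_relations = allowed_relations)
}

#' Write a knowledge graph as 3-column TSV
#' @param kg a [knowledge_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_triples <- function(kg, path) {
  trip <- kg$triples
  writeLines(paste(kg$entities[trip[, 1]], kg$relations[trip[, 2]],
                   kg$entities[trip[, 3]], sep = "\t"), path)
  invisible(path)
}

# resolve entity/relation names to indices, erroring on misses
entity_index <- function(kg, id) {
  i <- match(id, kg$entities)
  if (anyNA(i)) stop("entity id not in KG: ", id[which(is.na(i))[1L]])
  i
}
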