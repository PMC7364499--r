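#' Read pre-trained word vectors (word2vec or GloVe text dialects)
#'
#' The word2vec text dialect carries a `"<n> <dim>"` header line; the GloVe
#' dialect is headerless. Both are auto-detected.
#'
#' @param path text file, one `word v1 v2 ...` record per line.
#' @return named list: `words`, `vectors` (matrix, one row per word).
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty word-vector file: ", path)
  first <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first))))
    lines <- lines[-1L]                      # word2vec header
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  dims <- lengths(parts) - 1L
  if (length(unique(dims)) != 1L)
    stop("inconsistent vector dimensions in ", path)
  words <- vapply(parts, `[[`, character(1), 1L)
  vectors <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  list(words = words, vectors = vectors)
}

#' Build the word and three-entity position embedding tables
#'
#' The word table holds one trainable row per vocabulary word plus a
#' trainable out-of-vocabulary row; three separate position tables (drug,
#' gene, mutation) each span the clipped distance range
#' `-max_distance..max_distance`. Words found in `word_vectors` are
#' initialized from the file, everything else uniform in `[-0.05, 0.05]`.
#'
#' @param vocab character vector of known words.
#' @param d_w word embedding dimension (default 200).
#' @param d_p position embedding dimension, per role (default 50).
#' @param max_distance clip radius of the position feature (default 128).
#' @param word_vectors optional result of [read_word_vectors()].
#' @param seed integer seed for the random initialization.
#' @return object of class `embedding_tables`.
#' @export
embedding_tables <- function(vocab, d_w = 200L, d_p = 50L, max_distance = 128L,
                             word_vectors = NULL, seed = 1L) {
  d_w <- stopifnot_scalar_int(d_w, "d_w")
  d_p <- stopifnot_scalar_int(d_p, "d_p")
  max_distance <- stopifnot_scalar_int(max_distance, "max_distance")
  vocab <- unique(as.character(vocab))
  n_pos <- 2L * max_distance + 1L
  with_seed(derive_seed(seed, "init"), {
    word <- matrix(stats::runif((length(vocab) + 1L) * d_w, -0.05, 0.05),
                   length(vocab) + 1L, d_w)   # last row = OOV
    if (!is.null(word_vectors)) {
      if (ncol(word_vectors$vectors) != d_w)
        stop(sprintf("word-vector file has dim %d, expected %d",
                     ncol(word_vectors$vectors), d_w))
      hit <- match(vocab, word_vectors$words)
      found <- which(!is.na(hit))
      word[found, ] <- word_vectors$vectors[hit[found], , drop = FALSE]
    }
    pos <- replicate(3L, matrix(stats::runif(n_pos * d_p, -0.05, 0.05),
                                n_pos, d_p), simplify = FALSE)
    names(pos) <- c("drug", "gene", "mutation")
    structure(list(vocab = vocab, word = word, pos = pos, d_w = d_w,
                   d_p = d_p, max_distance = max_distance),
              class = "embedding_tables")
  })
}

#' @export
print.embedding_tables <- function(x, ...) {
  cat(sprintf("<embedding_tables> |V|=%d (+OOV), d_w=%d, d_p=%d x 3 roles, max_distance=%d\n",
              length(x$vocab), x$d_w, x$d_p, x$max_distance))
  invisible(x)
}

# row index into the word table (OOV -> last row)
word_row <- function(tables, tokens) {
  i <- match(tokens, tables$vocab)
  i[is.na(i)] <- length(tables$vocab) + 1L
  i
}

# row index into a position table for clipped distance d
pos_row <- function(tables, d) as.integer(d) + tables$max_distance + 1L

#' Embed a token sequence with word and position features
#'
#' Row `i` is the concatenation of the word vector of token `i` (unknown
#' words fall to the OOV row) with the three position vectors looked up at
#' the token's clipped distances to the drug, gene and mutation mentions.
#'
#' @param instance a [relation_instance()].
#' @param features a [compute_position_features()] matrix aligned with the
#'   instance tokens.
#' @param tables an [embedding_tables()] object.
#' @return numeric matrix `n x (d_w + 3 d_p)`.
#' @export
embed_sequence <- function(instance, features, tables) {
  n <- length(instance$tokens)
  if (nrow(features) != n)
    stop("position features not aligned with tokens")
  X <- cbind(tables$word[word_row(tables, instance$tokens), , drop = FALSE],
             tables$pos$drug[pos_row(tables, features[, "drug"]), , drop = FALSE],
             tables$pos$gene[pos_row(tables, features[, "gene"]), , drop = FALSE],
             tables$pos$mutation[pos_row(tables, features[, "mutation"]), , drop = FALSE])
  unname(X)
}
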