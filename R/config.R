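#' Training configuration
#'
#' Defaults follow the reference parameter design: word embedding 200,
#' position embedding 50 per role, Bi-LSTM hidden 200 per direction
#' (multihead model dim 400), 4 heads, relation-vector dimension 50,
#' minibatch 6, Adam learning rate 0.001, 10 epochs, and 0.5 dropout on
#' the recurrent inputs and the pooled representation. Any field can be
#' overridden; unknown fields are an error.
#'
#' @param ... overrides of the fields listed above, e.g. `epochs = 5`.
#' @return object of class `train_config`.
#' @examples
#' train_config(epochs = 3, hidden = 32)
#' @export
train_config <- function(...) {
  defaults <- list(
    d_w = 200L, d_p = 50L, hidden = 200L, heads = 4L, k = 50L,
    max_distance = 128L,
    batch_size = 6L, learning_rate = 0.001, epochs = 10L,
    recurrent_dropout = 0.5, output_dropout = 0.5,
    kg_variant = "TransR", pooling = "max",
    gate_variant = "literal", softmax_scale = "per_head",
    train_word_embeddings = TRUE, allow_binary_kg = FALSE,
    grad_clip = 5, seed = 1L)
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1L]]) &&
      is.null(names(overrides)))
    overrides <- overrides[[1L]]
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  for (nm in c("d_w", "d_p", "hidden", "heads", "k", "max_distance",
               "batch_size", "epochs", "seed"))
    cfg[[nm]] <- stopifnot_scalar_int(cfg[[nm]], nm,
                                      min = if (nm == "epochs") 0L else 1L)
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  for (nm in c("recurrent_dropout", "output_dropout"))
    if (cfg[[nm]] < 0 || cfg[[nm]] >= 1) stop(nm, " must be in [0, 1)")
  if ((2L * cfg$hidden) %% cfg$heads != 0L)
    stop("2*hidden must be divisible by the head count")
  structure(cfg, class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat("<train_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a training configuration from a YAML or JSON file
#'
#' The file holds a flat key/value mapping whose keys mirror
#' [train_config()]; unknown keys are an error.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a [train_config()].
#' @export
read_train_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must hold a key/value mapping")
  do.call(train_config, vals)
}
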