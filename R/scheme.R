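#' Label schemes for drug-gene-mutation relation instances
#'
#' The fine-grained (multiclass) scheme distinguishes five interaction
#' types; the binary scheme collapses every informative type to `"yes"`
#' and keeps `"none"` as `"no"`.
#'
#' @param mode `"multiclass"` or `"binary"`.
#' @return An object of class `label_scheme` with elements `mode` and
#'   `classes` (ordered class names).
#' @examples
#' label_scheme("multiclass")$classes
#' @export
label_scheme <- function(mode = c("multiclass", "binary")) {
  mode <- match.arg(mode)
  classes <- switch(mode,
    multiclass = c("resistance or nonresponse", "sensitivity", "response",
                   "resistance", "none"),
    binary = c("yes", "no"))
  structure(list(mode = mode, classes = classes), class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("<label_scheme: %s> %s\n", x$mode,
              paste(x$classes, collapse = " | ")))
  invisible(x)
}

#' Map a fine-grained label into a scheme
#'
#' Under the binary scheme every non-`"none"` multiclass label maps to
#' `"yes"` and `"none"` maps to `"no"`; labels already in the scheme pass
#' through unchanged.
#'
#' @param label character label.
#' @param scheme a [label_scheme()].
#' @return a label valid under `scheme`.
#' @export
map_label <- function(label, scheme) {
  if (label %in% scheme$classes) return(label)
  multi <- label_scheme("multiclass")$classes
  if (scheme$mode == "binary" && label %in% multi)
    return(if (label == "none") "no" else "yes")
  stop(sprintf("unknown label %s for %s scheme", dQuote(label), scheme$mode))
}

#' Roles a scheme requires on each instance
#' @param scheme a [label_scheme()].
#' @return character vector of required mention roles.
#' @export
required_roles <- function(scheme) {
  if (scheme$mode == "binary") c("drug", "mutation")
  else c("drug", "gene", "mutation")
}
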