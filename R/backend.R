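#' Embedding backends
#'
#' The conversation recommender is agnostic to the text-embedding model: any
#' backend satisfying this contract can drive it. A backend fixes an output
#' `dimension` and maps a character vector of texts to a numeric matrix with
#' one row per text. The contract requires determinism (identical text gives
#' an identical vector), one output row per input, and a non-zero vector for
#' non-empty text. Production systems typically plug in a multilingual
#' paraphrase sentence-transformer with mean pooling over the final hidden
#' layer; the package ships [fixture_backend()], a deterministic hashed
#' bag-of-tokens embedder, so the full pipeline runs with no model downloads.
#'
#' @param dimension Positive integer dimension of the embedding vectors.
#' @param embed A function `character vector -> numeric matrix` with
#'   `length(texts)` rows and `dimension` columns.
#' @param name Backend label used in error messages.
#' @return An object of class `embedding_backend`.
#' @export
embedding_backend <- function(dimension, embed, name = "custom") {
  if (!is.numeric(dimension) || length(dimension) != 1 || dimension < 1) {
    abort("`dimension` must be a positive integer")
  }
  if (!is.function(embed)) abort("`embed` must be a function")
  structure(
    list(dimension = as.integer(dimension), embed = embed, name = name),
    class = "embedding_backend"
  )
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat(sprintf("<embedding_backend '%s', dimension = %d>\n", x$name,
              x$dimension))
  invisible(x)
}

#' Embed a batch of texts
#'
#' Runs the backend and enforces its contract: one row per text with the
#' declared dimension. Backend failures are rethrown with the offending
#' batch identified.
#'
#' @param backend An [embedding_backend()].
#' @param texts Character vector of non-empty texts.
#' @return A numeric matrix, `length(texts)` rows by `backend$dimension`
#'   columns, with `texts` as row names.
#' @export
embed_texts <- function(backend, texts) {
  stopifnot(inherits(backend, "embedding_backend"))
  if (length(texts) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = backend$dimension))
  }
  if (!is.character(texts) || any(is.na(texts)) || any(!nzchar(trimws(texts)))) {
    abort("`texts` must be non-empty strings")
  }
  vecs <- tryCatch(
    backend$embed(texts),
    error = function(e) {
      abort(sprintf(
        "embedding backend '%s' failed on a batch of %d text(s) (first: %s): %s",
        backend$name, length(texts),
        substr(texts[1], 1, 40), conditionMessage(e)
      ), parent = e)
    }
  )
  if (!is.matrix(vecs) || nrow(vecs) != length(texts) ||
      ncol(vecs) != backend$dimension) {
    abort(sprintf(
      "backend '%s' violated its contract: expected %d x %d matrix",
      backend$name, length(texts), backend$dimension
    ))
  }
  rownames(vecs) <- texts
  vecs
}
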