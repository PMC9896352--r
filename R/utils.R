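#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   left_join distinct n bind_rows row_number desc across all_of
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Stable 32-bit rolling hash of a token; used to derive per-token embedding
# seeds that do not depend on R's serialization internals.
token_hash <- function(token) {
  bytes <- utf8ToInt(token)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Lowercase word tokenizer shared by the importance filter and the fixture
# embedding backend. Splits on any non-alphanumeric run.
tokenize <- function(text) {
  tokens <- unlist(strsplit(tolower(text), "[^a-z0-9]+"))
  tokens[nzchar(tokens)]
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  as.integer(seed %% 2147483647L)
}
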