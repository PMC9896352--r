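#' Validate a content-card catalog
#'
#' A catalog is a tibble with one row per self-care activity card and columns
#' `card_id`, `title`, `description`, and `category`. Card ids must be unique
#' and non-empty; descriptions and categories must be non-empty (descriptions
#' are what the conversation recommender embeds).
#'
#' @param catalog A data frame of cards.
#' @return The catalog as a tibble, rows sorted by `card_id` (the canonical
#'   iteration order), invisibly classed as validated.
#' @export
validate_catalog <- function(catalog) {
  assert_columns(catalog, c("card_id", "title", "description", "category"),
                 "catalog")
  catalog <- as_tibble(catalog)
  catalog$card_id <- as.character(catalog$card_id)
  empty_id <- !nzchar(trimws(catalog$card_id)) | is.na(catalog$card_id)
  if (any(empty_id)) {
    abort(sprintf("catalog rows %s have empty card_id",
                  paste(which(empty_id), collapse = ", ")))
  }
  dup <- unique(catalog$card_id[duplicated(catalog$card_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate card_id in catalog: %s",
                  paste(dup, collapse = ", ")))
  }
  for (col in c("description", "category")) {
    bad <- is.na(catalog[[col]]) | !nzchar(trimws(catalog[[col]]))
    if (any(bad)) {
      abort(sprintf("card(s) %s have empty %s",
                    paste(catalog$card_id[bad], collapse = ", "), col))
    }
  }
  arrange(catalog, .data$card_id)
}

#' Read a card catalog from CSV or JSON
#'
#' The CSV form has header `card_id,title,description,category` (RFC 4180
#' quoting, UTF-8). The JSON form is an array of objects with those keys.
#'
#' @param path Path to the catalog file.
#' @param format `"csv"` or `"json"`; by default guessed from the extension.
#' @return A validated catalog tibble sorted by `card_id`.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' cat <- generate_catalog(n_cards = 6, n_categories = 2, seed = 1)
#' write_catalog(cat, path)
#' read_catalog(path)
read_catalog <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("catalog file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  raw <- switch(format,
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE),
    json = as_tibble(jsonlite::fromJSON(path))
  )
  validate_catalog(raw)
}

#' Write a card catalog to CSV or JSON
#'
#' Writes only the four canonical columns; auxiliary columns (such as the
#' synthetic generator's planted `topic`) are dropped so that on-disk
#' catalogs are interchangeable.
#'
#' @param catalog A catalog tibble.
#' @inheritParams read_catalog
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  catalog <- validate_catalog(catalog)
  out <- catalog[, c("card_id", "title", "description", "category")]
  switch(format,
    csv = readr::write_csv(out, path, progress = FALSE),
    json = jsonlite::write_json(out, path, dataframe = "rows", pretty = TRUE)
  )
  invisible(path)
}

#' Category membership of a catalog
#'
#' @param catalog A catalog tibble.
#' @return A tibble with one row per category: `category`, `n_cards`, and a
#'   `card_ids` list-column. The union of `card_ids` exactly partitions the
#'   catalog.
#' @export
category_index <- function(catalog) {
  catalog <- validate_catalog(catalog)
  catalog |>
    group_by(.data$category) |>
    summarise(n_cards = n(), card_ids = list(sort(.data$card_id)),
              .groups = "drop") |>
    arrange(.data$category)
}
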