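#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a MAR table
#'
#' One row per (annotator, class) score, with the per-annotator
#' macro-average and the all-annotator class means appended as `statistic`
#' rows, mirroring how agreement tables are usually printed.
#'
#' @param x A `mar_table` from [mar()] or [mar_aggregate()].
#' @param ... Unused.
#' @return A tibble `annotator_id`, `class`, `f1`, `statistic`.
#' @export
tidy.mar_table <- function(x, ...) {
  bind_rows(
    mutate(x$by_annotator, statistic = "per_class_f1"),
    x$macro |>
      mutate(class = "macroaverage", statistic = "macro_f1") |>
      dplyr::rename(f1 = "macro_f1"),
    x$by_class |>
      mutate(annotator_id = "all", statistic = "class_mean") |>
      dplyr::rename(f1 = "mean_f1")
  )[, c("annotator_id", "class", "f1", "statistic")]
}

#' Summarise a MAR table in one row
#'
#' @param x A `mar_table`.
#' @param ... Unused.
#' @return A one-row tibble with `overall_mar`, `n_annotators`, `n_items`.
#' @export
glance.mar_table <- function(x, ...) {
  tibble(
    overall_mar = x$overall,
    n_annotators = nrow(x$macro),
    n_items = x$n_items
  )
}

#' Tidy a recommendation list
#'
#' @param x A [recommendation_list].
#' @param ... Unused.
#' @return A plain tibble `rank`, `card_id`, `score`, `algorithm`.
#' @export
tidy.recommendation_list <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "recommendation_list")
  out
}

#' Summarise a recommendation list in one row
#'
#' @param x A [recommendation_list].
#' @param ... Unused.
#' @return A one-row tibble with `algorithm`, `n_cards`, `top_card`,
#'   `top_score`.
#' @export
glance.recommendation_list <- function(x, ...) {
  tibble(
    algorithm = if (nrow(x) > 0) x$algorithm[1] else NA_character_,
    n_cards = nrow(x),
    top_card = if (nrow(x) > 0) x$card_id[1] else NA_character_,
    top_score = if (nrow(x) > 0) x$score[1] else NA_real_
  )
}
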