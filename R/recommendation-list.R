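#' Recommendation lists
#'
#' All three recommenders return the same shape: a tibble of class
#' `recommendation_list` with columns `rank` (1 = top of the shelf),
#' `card_id`, `score` (the ranking score, `NA` for cards that were inserted
#' by diversity sampling or drawn at random), and `algorithm`
#' (`"onboarding"`, `"conversation"` or `"random"`). Card ids are unique
#' within a list.
#'
#' @param items A tibble with columns `card_id` and `score`, already in rank
#'   order.
#' @param algorithm Which recommender produced the list.
#' @param generated_at Timestamp recorded on the list.
#' @return A `recommendation_list` tibble.
#' @name recommendation_list
#' @export
new_recommendation_list <- function(items,
                                    algorithm = c("onboarding", "conversation",
                                                  "random"),
                                    generated_at = Sys.time()) {
  algorithm <- match.arg(algorithm)
  assert_columns(items, c("card_id", "score"), "recommendation items")
  if (anyDuplicated(items$card_id)) {
    abort("recommendation list contains duplicate card ids")
  }
  out <- tibble(
    rank = seq_len(nrow(items)),
    card_id = items$card_id,
    score = items$score,
    algorithm = algorithm
  )
  attr(out, "generated_at") <- generated_at
  class(out) <- c("recommendation_list", class(out))
  out
}

#' @export
print.recommendation_list <- function(x, ...) {
  alg <- if (nrow(x) > 0) x$algorithm[1] else "(empty)"
  cat(sprintf("<recommendation_list: %d card(s), algorithm = %s>\n",
              nrow(x), alg))
  NextMethod()
}

#' Write a recommendation list as JSON
#'
#' @param x A `recommendation_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recommendations <- function(x, path) {
  stopifnot(inherits(x, "recommendation_list"))
  obj <- list(
    algorithm = if (nrow(x) > 0) x$algorithm[1] else NA_character_,
    generated_at = format(attr(x, "generated_at") %||% Sys.time(),
                          "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    items = as.data.frame(x[, c("rank", "card_id", "score")])
  )
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}
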