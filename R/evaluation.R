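#' Collapse 3-level relevance labels to binary
#'
#' Annotators grade each recommended card as not, somewhat, or very relevant
#' to a session; the two positive grades are combined as "relevant" for
#' analysis.
#'
#' @param label Character vector of labels among `not_relevant`,
#'   `somewhat_relevant`, `very_relevant`.
#' @return Character vector of `"relevant"` / `"not_relevant"`.
#' @export
binarize_relevance <- function(label) {
  out <- dplyr::case_match(
    label,
    c("somewhat_relevant", "very_relevant") ~ "relevant",
    "not_relevant" ~ "not_relevant"
  )
  if (any(is.na(out) & !is.na(label)) || any(is.na(label))) {
    bad <- unique(label[is.na(out) | is.na(label)])
    abort(sprintf("unknown relevance label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  out
}

#' Majority vote over annotators
#'
#' Per item, the binary label held by more than half the annotators. The
#' annotator count per item must be odd so the majority is always defined.
#'
#' @param annotations A data frame with columns `annotator_id`, `label`
#'   (already binarized) and the item-identifying columns in `item_cols`.
#' @param item_cols Columns that jointly identify an item.
#' @return A tibble of the item columns plus `majority`.
#' @export
majority_vote <- function(annotations,
                          item_cols = c("session_id", "card_id")) {
  assert_columns(annotations, c("annotator_id", "label", item_cols),
                 "annotations")
  bad <- setdiff(unique(annotations$label), c("relevant", "not_relevant"))
  if (length(bad) > 0) {
    abort(sprintf("labels must be binarized first; found: %s",
                  paste(bad, collapse = ", ")))
  }
  counts <- annotations |>
    group_by(across(all_of(item_cols))) |>
    summarise(n_annotators = dplyr::n_distinct(.data$annotator_id),
              n_relevant = sum(.data$label == "relevant"),
              .groups = "drop")
  if (any(counts$n_annotators %% 2 == 0)) {
    abort("majority vote requires an odd number of annotators per item")
  }
  counts |>
    mutate(majority = ifelse(.data$n_relevant > .data$n_annotators / 2,
                             "relevant", "not_relevant")) |>
    select(all_of(item_cols), "majority")
}

#' Per-class F1 score
#'
#' Standard F1 for one class, treating `reference` as truth. When the class
#' has no true positives and is absent from either side's support, the score
#' is defined as 0.
#'
#' @param predicted,reference Vectors of class labels, equal length.
#' @param class The class scored as positive.
#' @return F1 in \[0, 1\].
#' @export
per_class_f1 <- function(predicted, reference, class) {
  if (length(predicted) != length(reference)) {
    abort(sprintf("length mismatch: %d predictions vs %d references",
                  length(predicted), length(reference)))
  }
  tp <- sum(predicted == class & reference == class)
  fp <- sum(predicted == class & reference != class)
  fn <- sum(predicted != class & reference == class)
  if (tp == 0) return(0)
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  2 * precision * recall / (precision + recall)
}

#' Majority agreement rate (MAR) with macro-F1
#'
#' MAR measures inter-annotator agreement as how well each annotator
#' predicts the panel's majority vote, scored with a classification metric —
#' here per-class F1, macro-averaged over the two binary classes. The
#' overall MAR is the mean of the annotators' macro-averages.
#'
#' @param annotations A data frame with columns `annotator_id`, `label`
#'   (binarized) and the item columns; every annotator must label every
#'   item.
#' @param item_cols Columns that jointly identify an item.
#' @param classes The class labels scored; defaults to the binary relevance
#'   classes.
#' @return An object of class `mar_table`; see [tidy.mar_table()] and
#'   [glance.mar_table()]. Components: `by_annotator` (per annotator x
#'   class F1), `macro` (per-annotator macro-average), `by_class`
#'   (all-annotator mean per class), `overall`.
#' @export
#' @examples
#' ann <- tidyr::expand_grid(annotator_id = c("a1", "a2", "a3"),
#'                           item = 1:4)
#' ann$label <- "relevant"
#' mar(ann, item_cols = "item")$overall # perfect agreement -> 1
mar <- function(annotations, item_cols = c("session_id", "card_id"),
                classes = c("not_relevant", "relevant")) {
  assert_columns(annotations, c("annotator_id", "label", item_cols),
                 "annotations")
  annotators <- sort(unique(annotations$annotator_id))
  if (length(annotators) < 3 || length(annotators) %% 2 == 0) {
    abort("MAR requires an odd panel of at least 3 annotators")
  }
  grid <- tidyr::expand_grid(
    annotator_id = annotators,
    distinct(annotations[, item_cols, drop = FALSE])
  )
  joined <- left_join(grid, annotations,
                      by = c("annotator_id", item_cols))
  if (any(is.na(joined$label))) {
    miss <- joined[is.na(joined$label), , drop = FALSE][1, ]
    abort(sprintf("missing label for annotator '%s' on item (%s)",
                  miss$annotator_id,
                  paste(unlist(miss[item_cols]), collapse = ", ")))
  }

  majority <- majority_vote(annotations, item_cols)
  joined <- left_join(joined, majority, by = item_cols)

  by_annotator <- tidyr::expand_grid(annotator_id = annotators,
                                     class = classes) |>
    mutate(f1 = purrr::map2_dbl(.data$annotator_id, .data$class, function(a, cl) {
      rows <- joined[joined$annotator_id == a, ]
      per_class_f1(rows$label, rows$majority, cl)
    }))

  mar_aggregate(by_annotator, n_items = nrow(majority))
}

#' Aggregate per-annotator, per-class agreement scores into a MAR table
#'
#' The aggregation half of [mar()], usable on its own when the per-class F1
#' scores are already known: macro-average per annotator (unweighted mean
#' over classes), the all-annotator mean per class, and the overall MAR
#' (mean of the macro-averages).
#'
#' @param by_annotator A data frame with columns `annotator_id`, `class`,
#'   `f1`.
#' @param n_items Number of scored items, if known (metadata only).
#' @return A `mar_table` object.
#' @export
mar_aggregate <- function(by_annotator, n_items = NA_integer_) {
  assert_columns(by_annotator, c("annotator_id", "class", "f1"),
                 "by_annotator")
  by_annotator <- as_tibble(by_annotator)
  macro <- by_annotator |>
    group_by(.data$annotator_id) |>
    summarise(macro_f1 = mean(.data$f1), .groups = "drop")
  by_class <- by_annotator |>
    group_by(.data$class) |>
    summarise(mean_f1 = mean(.data$f1), .groups = "drop")
  structure(
    list(by_annotator = by_annotator, macro = macro, by_class = by_class,
         overall = mean(macro$macro_f1), n_items = n_items),
    class = "mar_table"
  )
}

#' @export
print.mar_table <- function(x, digits = 6, ...) {
  cat("Interannotator agreement (majority agreement rate, macro-F1)\n")
  wide <- tidyr::pivot_wider(x$by_annotator, names_from = "annotator_id",
                             values_from = "f1")
  print(as.data.frame(wide), digits = digits, row.names = FALSE)
  cat(sprintf("Overall MAR: %.*f\n", digits, x$overall))
  invisible(x)
}

#' Session-length buckets
#'
#' Sessions are stratified by message count into half-open buckets
#' \[0,5), \[5,10), \[10,20), \[20,40), \[40, Inf) — a partition of the
#' non-negative integers, so a 5-message session falls in "5-10".
#'
#' @param message_count Non-negative integer vector.
#' @return A factor with levels `0-5`, `5-10`, `10-20`, `20-40`,
#'   `40 and above`.
#' @export
bucket_sessions <- function(message_count) {
  if (any(is.na(message_count)) || any(message_count < 0)) {
    abort("message counts must be non-negative")
  }
  cut(message_count, breaks = c(0, 5, 10, 20, 40, Inf), right = FALSE,
      labels = c("0-5", "5-10", "10-20", "20-40", "40 and above"))
}

#' Top-K relevance rate per session
#'
#' The probability that a card among a session's top-`k` recommendations is
#' (majority-)labeled relevant. Every top-`k` card must carry a label;
#' a missing one is an error naming the card, never silently skipped.
#'
#' @param recommendations A data frame with columns `session_id`, `rank`,
#'   `card_id` (one shelf per session).
#' @param relevance A data frame with columns `session_id`, `card_id`,
#'   `majority` (binary labels, e.g. from [majority_vote()]).
#' @param k Number of top-ranked cards scored per session.
#' @return A tibble `session_id`, `n_scored`, `n_relevant`, `rate`.
#' @export
relevance_rate_at_k <- function(recommendations, relevance, k = 5) {
  assert_columns(recommendations, c("session_id", "rank", "card_id"),
                 "recommendations")
  assert_columns(relevance, c("session_id", "card_id", "majority"),
                 "relevance")
  top <- recommendations |>
    filter(.data$rank <= k) |>
    left_join(relevance[, c("session_id", "card_id", "majority")],
              by = c("session_id", "card_id"))
  if (any(is.na(top$majority))) {
    miss <- top[is.na(top$majority), ][1, ]
    abort(sprintf("no relevance label for card '%s' in session '%s'",
                  miss$card_id, miss$session_id))
  }
  top |>
    group_by(.data$session_id) |>
    summarise(n_scored = n(),
              n_relevant = sum(.data$majority == "relevant"),
              rate = .data$n_relevant / .data$n_scored,
              .groups = "drop")
}

#' Mean relevance rate per session-length bucket
#'
#' Unweighted mean of per-session relevance rates within each
#' [bucket_sessions()] bucket.
#'
#' @param per_session Output of [relevance_rate_at_k()].
#' @param session_sizes A data frame `session_id`, `n_messages`.
#' @return A tibble `bucket`, `n_sessions`, `rate`.
#' @export
relevance_by_bucket <- function(per_session, session_sizes) {
  assert_columns(session_sizes, c("session_id", "n_messages"),
                 "session_sizes")
  per_session |>
    left_join(session_sizes, by = "session_id") |>
    mutate(bucket = bucket_sessions(.data$n_messages)) |>
    group_by(.data$bucket) |>
    summarise(n_sessions = n(), rate = mean(.data$rate), .groups = "drop")
}

#' Validate an engagement event log
#'
#' Checks column presence, known event types, and the ordering invariant
#' that a completion of a card by a user is preceded by a click on it.
#'
#' @param events An engagement event data frame with columns `user_id`,
#'   `source`, `algorithm`, `card_id`, `event`, `timestamp`, `age_bin`,
#'   `gender`.
#' @return The events tibble, invisibly validated.
#' @export
validate_events <- function(events) {
  assert_columns(events, c("user_id", "source", "algorithm", "card_id",
                           "event", "timestamp", "age_bin", "gender"),
                 "events")
  events <- as_tibble(events)
  bad <- setdiff(unique(events$event), c("click", "completion"))
  if (length(bad) > 0) {
    abort(sprintf("unknown event type(s): %s", paste(bad, collapse = ", ")))
  }
  chk <- events |>
    group_by(.data$user_id, .data$card_id) |>
    summarise(orphan = any(.data$event == "completion") &&
                (!any(.data$event == "click") ||
                 min(.data$timestamp[.data$event == "completion"]) <
                   min(.data$timestamp[.data$event == "click"])),
              .groups = "drop")
  if (any(chk$orphan)) {
    first <- chk[chk$orphan, ][1, ]
    abort(sprintf("completion without prior click for user '%s', card '%s'",
                  first$user_id, first$card_id))
  }
  invisible(events)
}

#' Read an engagement event CSV
#'
#' Header: `user_id,source,algorithm,card_id,event,timestamp,age_bin,gender`.
#'
#' @param path Path to the CSV file.
#' @return A validated events tibble.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("event file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  validate_events(df)
  as_tibble(df)
}

#' Card completion rates by group
#'
#' The completion rate of a group is completions divided by clicks (the
#' count of card views) within that group. Accepts either a raw event log
#' (a data frame with an `event` column, tallied here) or an already
#' aggregated table with `clicks` and `completions` columns, such as a
#' published results table. Groups with zero clicks get an `NA` rate, never
#' a division error.
#'
#' @param data Event log or aggregated counts.
#' @param ... Grouping columns (tidy-select), e.g. `source`, `algorithm`,
#'   `age_bin`, `gender`. Ignored for pre-aggregated input.
#' @return A tibble of class `completion_rates`: grouping columns plus
#'   `clicks`, `completions`, `rate`.
#' @export
#' @examples
#' printed <- tibble::tibble(
#'   source = c("recommendations", "home"),
#'   clicks = c(7871, 21863), completions = c(3353, 8679)
#' )
#' completion_rates(printed)
completion_rates <- function(data, ...) {
  group_cols <- sapply(rlang::enquos(...), rlang::as_name)
  if (all(c("clicks", "completions") %in% names(data))) {
    out <- as_tibble(data)
  } else {
    assert_columns(data, c("event", group_cols), "events")
    out <- data |>
      group_by(across(all_of(unname(group_cols)))) |>
      summarise(clicks = sum(.data$event == "click"),
                completions = sum(.data$event == "completion"),
                .groups = "drop")
  }
  out <- out |>
    mutate(rate = ifelse(.data$clicks == 0, NA_real_,
                         .data$completions / .data$clicks))
  class(out) <- c("completion_rates", class(out))
  out
}

#' Difference between two rate tables
#'
#' Elementwise algorithm-minus-control difference, matched on bucket label.
#'
#' @param algorithm_rates,control_rates Data frames with columns `bucket`
#'   and `rate` over identical bucket sets.
#' @return A tibble `bucket`, `algorithm`, `control`, `difference`.
#' @export
difference_table <- function(algorithm_rates, control_rates) {
  assert_columns(algorithm_rates, c("bucket", "rate"), "algorithm_rates")
  assert_columns(control_rates, c("bucket", "rate"), "control_rates")
  if (!setequal(algorithm_rates$bucket, control_rates$bucket) ||
      nrow(algorithm_rates) != nrow(control_rates)) {
    abort("bucket labels do not match between the two rate tables")
  }
  tibble(bucket = algorithm_rates$bucket,
         algorithm = algorithm_rates$rate) |>
    left_join(tibble(bucket = control_rates$bucket,
                     control = control_rates$rate),
              by = "bucket") |>
    mutate(difference = .data$algorithm - .data$control)
}

#' Read relevance annotations from CSV
#'
#' Header: `annotator_id,session_id,card_id,label` with 3-level labels.
#'
#' @param path Path to the CSV file.
#' @return A tibble of relevance annotation records.
#' @export
read_relevance_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  assert_columns(df, c("annotator_id", "session_id", "card_id", "label"),
                 "relevance annotation file")
  binarize_relevance(df$label) # validates the label set
  df
}
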