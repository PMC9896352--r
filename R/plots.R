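#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   labs theme_minimal coord_flip facet_wrap
#' @export
ggplot2::autoplot

#' Plot a recommendation shelf
#'
#' Horizontal bars of ranking scores, top of the shelf first. Cards inserted
#' by diversity sampling or drawn at random have no score and are shown at
#' zero.
#'
#' @param object A [recommendation_list].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recommendation_list <- function(object, ...) {
  df <- as_tibble(object)
  df$score_plot <- ifelse(is.na(df$score), 0, df$score)
  ggplot(df, aes(x = stats::reorder(.data$card_id, -.data$rank),
                 y = .data$score_plot)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "ranking score",
         title = sprintf("%s recommendations", df$algorithm[1])) +
    theme_minimal()
}

#' Plot an interannotator agreement table
#'
#' Per-class F1 of each annotator against the majority vote, with the
#' macro-average overlaid.
#'
#' @param object A `mar_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mar_table <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$statistic != "class_mean", ]
  ggplot(df, aes(x = .data$annotator_id, y = .data$f1, fill = .data$class)) +
    geom_col(position = "dodge") +
    labs(x = "annotator", y = "F1 vs majority vote",
         title = sprintf("Majority agreement rate (overall %.3f)",
                         object$overall)) +
    theme_minimal()
}

#' Plot completion rates
#'
#' One bar per group; the grouping columns are pasted into a single label.
#'
#' @param object A `completion_rates` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.completion_rates <- function(object, ...) {
  df <- as_tibble(object)
  group_cols <- setdiff(names(df), c("clicks", "completions", "rate"))
  df$group <- if (length(group_cols) > 0) {
    do.call(paste, c(df[group_cols], sep = " / "))
  } else {
    "all"
  }
  ggplot(df, aes(x = stats::reorder(.data$group, .data$rate),
                 y = .data$rate)) +
    geom_col(fill = "darkseagreen4") +
    coord_flip() +
    labs(x = NULL, y = "completion rate (completions / clicks)") +
    theme_minimal()
}

#' Plot relevance rates by session-length bucket
#'
#' Point-and-line display of mean top-K relevance per bucket, optionally
#' for several arms at once.
#'
#' @param bucket_rates Output of [relevance_by_bucket()], or several such
#'   tables row-bound with an `arm` column.
#' @return A ggplot object.
#' @export
plot_relevance_by_bucket <- function(bucket_rates) {
  assert_columns(bucket_rates, c("bucket", "rate"), "bucket_rates")
  has_arm <- "arm" %in% names(bucket_rates)
  p <- ggplot(bucket_rates,
              aes(x = .data$bucket, y = .data$rate,
                  group = if (has_arm) .data$arm else 1))
  if (has_arm) {
    p <- p + aes(colour = .data$arm)
  }
  p + geom_line() + geom_point(size = 2) +
    labs(x = "messages in session", y = "top-K relevance rate") +
    theme_minimal()
}
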