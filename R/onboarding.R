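#' Aggregate expert annotations into card label vectors
#'
#' Expert annotators each select, for every card, the onboarding answers the
#' card could help address. The selections are pooled into one weight per
#' (card, label): the fraction of that card's annotators who selected the
#' label, so every weight lies in \[0, 1\] and unanimous selections score 1.
#'
#' @param annotations A data frame with columns `annotator_id`, `card_id`,
#'   `label` — one row per selected label.
#' @param space A [label_space()].
#' @param catalog Optional catalog; when given, annotations for unknown cards
#'   error and catalog cards with no annotations are dropped with a warning.
#' @param n_annotators Optional fixed annotator-panel size to use as the
#'   denominator. By default the denominator is the number of distinct
#'   annotators with at least one selection for the card, which undercounts
#'   annotators who selected nothing for that card.
#'
#' @return A tibble with columns `card_id`, `label_id`, `weight`, in label
#'   space order within each card: the card label vectors in long form.
#' @export
#' @examples
#' space <- default_label_space()
#' ann <- tibble::tibble(
#'   annotator_id = rep(c("a1", "a2"), each = 2),
#'   card_id = "c1",
#'   label = c("Anxious", "Career", "Anxious", "Family")
#' )
#' aggregate_annotations(ann, space) # Anxious 1.0, Career 0.5, Family 0.5
aggregate_annotations <- function(annotations, space = default_label_space(),
                                  catalog = NULL, n_annotators = NULL) {
  assert_columns(annotations, c("annotator_id", "card_id", "label"),
                 "annotations")
  annotations <- as_tibble(annotations)
  unknown <- setdiff(annotations$label, space$label)
  if (length(unknown) > 0) {
    abort(sprintf("annotation label(s) not in the label space: %s",
                  paste(unique(unknown), collapse = ", ")))
  }
  if (!is.null(catalog)) {
    catalog <- validate_catalog(catalog)
    stray <- setdiff(annotations$card_id, catalog$card_id)
    if (length(stray) > 0) {
      abort(sprintf("annotations reference card(s) not in the catalog: %s",
                    paste(stray, collapse = ", ")))
    }
    orphans <- setdiff(catalog$card_id, annotations$card_id)
    if (length(orphans) > 0) {
      warn(sprintf("card(s) with no annotations excluded: %s",
                   paste(orphans, collapse = ", ")))
    }
  }

  denom <- annotations |>
    distinct(.data$card_id, .data$annotator_id) |>
    dplyr::count(.data$card_id, name = "n_annotators")
  if (!is.null(n_annotators)) denom$n_annotators <- n_annotators

  # A label may map to more than one coordinate only for the catch-all
  # answer, which is non-informative; it is counted on every matching
  # coordinate so selections remain a subset of the space.
  counts <- annotations |>
    distinct(.data$annotator_id, .data$card_id, .data$label) |>
    left_join(space[, c("label", "label_id")], by = "label",
              relationship = "many-to-many") |>
    dplyr::count(.data$card_id, .data$label_id, name = "n_selected")

  grid <- tidyr::expand_grid(card_id = sort(unique(annotations$card_id)),
                             label_id = space$label_id)
  grid |>
    left_join(counts, by = c("card_id", "label_id")) |>
    left_join(denom, by = "card_id") |>
    mutate(weight = ifelse(is.na(.data$n_selected), 0,
                           .data$n_selected / .data$n_annotators)) |>
    select("card_id", "label_id", "weight")
}

#' Read an annotation file
#'
#' CSV with header `annotator_id,card_id,label`, one row per selected label.
#'
#' @param path Path to the CSV file.
#' @return A tibble of annotation records.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  assert_columns(df, c("annotator_id", "card_id", "label"), "annotation file")
  df
}

#' Vectorize an onboarding response
#'
#' Produces the binary user vector over the label space: 1 at every selected
#' informative label, 0 elsewhere. Catch-all answers contribute nothing.
#'
#' @param response An [onboarding_response()].
#' @param space A [label_space()].
#' @return A named numeric 0/1 vector of length `nrow(space)`, names equal to
#'   `space$label_id`.
#' @export
#' @examples
#' u <- response_to_vector(onboarding_response("Anxious", "Career"))
#' u[u > 0]
response_to_vector <- function(response, space = default_label_space()) {
  stopifnot(inherits(response, "onboarding_response"))
  selected <- (space$question == "feeling" & space$label %in% response$feelings) |
    (space$question == "impact" & space$label %in% response$impacts)
  values <- as.numeric(selected & space$informative)
  names(values) <- space$label_id
  values
}

#' Cosine similarity of two vectors
#'
#' `dot(u, v) / (||u|| ||v||)`, defined as 0 when either vector has zero
#' norm.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single number in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    abort(sprintf("vector length mismatch: %d vs %d", length(u), length(v)))
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Rank cards against an onboarding response vector
#'
#' Scores every card label vector by cosine similarity to the user vector and
#' sorts from most to least similar. Ties are broken by ascending `card_id`
#' so the ordering is deterministic.
#'
#' @param card_vectors Long-form card label vectors as returned by
#'   [aggregate_annotations()].
#' @param response An [onboarding_response()] or a precomputed numeric user
#'   vector over the space.
#' @param space A [label_space()].
#' @return A tibble `card_id`, `score` sorted by descending score.
#' @export
rank_cards_by_onboarding <- function(card_vectors, response,
                                     space = default_label_space()) {
  assert_columns(card_vectors, c("card_id", "label_id", "weight"),
                 "card_vectors")
  u <- if (inherits(response, "onboarding_response")) {
    response_to_vector(response, space)
  } else {
    response
  }
  if (length(u) != nrow(space)) {
    abort("user vector length does not match the label space")
  }
  if (all(u == 0)) {
    abort("onboarding response vector is all zero; route to random recommendations",
          class = "contentrec_zero_response")
  }
  wide <- tidyr::pivot_wider(card_vectors, id_cols = "card_id",
                             names_from = "label_id", values_from = "weight",
                             values_fill = 0)
  mat <- as.matrix(wide[, space$label_id, drop = FALSE])
  scores <- apply(mat, 1, cosine_similarity, v = u)
  tibble(card_id = wide$card_id, score = as.numeric(scores)) |>
    arrange(desc(.data$score), .data$card_id)
}

#' Category-based diversity sampling
#'
#' Replaces a random fraction (one third by default) of a ranked
#' recommendation list with other cards drawn from the replaced card's
#' category, to diversify the shelf a user sees. Exactly
#' `floor(fraction * n)` positions are chosen uniformly without replacement;
#' each replacement is drawn uniformly from the original card's category
#' excluding cards already present in the list (a shelf never shows
#' duplicates). A position with no eligible replacement keeps its card.
#'
#' @param ranked A tibble with a `card_id` column (and optionally `score`),
#'   or a character vector of card ids, in ranked order.
#' @param catalog The full catalog the replacements are drawn from.
#' @param fraction Fraction of positions to replace, in \[0, 1\].
#' @param seed Integer seed for the replacement draws (the only stochastic
#'   step of the onboarding recommender).
#' @return A tibble `card_id`, `score`, `replaced`; substituted cards carry
#'   `NA` score since they were not ranked.
#' @export
category_diversify <- function(ranked, catalog, fraction = 1 / 3, seed) {
  if (is.character(ranked)) ranked <- tibble(card_id = ranked)
  assert_columns(ranked, "card_id", "ranked list")
  if (!("score" %in% names(ranked))) ranked$score <- NA_real_
  catalog <- validate_catalog(catalog)
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1]")
  stray <- setdiff(ranked$card_id, catalog$card_id)
  if (length(stray) > 0) {
    abort(sprintf("ranked card(s) not in catalog: %s",
                  paste(stray, collapse = ", ")))
  }
  seed <- check_seed(seed)

  n <- nrow(ranked)
  out <- tibble(card_id = ranked$card_id, score = ranked$score,
                replaced = FALSE)
  n_rep <- floor(fraction * n)
  if (n_rep == 0) return(out)

  cat_of <- stats::setNames(catalog$category, catalog$card_id)
  withr::with_seed(seed, {
    positions <- sample.int(n, n_rep)
    for (pos in positions) {
      original <- ranked$card_id[pos]
      pool <- catalog$card_id[catalog$category == cat_of[[original]]]
      eligible <- setdiff(pool, out$card_id)
      if (length(eligible) == 0) next
      pick <- if (length(eligible) == 1) eligible else sample(eligible, 1)
      out$card_id[pos] <- pick
      out$score[pos] <- NA_real_
      out$replaced[pos] <- TRUE
    }
  })
  out
}

#' Onboarding-based recommendations
#'
#' The cold-start recommender: vectorize the user's onboarding answers, rank
#' all annotated cards by cosine similarity, keep the top `k`, then apply
#' category-based diversity sampling to the shelf.
#'
#' @inheritParams rank_cards_by_onboarding
#' @inheritParams category_diversify
#' @param k Shelf size (number of cards to return).
#' @return A [recommendation_list] tibble with columns `rank`, `card_id`,
#'   `score`, `algorithm = "onboarding"`.
#' @export
#' @examples
#' cat <- generate_catalog(12, 3, seed = 4)
#' ann <- generate_onboarding_annotations(cat, seed = 4)
#' vecs <- aggregate_annotations(ann)
#' recommend_onboarding(onboarding_response("Anxious", "Career"),
#'                      cat, vecs, k = 5, seed = 9)
recommend_onboarding <- function(response, catalog, card_vectors,
                                 space = default_label_space(), k = 5,
                                 seed, fraction = 1 / 3) {
  if (k < 1) abort("`k` must be at least 1")
  ranked <- rank_cards_by_onboarding(card_vectors, response, space)
  shelf <- utils::head(ranked, k)
  shelf <- category_diversify(shelf, catalog, fraction = fraction, seed = seed)
  new_recommendation_list(shelf[, c("card_id", "score")], "onboarding")
}
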