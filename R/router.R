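#' User state for routing
#'
#' Everything the router needs to pick a recommender: the user's onboarding
#' answers (if any), their latest coaching session (if any), and the current
#' time.
#'
#' @param onboarding An [onboarding_response()] or `NULL`.
#' @param latest_session A [conversation_session()] or `NULL`.
#' @param now Current time (`POSIXct`).
#' @return A list of class `user_state`.
#' @export
user_state <- function(onboarding = NULL, latest_session = NULL,
                       now = Sys.time()) {
  if (!is.null(onboarding)) stopifnot(inherits(onboarding, "onboarding_response"))
  if (!is.null(latest_session)) {
    stopifnot(inherits(latest_session, "conversation_session"))
    if (!is.na(latest_session$ended_at) && now < latest_session$ended_at) {
      abort("`now` cannot precede the latest session's end time")
    }
  }
  structure(list(onboarding = onboarding, latest_session = latest_session,
                 now = now),
            class = "user_state")
}

#' Choose the recommendation algorithm for a user
#'
#' The decision flow: a user with a coaching conversation in the past 60
#' days (inclusive, judged on the session end time) that has more than 15
#' messages gets conversation-based recommendations. Otherwise onboarding
#' answers drive the shelf — unless the user selected only the catch-all
#' answer for both questions (or never answered onboarding), in which case
#' recommendations are random.
#'
#' @param state A [user_state()].
#' @param space The onboarding [label_space()].
#' @return `"conversation"`, `"onboarding"` or `"random"`.
#' @export
#' @examples
#' route_algorithm(user_state()) # no data at all -> "random"
route_algorithm <- function(state, space = default_label_space()) {
  stopifnot(inherits(state, "user_state"))
  ses <- state$latest_session
  if (!is.null(ses) && nrow(ses$messages) > 15 && !is.na(ses$ended_at)) {
    age_days <- as.numeric(difftime(state$now, ses$ended_at, units = "days"))
    if (age_days <= 60) return("conversation")
  }
  if (is.null(state$onboarding) ||
      is_uninformative_response(state$onboarding, space)) {
    return("random")
  }
  "onboarding"
}

#' Seeded random recommendations
#'
#' Uniform sample of `min(k, n)` distinct cards; the control arm of the
#' recommendation system and the fallback when nothing is known about a
#' user.
#'
#' @param catalog The card catalog.
#' @param k Shelf size.
#' @param seed Integer seed.
#' @return A [recommendation_list] with `algorithm = "random"` and `NA`
#'   scores.
#' @export
recommend_random <- function(catalog, k = 5, seed) {
  catalog <- validate_catalog(catalog)
  if (nrow(catalog) == 0) abort("catalog is empty")
  seed <- check_seed(seed)
  k <- min(k, nrow(catalog))
  ids <- withr::with_seed(seed, sample(catalog$card_id, k))
  new_recommendation_list(tibble(card_id = ids, score = NA_real_), "random")
}

#' Recommend content for a user
#'
#' Routes via [route_algorithm()] and dispatches to the matching
#' recommender. A branch that fails (for example, a conversation branch
#' whose session turns out to be empty, or an onboarding branch with an
#' all-zero response vector) falls through to the next branch in the order
#' conversation, onboarding, random — a shelf is always returned.
#'
#' @param state A [user_state()].
#' @param catalog The card catalog.
#' @param card_vectors Card label vectors from [aggregate_annotations()]
#'   (required for the onboarding branch).
#' @param backend An [embedding_backend()] (required for the conversation
#'   branch).
#' @param space The onboarding [label_space()].
#' @param config An [importance_config()].
#' @param k Shelf size.
#' @param seed Integer seed for the stochastic branches.
#' @return A [recommendation_list]; its `algorithm` column records the
#'   branch that actually produced the shelf.
#' @export
recommend_cards <- function(state, catalog, card_vectors = NULL,
                            backend = NULL, space = default_label_space(),
                            config = importance_config(), k = 5, seed) {
  catalog <- validate_catalog(catalog)
  if (nrow(catalog) == 0) abort("catalog is empty")
  branch <- route_algorithm(state, space)

  if (branch == "conversation") {
    res <- tryCatch(
      recommend_conversation(state$latest_session, catalog, backend,
                             config, k),
      error = function(e) NULL
    )
    if (!is.null(res)) return(res)
    branch <- if (!is.null(state$onboarding) &&
                  !is_uninformative_response(state$onboarding, space)) {
      "onboarding"
    } else {
      "random"
    }
  }
  if (branch == "onboarding") {
    res <- tryCatch(
      recommend_onboarding(state$onboarding, catalog, card_vectors, space,
                           k = k, seed = seed),
      error = function(e) NULL
    )
    if (!is.null(res)) return(res)
  }
  recommend_random(catalog, k, seed)
}
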