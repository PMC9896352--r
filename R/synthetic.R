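#' Topic banks for synthetic text
#'
#' A topic bank drives every synthetic text generator: each topic owns a
#' word list, pairwise disjoint from every other topic and from the shared
#' filler vocabulary. Disjointness is what makes planted relevance
#' recoverable — a card and a session about the same topic share words,
#' while off-topic pairs overlap only on filler.
#'
#' @param topics Named list of character vectors (topic word lists).
#' @param filler Character vector of neutral words mixed into all texts.
#' @return A list of class `topic_bank`.
#' @export
topic_bank <- function(topics, filler) {
  stopifnot(is.list(topics), !is.null(names(topics)), is.character(filler))
  all_words <- c(unlist(topics), filler)
  if (anyDuplicated(all_words)) {
    abort(sprintf(
      "topic and filler word lists must be pairwise disjoint; duplicated: %s",
      paste(unique(all_words[duplicated(all_words)]), collapse = ", ")
    ))
  }
  structure(list(topics = topics, filler = filler), class = "topic_bank")
}

#' @rdname topic_bank
#' @export
default_topic_bank <- function() {
  topic_bank(
    topics = list(
      anxiety = c("panic", "worry", "racing", "nervous", "jitters", "dread",
                  "restless", "uneasy"),
      sleep = c("insomnia", "bedtime", "rest", "dreams", "drowsy", "nap",
                "waking", "snooze"),
      depression = c("sadness", "hopeless", "numb", "gloom", "empty",
                     "crying", "low", "withdrawn"),
      work = c("deadlines", "workload", "boss", "meetings", "burnout",
               "office", "projects", "overtime"),
      relationships = c("partner", "arguments", "trust", "intimacy",
                        "breakup", "listening", "boundaries", "conflict"),
      grief = c("loss", "mourning", "funeral", "memories", "missing",
                "bereaved", "sorrow", "grieving"),
      mindfulness = c("breathing", "meditation", "present", "awareness",
                      "calm", "grounding", "stillness", "body"),
      finance = c("money", "debt", "bills", "budget", "savings", "spending",
                  "rent", "paycheck"),
      health = c("exercise", "nutrition", "doctor", "pain", "fatigue",
                 "illness", "recovery", "fitness"),
      motivation = c("goals", "procrastination", "energy", "focus", "habits",
                     "routine", "purpose", "drive")
    ),
    filler = c("i", "feel", "about", "with", "really", "lately", "been",
               "having", "trouble", "my", "the", "and", "some", "much",
               "keeps", "getting")
  )
}

# Short small-talk and scheduling lines; all are eliminated by the default
# importance filter.
greeting_pool <- function() {
  c("hi", "hello", "good morning", "good afternoon", "thanks", "thank you",
    "take care", "sounds good", "see you tuesday at 3", "talk soon",
    "have a great day", "same time next week")
}

#' Deterministic fixture embedding backend
#'
#' A hashed bag-of-tokens embedder satisfying the [embedding_backend()]
#' contract with no model downloads: each lowercase token maps to a fixed
#' pseudo-random unit-scale vector derived from a stable 32-bit hash of the
#' token and the backend seed, and a text embeds as the L2-normalized sum of
#' its token vectors. Identical texts (and any reordering of the same
#' tokens) embed identically; distinct token sets are nearly orthogonal in
#' expectation, so lexical overlap drives cosine similarity.
#'
#' @param dimension Embedding dimension (at least 8).
#' @param seed Integer seed fixing the token-vector table.
#' @return An [embedding_backend()].
#' @export
#' @examples
#' b <- fixture_backend(seed = 1)
#' v <- embed_texts(b, c("anxiety at work", "work at anxiety"))
#' all.equal(v[1, ], v[2, ], check.attributes = FALSE) # bag property
fixture_backend <- function(dimension = 32, seed = 0) {
  if (dimension < 8) abort("`dimension` must be at least 8")
  seed <- check_seed(seed)
  cache <- new.env(parent = emptyenv())
  token_vector <- function(token) {
    if (!is.null(cache[[token]])) return(cache[[token]])
    h <- (token_hash(token) + (seed * 7919) %% 2147483647) %% 2147483647
    v <- withr::with_seed(as.integer(h), stats::rnorm(dimension))
    cache[[token]] <- v
    v
  }
  embed <- function(texts) {
    t(vapply(texts, function(text) {
      tokens <- tokenize(text)
      if (length(tokens) == 0) tokens <- trimws(tolower(text))
      v <- rowSums(vapply(tokens, token_vector,
                          numeric(dimension)))
      v / sqrt(sum(v^2))
    }, numeric(dimension), USE.NAMES = FALSE))
  }
  embedding_backend(dimension, embed, name = "fixture-hashed-bow")
}

#' Generate a synthetic card catalog with planted topics
#'
#' Cards are assigned a topic (round-robin over the bank's topics) and a
#' category (round-robin over `n_categories` synthetic category names);
#' each description is a seeded draw of words from the card's topic plus a
#' little filler, so it contains words from its own topic and none from any
#' other.
#'
#' @param n_cards Number of cards (`>= n_categories`).
#' @param n_categories Number of categories.
#' @param bank A [topic_bank()].
#' @param seed Integer seed.
#' @param topic_words,filler_words Words per description drawn from the
#'   topic and filler lists.
#' @return A catalog tibble with the planted `topic` as an extra column
#'   (dropped by [write_catalog()]).
#' @export
generate_catalog <- function(n_cards, n_categories,
                             bank = default_topic_bank(), seed,
                             topic_words = 6, filler_words = 2) {
  if (n_cards < n_categories || n_categories < 1) {
    abort("need n_cards >= n_categories >= 1")
  }
  seed <- check_seed(seed)
  topic_names <- names(bank$topics)
  idx <- seq_len(n_cards)
  topics <- topic_names[(idx - 1) %% length(topic_names) + 1]
  categories <- sprintf("category_%02d", (idx - 1) %% n_categories + 1)
  descriptions <- withr::with_seed(seed, {
    vapply(idx, function(i) {
      words <- c(
        sample(bank$topics[[topics[i]]],
               min(topic_words, length(bank$topics[[topics[i]]]))),
        sample(bank$filler, min(filler_words, length(bank$filler)))
      )
      paste(sample(words), collapse = " ")
    }, character(1))
  })
  tibble(
    card_id = sprintf("card_%03d", idx),
    title = sprintf("%s activity %d", topics, idx),
    description = descriptions,
    category = categories,
    topic = topics
  )
}

#' Default topic-to-onboarding-label map
#'
#' Maps each default topic to the informative onboarding labels a card on
#' that topic would plausibly address.
#'
#' @return A named list, topic to character vector of labels.
#' @export
default_topic_labels <- function() {
  list(
    anxiety = c("Anxious", "Overwhelmed"),
    sleep = c("Physical health"),
    depression = c("Depressed"),
    work = c("Stressed", "Career"),
    relationships = c("Dating", "Social life"),
    grief = c("Grieving", "Family"),
    mindfulness = c("Personal growth"),
    finance = c("Personal finance"),
    health = c("Physical health", "Hobbies"),
    motivation = c("Not motivated")
  )
}

#' Generate synthetic expert annotations for a catalog
#'
#' Emulates a panel of annotators labeling each card with the onboarding
#' answers it addresses. Each annotator starts from the card's true labels
#' (via the planted topic) and flips every informative label independently
#' with probability `flip_prob`, so `flip_prob = 0` reproduces the truth
#' exactly and [aggregate_annotations()] recovers indicator weights.
#'
#' @param catalog A catalog with a planted `topic` column (from
#'   [generate_catalog()]).
#' @param topic_labels Named list mapping topics to true labels.
#' @param n_annotators Panel size.
#' @param flip_prob Per-label symmetric flip probability, in \[0, 0.5).
#' @param space A [label_space()].
#' @param seed Integer seed.
#' @return An annotation tibble `annotator_id`, `card_id`, `label`.
#' @export
generate_onboarding_annotations <- function(catalog,
                                            topic_labels = default_topic_labels(),
                                            n_annotators = 6, flip_prob = 0,
                                            space = default_label_space(),
                                            seed) {
  assert_columns(catalog, c("card_id", "topic"), "catalog")
  if (flip_prob < 0 || flip_prob >= 0.5) abort("`flip_prob` must be in [0, 0.5)")
  seed <- check_seed(seed)
  informative <- space$label[space$informative]
  grid <- tidyr::expand_grid(
    annotator_id = sprintf("annotator_%d", seq_len(n_annotators)),
    catalog[, c("card_id", "topic")],
    label = informative
  )
  truth <- purrr::map2_lgl(grid$topic, grid$label,
                           function(tp, lb) lb %in% (topic_labels[[tp]] %||% character(0)))
  flips <- withr::with_seed(seed, stats::runif(nrow(grid)) < flip_prob)
  grid$selected <- xor(truth, flips)
  grid |>
    filter(.data$selected) |>
    select("annotator_id", "card_id", "label")
}

#' Generate a synthetic coaching session
#'
#' Mixes substantive messages (words from the session's planted topics plus
#' filler) with short greeting/scheduling messages at rate `filler_ratio`.
#' Substantive messages cycle through `topics`; timestamps are strictly
#' increasing; senders alternate user/coach.
#'
#' @param session_id Session identifier.
#' @param topics Character vector of topic names the session is about.
#' @param n_messages Number of messages.
#' @param filler_ratio Probability that a message is small talk rather than
#'   substance.
#' @param bank A [topic_bank()].
#' @param seed Integer seed.
#' @param start Timestamp of the first message.
#' @param topic_words,filler_words Words per substantive message.
#' @return A [conversation_session()].
#' @export
generate_session <- function(session_id = "session_1", topics, n_messages,
                             filler_ratio = 0.3, bank = default_topic_bank(),
                             seed, start = as.POSIXct("2021-06-01 10:00:00",
                                                      tz = "UTC"),
                             topic_words = 6, filler_words = 2) {
  if (n_messages < 0) abort("`n_messages` must be non-negative")
  unknown <- setdiff(topics, names(bank$topics))
  if (length(unknown) > 0) {
    abort(sprintf("unknown topic(s): %s", paste(unknown, collapse = ", ")))
  }
  seed <- check_seed(seed)
  if (n_messages == 0) {
    return(conversation_session(session_id, tibble(
      sender = character(0), timestamp = as.POSIXct(character(0), tz = "UTC"),
      text = character(0)
    ), ended_at = start))
  }
  texts <- withr::with_seed(seed, {
    smalltalk <- stats::runif(n_messages) < filler_ratio
    vapply(seq_len(n_messages), function(i) {
      if (smalltalk[i]) {
        sample(greeting_pool(), 1)
      } else {
        tp <- topics[(i - 1) %% length(topics) + 1]
        words <- c(sample(bank$topics[[tp]],
                          min(topic_words, length(bank$topics[[tp]]))),
                   sample(bank$filler, min(filler_words, length(bank$filler))))
        paste(sample(words), collapse = " ")
      }
    }, character(1))
  })
  conversation_session(session_id, tibble(
    sender = rep_len(c("user", "coach"), n_messages),
    timestamp = start + 60 * seq_len(n_messages),
    text = texts
  ))
}

#' Default demographic mix for synthetic event streams
#'
#' Age-bin and gender proportions (including an explicit unreported share)
#' shaped like a large consumer mental-health user base.
#'
#' @return A list with named probability vectors `age_bins` and `genders`.
#' @export
default_demographics <- function() {
  list(
    age_bins = c("18-24" = 0.054, "25-34" = 0.340, "35-44" = 0.196,
                 "45-64" = 0.152, "65+" = 0.010, "unreported" = 0.248),
    genders = c("male" = 0.184, "female" = 0.404, "nonbinary" = 0.067,
                "unreported" = 0.345)
  )
}

#' Generate a synthetic engagement event stream
#'
#' Each user carries sampled demographics; clicks are assigned round-robin
#' across the named groups in `completion_probs` (so group click counts are
#' fixed, not multinomial), and each click independently converts to a
#' completion with its group's probability. Group names matching an
#' algorithm (`conversation`, `onboarding`, `random`) land in the
#' `recommendations` source; any other name is treated as an app section.
#'
#' @param n_users Number of users.
#' @param clicks_per_user Clicks per user.
#' @param completion_probs Named vector of per-group completion
#'   probabilities.
#' @param demographics A list like [default_demographics()].
#' @param cards Card ids clicked cards are drawn from.
#' @param seed Integer seed.
#' @return A validated events tibble.
#' @export
#' @examples
#' ev <- generate_engagement_events(30, 10,
#'   completion_probs = c(conversation = 0.9, random = 0.1), seed = 2)
#' completion_rates(ev, algorithm)
generate_engagement_events <- function(n_users, clicks_per_user,
                                       completion_probs = c(
                                         conversation = 0.469,
                                         onboarding = 0.421,
                                         random = 0.371
                                       ),
                                       demographics = default_demographics(),
                                       cards = sprintf("card_%03d", 1:50),
                                       seed) {
  if (any(completion_probs < 0 | completion_probs > 1)) {
    abort("completion probabilities must be in [0, 1]")
  }
  if (is.null(names(completion_probs))) {
    abort("`completion_probs` must be named by group")
  }
  seed <- check_seed(seed)
  algorithms <- c("conversation", "onboarding", "random")
  n_clicks <- n_users * clicks_per_user
  groups <- rep_len(names(completion_probs), n_clicks)

  withr::with_seed(seed, {
    users <- tibble(
      user_id = sprintf("user_%05d", seq_len(n_users)),
      age_bin = sample(names(demographics$age_bins), n_users, replace = TRUE,
                       prob = demographics$age_bins),
      gender = sample(names(demographics$genders), n_users, replace = TRUE,
                      prob = demographics$genders)
    )
    clicks <- tibble(
      user_id = rep(users$user_id, each = clicks_per_user),
      group = groups,
      card_id = sample(cards, n_clicks, replace = TRUE),
      timestamp = as.POSIXct("2021-06-01 00:00:00", tz = "UTC") +
        60 * seq_len(n_clicks)
    )
    completed <- stats::runif(n_clicks) < completion_probs[clicks$group]
  })

  clicks <- clicks |>
    mutate(
      source = ifelse(.data$group %in% algorithms, "recommendations",
                      .data$group),
      algorithm = ifelse(.data$group %in% algorithms, .data$group,
                         NA_character_)
    ) |>
    left_join(users, by = "user_id")

  events <- bind_rows(
    mutate(clicks, event = "click"),
    mutate(clicks[completed, , drop = FALSE], event = "completion",
           timestamp = .data$timestamp + 30)
  ) |>
    arrange(.data$timestamp, .data$user_id) |>
    select("user_id", "source", "algorithm", "card_id", "event", "timestamp",
           "age_bin", "gender")
  validate_events(events)
  events
}

#' Planted relevant cards for sessions
#'
#' The ground-truth relevance relation of the synthetic world: a card is
#' relevant to a session exactly when its planted topic is among the
#' session's topics.
#'
#' @param catalog A catalog with a `topic` column.
#' @param session_topics Named list, session id to character vector of
#'   topics.
#' @return A named list, session id to character vector of relevant card
#'   ids.
#' @export
planted_relevant_sets <- function(catalog, session_topics) {
  assert_columns(catalog, c("card_id", "topic"), "catalog")
  purrr::map(session_topics, function(tps) {
    sort(catalog$card_id[catalog$topic %in% tps])
  })
}

#' Generate synthetic relevance annotations
#'
#' Emulates a panel of coaches grading recommended cards. Each
#' (session, card) has a planted binary truth (membership in the session's
#' relevant set); every annotator flips it independently with probability
#' `flip_prob`, and relevant verdicts split at random between "somewhat"
#' and "very" relevant.
#'
#' @param recommendations A data frame with columns `session_id`, `card_id`
#'   (one row per recommended card to be graded).
#' @param relevant_sets Named list, session id to relevant card ids (e.g.
#'   from [planted_relevant_sets()]).
#' @param n_annotators Panel size (odd for downstream majority votes).
#' @param flip_prob Per-annotator flip probability, in \[0, 0.5).
#' @param seed Integer seed.
#' @return A tibble `annotator_id`, `session_id`, `card_id`, `label` with
#'   3-level labels.
#' @export
generate_relevance_annotations <- function(recommendations, relevant_sets,
                                           n_annotators = 3, flip_prob = 0,
                                           seed) {
  assert_columns(recommendations, c("session_id", "card_id"),
                 "recommendations")
  if (flip_prob < 0 || flip_prob >= 0.5) abort("`flip_prob` must be in [0, 0.5)")
  seed <- check_seed(seed)
  items <- distinct(as_tibble(recommendations)[, c("session_id", "card_id")])
  missing_sets <- setdiff(items$session_id, names(relevant_sets))
  if (length(missing_sets) > 0) {
    abort(sprintf("no relevant set for session(s): %s",
                  paste(missing_sets, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(
    annotator_id = sprintf("annotator_%d", seq_len(n_annotators)),
    items
  )
  truth <- purrr::map2_lgl(grid$session_id, grid$card_id,
                           function(s, cd) cd %in% relevant_sets[[s]])
  withr::with_seed(seed, {
    flips <- stats::runif(nrow(grid)) < flip_prob
    observed <- xor(truth, flips)
    grid$label <- ifelse(
      observed,
      sample(c("somewhat_relevant", "very_relevant"), nrow(grid),
             replace = TRUE),
      "not_relevant"
    )
  })
  grid[, c("annotator_id", "session_id", "card_id", "label")]
}
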