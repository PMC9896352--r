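#' Conversation sessions
#'
#' A session is an ordered, timestamped exchange of text messages between a
#' mental-health coach and a user. Timestamps must be non-decreasing and the
#' session end time cannot precede its last message.
#'
#' @param session_id Session identifier.
#' @param messages A tibble with columns `sender` (`"coach"` or `"user"`),
#'   `timestamp` (`POSIXct`), `text` (non-empty after whitespace strip).
#' @param ended_at When the session ended; defaults to the last message
#'   timestamp.
#' @return An object of class `conversation_session`.
#' @export
conversation_session <- function(session_id, messages,
                                 ended_at = NULL) {
  assert_columns(messages, c("sender", "timestamp", "text"), "messages")
  messages <- as_tibble(messages)
  if (nrow(messages) > 0) {
    bad_sender <- !(messages$sender %in% c("coach", "user"))
    if (any(bad_sender)) {
      abort(sprintf("unknown sender(s): %s",
                    paste(unique(messages$sender[bad_sender]), collapse = ", ")))
    }
    if (any(!nzchar(trimws(messages$text)))) {
      abort("messages must have non-empty text")
    }
    if (is.unsorted(messages$timestamp)) {
      abort("message timestamps must be non-decreasing within a session")
    }
  }
  if (is.null(ended_at)) {
    ended_at <- if (nrow(messages) > 0) max(messages$timestamp) else NA
  }
  if (nrow(messages) > 0 && !is.na(ended_at) &&
      ended_at < max(messages$timestamp)) {
    abort("`ended_at` cannot precede the last message timestamp")
  }
  structure(
    list(session_id = as.character(session_id), messages = messages,
         ended_at = ended_at),
    class = "conversation_session"
  )
}

#' @export
print.conversation_session <- function(x, ...) {
  cat(sprintf("<conversation_session '%s': %d message(s), ended %s>\n",
              x$session_id, nrow(x$messages), format(x$ended_at)))
  invisible(x)
}

#' Read conversation transcripts from JSONL
#'
#' One JSON object per line with keys `session_id`, `sender`, `timestamp`
#' (ISO-8601), `text`.
#'
#' @param path Path to a JSONL transcript file.
#' @return A named list of [conversation_session()] objects, one per
#'   session id, messages in timestamp order.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) abort(sprintf("transcript file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::map(lines, jsonlite::fromJSON)
  df <- purrr::map_dfr(rows, function(r) {
    assert_columns(as.data.frame(r), c("session_id", "sender", "timestamp",
                                       "text"), "transcript record")
    tibble(session_id = r$session_id, sender = r$sender,
           timestamp = as.POSIXct(r$timestamp, tz = "UTC",
                                  format = "%Y-%m-%dT%H:%M:%S"),
           text = r$text)
  })
  split(df, df$session_id) |>
    purrr::imap(function(msgs, sid) {
      msgs <- arrange(msgs, .data$timestamp)
      conversation_session(sid, msgs[, c("sender", "timestamp", "text")])
    })
}

#' Importance-filter configuration
#'
#' The conversation recommender only embeds the messages that carry
#' substance; greetings, sign-offs and scheduling chatter would otherwise
#' produce spurious card matches. The default scorer is rule-based: it strips
#' a configurable phrase list from each message, tokenizes what remains, and
#' keeps messages with at least `min_tokens` content tokens. A custom
#' `scorer` (a function mapping a message tibble to a logical keep-vector)
#' can replace the rule entirely, which is the plug-in point for a learned
#' importance model.
#'
#' @param min_tokens Minimum content tokens for a message to be kept.
#' @param blacklist Phrases removed before counting tokens (case-insensitive).
#' @param scorer Optional replacement scorer.
#' @return A list of class `importance_config`.
#' @export
importance_config <- function(min_tokens = 5,
                              blacklist = default_phrase_blacklist(),
                              scorer = NULL) {
  structure(list(min_tokens = min_tokens, blacklist = blacklist,
                 scorer = scorer),
            class = "importance_config")
}

#' @rdname importance_config
#' @export
default_phrase_blacklist <- function() {
  c(
    "good morning", "good afternoon", "good evening", "good night",
    "hi there", "hello", "hi", "hey", "thank you", "thanks",
    "you're welcome", "no problem", "see you", "talk to you", "talk soon",
    "have a great day", "have a good one", "take care", "goodbye", "bye",
    "sounds good", "ok great", "okay great",
    "same time", "next week", "next session", "reschedule", "schedule",
    "monday", "tuesday", "wednesday", "thursday", "friday", "saturday",
    "sunday", "tomorrow", "at [0-9]{1,2}(:[0-9]{2})?\\s*(am|pm)?"
  )
}

#' Read importance configuration from YAML
#'
#' Expects top-level keys `min_tokens` and `blacklist`.
#'
#' @param path Path to a YAML file.
#' @return An [importance_config()].
#' @export
read_importance_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the 'yaml' package is required to read YAML configs")
  }
  cfg <- yaml::read_yaml(path)
  importance_config(
    min_tokens = cfg$min_tokens %||% 5,
    blacklist = cfg$blacklist %||% default_phrase_blacklist()
  )
}

content_token_count <- function(texts, config) {
  cleaned <- tolower(texts)
  for (phrase in config$blacklist) {
    # word-boundary anchors so "hi" never eats the middle of "this"
    cleaned <- gsub(paste0("\\b", phrase, "\\b"), " ", cleaned,
                    ignore.case = TRUE)
  }
  vapply(cleaned, function(t) length(tokenize(t)), integer(1),
         USE.NAMES = FALSE)
}

#' Filter a session down to its important messages
#'
#' Applies the importance scorer from `config` and returns the kept
#' subsequence of messages in their original order. If nothing survives the
#' filter, all messages are returned instead: the shelf must still be
#' producible from a session of pure small talk.
#'
#' @param session A [conversation_session()].
#' @param config An [importance_config()].
#' @return A tibble of messages (possibly empty only when the session itself
#'   is empty).
#' @export
filter_important_messages <- function(session, config = importance_config()) {
  stopifnot(inherits(session, "conversation_session"))
  msgs <- session$messages
  if (nrow(msgs) == 0) return(msgs)
  keep <- if (!is.null(config$scorer)) {
    config$scorer(msgs)
  } else {
    content_token_count(msgs$text, config) >= config$min_tokens
  }
  if (!any(keep)) return(msgs)
  msgs[keep, , drop = FALSE]
}

#' Message-by-card cosine similarity matrix
#'
#' @param message_vecs Numeric matrix of message embeddings (rows =
#'   messages).
#' @param card_vecs Numeric matrix of card-description embeddings (rows =
#'   cards).
#' @return A `|messages| x |cards|` matrix of cosine similarities, row and
#'   column names carried over from the inputs.
#' @export
similarity_matrix <- function(message_vecs, card_vecs) {
  if (ncol(message_vecs) != ncol(card_vecs)) {
    abort(sprintf("embedding dimension mismatch: %d vs %d",
                  ncol(message_vecs), ncol(card_vecs)))
  }
  normalize_rows <- function(m) {
    norms <- sqrt(rowSums(m^2))
    norms[norms == 0] <- 1 # zero vectors get similarity 0, not NaN
    m / norms
  }
  out <- tcrossprod(normalize_rows(message_vecs), normalize_rows(card_vecs))
  # clamp floating-point spill just outside the cosine bound
  out[out > 1] <- 1
  out[out < -1] <- -1
  out
}

#' Max-pool per-card scores from a similarity matrix
#'
#' Each card's relevance to the session is the similarity of the single most
#' similar message (columnwise maximum), emphasizing individual messages
#' over the session average.
#'
#' @param matrix A message-by-card similarity matrix with card ids as column
#'   names.
#' @return A tibble `card_id`, `score`.
#' @export
max_pool_scores <- function(matrix) {
  if (nrow(matrix) == 0) abort("no messages to pool over")
  tibble(
    card_id = colnames(matrix) %||% as.character(seq_len(ncol(matrix))),
    score = unname(apply(matrix, 2, max))
  )
}

#' Conversation-based recommendations
#'
#' Three stages: (1) filter the session to important messages; (2) embed the
#' kept messages and all card descriptions with the backend; (3) max-pool
#' the message-by-card cosine matrix per card and sort descending (ties by
#' ascending `card_id`), keeping the top `k`.
#'
#' @param session A [conversation_session()].
#' @param catalog The card catalog; descriptions are what gets embedded.
#' @param backend An [embedding_backend()].
#' @param config An [importance_config()].
#' @param k Shelf size.
#' @return A [recommendation_list] with `algorithm = "conversation"` and
#'   non-increasing scores.
#' @export
#' @examples
#' cat <- generate_catalog(8, 2, seed = 3)
#' ses <- generate_session("s1", topics = "sleep", n_messages = 6, seed = 3)
#' recommend_conversation(ses, cat, fixture_backend(seed = 3), k = 3)
recommend_conversation <- function(session, catalog, backend,
                                   config = importance_config(), k = 5) {
  if (k < 1) abort("`k` must be at least 1")
  catalog <- validate_catalog(catalog)
  if (nrow(catalog) == 0) abort("catalog is empty")
  msgs <- filter_important_messages(session, config)
  if (nrow(msgs) == 0) {
    abort("session has no messages; fall back to another recommender",
          class = "contentrec_empty_session")
  }
  message_vecs <- embed_texts(backend, msgs$text)
  card_vecs <- embed_texts(backend, catalog$description)
  rownames(card_vecs) <- catalog$card_id
  sims <- similarity_matrix(message_vecs, card_vecs)
  colnames(sims) <- catalog$card_id
  scores <- max_pool_scores(sims) |>
    arrange(desc(.data$score), .data$card_id) |>
    utils::head(k)
  new_recommendation_list(scores, "conversation")
}
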