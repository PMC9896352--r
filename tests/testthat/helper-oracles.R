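# Independent brute-force re-implementations used as oracles. These stay
# deliberately naive (explicit loops, no shared code with the package) so
# they check the pipeline rather than mirror it.

oracle_cosine <- function(u, v) {
  nu <- sqrt(sum(u * u))
  nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

# Onboarding ranking oracle: score every card with a loop, then sort by
# descending score with ascending card_id as tie-break.
oracle_rank_onboarding <- function(weight_matrix, u) {
  scores <- numeric(nrow(weight_matrix))
  for (i in seq_len(nrow(weight_matrix))) {
    scores[i] <- oracle_cosine(u, weight_matrix[i, ])
  }
  ord <- order(-scores, rownames(weight_matrix))
  data.frame(card_id = rownames(weight_matrix)[ord], score = scores[ord],
             stringsAsFactors = FALSE)
}

# Monolithic conversation pipeline oracle: embed, double-loop cosines,
# per-card max, sort, truncate.
oracle_conversation <- function(texts, catalog, backend, k) {
  mv <- backend$embed(texts)
  cv <- backend$embed(catalog$description)
  scores <- numeric(nrow(catalog))
  for (j in seq_len(nrow(catalog))) {
    best <- -Inf
    for (i in seq_len(nrow(mv))) {
      s <- oracle_cosine(mv[i, ], cv[j, ])
      if (s > best) best <- s
    }
    scores[j] <- best
  }
  ord <- order(-scores, catalog$card_id)
  head(data.frame(card_id = catalog$card_id[ord], score = scores[ord],
                  stringsAsFactors = FALSE), k)
}

# Majority-vote oracle: per item, tabulate and demand a strict majority.
oracle_majority <- function(labels) {
  tab <- table(labels)
  winner <- names(tab)[tab > length(labels) / 2]
  stopifnot(length(winner) == 1)
  winner
}

# Tiny catalog used across unit tests.
toy_catalog <- function() {
  tibble::tibble(
    card_id = c("c1", "c2", "c3", "c4", "c5", "c6"),
    title = paste("card", 1:6),
    description = c("panic worry racing", "insomnia bedtime rest",
                    "sadness hopeless numb", "deadlines workload boss",
                    "partner trust conflict", "loss mourning sorrow"),
    category = c("calm", "calm", "mood", "mood", "social", "social")
  )
}

random_label_matrix <- function(n_cards, n_labels) {
  m <- matrix(round(runif(n_cards * n_labels), 2), nrow = n_cards)
  rownames(m) <- sprintf("c%02d", sample(n_cards)) # unsorted ids on purpose
  m
}

matrix_to_long <- function(m, space) {
  df <- tidyr::expand_grid(card_id = rownames(m), label_id = space$label_id)
  df$weight <- as.vector(t(m))
  df
}
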