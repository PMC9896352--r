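space4 <- label_space(feelings = c("Anxious", "Depressed", "Grieving"),
                      impacts = c("Social life"))

test_that("annotation aggregation is the annotator-selection fraction", {
  ann <- tibble::tibble(
    annotator_id = rep(sprintf("a%d", 1:6), times = c(2, 2, 2, 1, 1, 1)),
    card_id = "c1",
    label = c("Anxious", "Social life", "Anxious", "Social life",
              "Anxious", "Social life", "Anxious", "Anxious", "Anxious")
  )
  w <- aggregate_annotations(ann, space4)
  get <- function(lbl) w$weight[w$label_id == lbl]
  expect_equal(get("Anxious"), 1)       # unanimous
  expect_equal(get("Grieving"), 0)      # never selected
  expect_equal(get("Social life"), 0.5) # 3 of 6
})

test_that("aggregation ignores record order and duplicate selections", {
  ann <- tibble::tibble(
    annotator_id = c("a1", "a2", "a3", "a1"),
    card_id = "c1",
    label = c("Anxious", "Depressed", "Anxious", "Anxious") # a1 repeated
  )
  w1 <- aggregate_annotations(ann, space4)
  w2 <- aggregate_annotations(ann[sample(nrow(ann)), ], space4)
  expect_equal(w1, w2)
  expect_equal(w1$weight[w1$label_id == "Anxious"], 2 / 3)
})

test_that("unknown labels and unannotated catalog cards are surfaced", {
  ann <- tibble::tibble(annotator_id = "a1", card_id = "c1", label = "Bogus")
  expect_error(aggregate_annotations(ann, space4), "Bogus")
  ok <- tibble::tibble(annotator_id = "a1", card_id = "c1", label = "Anxious")
  expect_warning(
    aggregate_annotations(ok, space4, catalog = toy_catalog()[1:2, ]),
    "c2"
  )
})

test_that("response vectors are binary with catch-all answers zeroed", {
  space <- default_label_space()
  u <- response_to_vector(onboarding_response(c("Anxious", "Depressed"),
                                              "Something else"), space)
  expect_equal(sum(u), 2)
  expect_equal(unname(u[space$label_id %in% c("Anxious", "Depressed")]),
               c(1, 1))

  both_se <- response_to_vector(
    onboarding_response("Something else", "Something else"), space)
  expect_true(all(both_se == 0))

  all_inf <- onboarding_response(
    space$label[space$question == "feeling" & space$informative],
    space$label[space$question == "impact" & space$informative], space)
  expect_equal(sum(response_to_vector(all_inf, space)),
               sum(space$informative))
})

test_that("cosine similarity matches hand arithmetic and its edge rules", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 0), c(2, 1, 1)), 4 / sqrt(30))
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)
  expect_error(cosine_similarity(1:3, 1:2), "mismatch")
})

test_that("ranking reproduces the worked answer-vector example", {
  # u = [1,1,0,0] against card weights [0.72, 0.11, 0.02, 0.2]
  vecs <- tibble::tibble(card_id = "c1", label_id = space4$label_id,
                         weight = c(0.72, 0.11, 0.02, 0.2))
  u <- c(1, 1, 0, 0)
  names(u) <- space4$label_id
  r <- rank_cards_by_onboarding(vecs, u, space4)
  expect_equal(r$score, 0.83 / (sqrt(2) * sqrt(0.5709)), tolerance = 1e-12)
  expect_equal(round(r$score, 3), 0.777)
})

test_that("a card parallel to the user vector ranks first with score 1", {
  space <- space4
  u <- c(1, 1, 0, 0)
  names(u) <- space$label_id
  vecs <- matrix_to_long(
    rbind(c1 = c(0.5, 0.5, 0, 0), c2 = c(1, 0, 0, 0)), space)
  r <- rank_cards_by_onboarding(vecs, u, space)
  expect_equal(r$card_id[1], "c1")
  expect_equal(r$score[1], 1)
})

test_that("an all-zero response vector signals the random route", {
  vecs <- matrix_to_long(rbind(c1 = c(1, 0, 0, 0)), space4)
  expect_error(
    rank_cards_by_onboarding(vecs, rep(0, 4), space4),
    class = "contentrec_zero_response"
  )
})

test_that("ranking agrees with the brute-force oracle on random catalogs", {
  space <- space4
  withr::with_seed(404, {
    for (trial in 1:50) {
      n <- sample(2:20, 1)
      m <- random_label_matrix(n, 4)
      u <- as.numeric(runif(4) < 0.5)
      if (all(u == 0)) u[1] <- 1
      ours <- rank_cards_by_onboarding(matrix_to_long(m, space), u, space)
      oracle <- oracle_rank_onboarding(m, u)
      expect_equal(ours$card_id, oracle$card_id)
      expect_equal(ours$score, oracle$score, tolerance = 1e-12)
    }
  })
})

test_that("diversity sampling replaces floor(n/3) positions within category", {
  cat <- generate_catalog(30, 5, seed = 21)
  ranked <- cat$card_id[1:9]
  out <- category_diversify(ranked, cat, seed = 99)
  expect_equal(nrow(out), 9)
  expect_equal(sum(out$replaced), 3)
  expect_false(anyDuplicated(out$card_id) > 0)
  # unreplaced positions untouched, replacements share the original category
  cat_of <- setNames(cat$category, cat$card_id)
  for (i in seq_len(9)) {
    if (out$replaced[i]) {
      expect_equal(unname(cat_of[out$card_id[i]]), unname(cat_of[ranked[i]]))
      expect_false(out$card_id[i] %in% ranked)
    } else {
      expect_equal(out$card_id[i], ranked[i])
    }
  }
  # bit-identical on reruns with the same seed
  expect_equal(category_diversify(ranked, cat, seed = 99), out)
})

test_that("diversity sampling degenerates correctly", {
  cat <- toy_catalog()
  ranked <- cat$card_id
  expect_equal(category_diversify(ranked, cat, fraction = 0, seed = 1)$card_id,
               ranked)
  # whole catalog already on the shelf: nothing eligible to swap in
  out <- category_diversify(ranked, cat, seed = 1)
  expect_equal(out$card_id, ranked)
  expect_false(any(out$replaced))
})

test_that("diversity sampling preserves length and uniqueness across seeds", {
  cat <- generate_catalog(24, 4, seed = 7)
  ranked <- cat$card_id[seq(1, 24, by = 2)]
  for (seed in 1:1000) {
    out <- category_diversify(ranked, cat, seed = seed)
    expect_equal(nrow(out), length(ranked))
    expect_false(anyDuplicated(out$card_id) > 0)
  }
})

test_that("the onboarding recommender composes and truncates", {
  cat <- generate_catalog(12, 3, seed = 31)
  ann <- generate_onboarding_annotations(cat, seed = 31)
  vecs <- aggregate_annotations(ann)
  resp <- onboarding_response("Anxious", "Career")

  all_cards <- recommend_onboarding(resp, cat, vecs, k = 50, seed = 1)
  expect_equal(nrow(all_cards), 12)
  expect_equal(all_cards$algorithm[1], "onboarding")

  r1 <- recommend_onboarding(resp, cat, vecs, k = 5, seed = 8)
  r2 <- recommend_onboarding(resp, cat, vecs, k = 5, seed = 8)
  expect_equal(r1, r2)

  se <- onboarding_response("Something else", "Something else")
  expect_error(recommend_onboarding(se, cat, vecs, k = 5, seed = 1),
               class = "contentrec_zero_response")
})

test_that("a planted user matching one card ranks that card first", {
  cat <- generate_catalog(20, 4, seed = 13)
  ann <- generate_onboarding_annotations(cat, seed = 13)
  vecs <- aggregate_annotations(ann)
  # the motivation topic maps to exactly {"Not motivated"}
  resp <- onboarding_response("Not motivated", "Something else")
  r <- rank_cards_by_onboarding(vecs, resp)
  top_topic <- cat$topic[cat$card_id == r$card_id[1]]
  expect_equal(top_topic, "motivation")
  expect_equal(r$score[1], 1)
})
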