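test_that("relevance labels binarize per the combining rule", {
  expect_equal(binarize_relevance(c("somewhat_relevant", "very_relevant",
                                    "not_relevant")),
               c("relevant", "relevant", "not_relevant"))
  expect_error(binarize_relevance("kind_of_relevant"), "kind_of_relevant")
})

test_that("majority vote needs an odd panel and matches enumeration", {
  ann <- tidyr::expand_grid(annotator_id = c("a1", "a2", "a3"), item = 1:4)
  ann$label <- c("relevant", "relevant", "not_relevant", "relevant",
                 "relevant", "not_relevant", "not_relevant", "not_relevant",
                 "relevant", "not_relevant", "relevant", "not_relevant")
  got <- majority_vote(ann, item_cols = "item")
  for (it in 1:4) {
    expect_equal(got$majority[got$item == it],
                 oracle_majority(ann$label[ann$item == it]),
                 label = sprintf("item %d", it))
  }
  even <- ann[ann$annotator_id != "a3", ]
  expect_error(majority_vote(even, item_cols = "item"), "odd")
})

test_that("per-class F1 follows precision/recall arithmetic", {
  expect_equal(per_class_f1(c("r", "n"), c("r", "n"), "r"), 1)
  expect_equal(per_class_f1(c("r", "n"), c("r", "n"), "n"), 1)
  # all predicted relevant, half truly relevant (n = 4): F1 = 2/3
  expect_equal(per_class_f1(rep("r", 4), c("r", "r", "n", "n"), "r"), 2 / 3)
  # class absent from both sides: degenerate value 0
  expect_equal(per_class_f1(c("r", "r"), c("r", "r"), "n"), 0)
  expect_error(per_class_f1("r", c("r", "n"), "r"), "length mismatch")
})

test_that("MAR is 1 under perfect agreement and bounded by 1 always", {
  ann <- tidyr::expand_grid(annotator_id = c("a1", "a2", "a3"), item = 1:5)
  ann$label <- rep(c("relevant", "not_relevant"), length.out = nrow(ann))
  ann$label <- rep(c("relevant", "relevant", "not_relevant", "not_relevant",
                     "relevant"), times = 3)
  m <- mar(ann, item_cols = "item")
  expect_equal(m$overall, 1)
  expect_true(all(tidy(m)$f1 >= 0 & tidy(m)$f1 <= 1))

  # single class present degenerates gracefully
  ann$label <- "relevant"
  m1 <- mar(ann, item_cols = "item")
  expect_true(m1$overall <= 1)
  expect_equal(m1$by_class$mean_f1[m1$by_class$class == "relevant"], 1)
})

test_that("a hand-built 3x6 panel reproduces step-by-step computation", {
  items <- 1:6
  labels <- list(
    a1 = c("r", "r", "n", "n", "r", "n"),
    a2 = c("r", "n", "n", "n", "r", "r"),
    a3 = c("r", "r", "r", "n", "n", "n")
  )
  ann <- purrr::imap_dfr(labels, function(l, a) {
    tibble::tibble(annotator_id = a, item = items,
                   label = ifelse(l == "r", "relevant", "not_relevant"))
  })
  # majority by hand: items 1,2,5 relevant; 3,4,6 not
  maj <- c("relevant", "relevant", "not_relevant", "not_relevant",
           "relevant", "not_relevant")
  m <- mar(ann, item_cols = "item")
  for (a in names(labels)) {
    pred <- ifelse(labels[[a]] == "r", "relevant", "not_relevant")
    for (cl in c("relevant", "not_relevant")) {
      expect_equal(
        m$by_annotator$f1[m$by_annotator$annotator_id == a &
                            m$by_annotator$class == cl],
        per_class_f1(pred, maj, cl),
        label = sprintf("%s / %s", a, cl)
      )
    }
  }
  macro_by_hand <- sapply(names(labels), function(a) {
    pred <- ifelse(labels[[a]] == "r", "relevant", "not_relevant")
    mean(c(per_class_f1(pred, maj, "relevant"),
           per_class_f1(pred, maj, "not_relevant")))
  })
  expect_equal(m$overall, mean(macro_by_hand))
})

test_that("MAR errors name a missing (annotator, item) pair", {
  ann <- tidyr::expand_grid(annotator_id = c("a1", "a2", "a3"), item = 1:3)
  ann$label <- "relevant"
  ann <- ann[-5, ] # drop a2 on item 2
  expect_error(mar(ann, item_cols = "item"), "a2")
})

test_that("session buckets are half-open and partition the integers", {
  expect_equal(as.character(bucket_sessions(3)), "0-5")
  expect_equal(as.character(bucket_sessions(5)), "5-10")
  expect_equal(as.character(bucket_sessions(40)), "40 and above")
  expect_error(bucket_sessions(-1), "non-negative")
  # every count lands in exactly one bucket
  b <- bucket_sessions(0:100)
  expect_false(any(is.na(b)))
  expect_equal(as.vector(table(b)), c(5, 5, 10, 20, 61))
})

test_that("top-K relevance counts and bucket means follow the arithmetic", {
  recs <- tibble::tibble(
    session_id = rep(c("s1", "s2"), each = 5),
    rank = rep(1:5, 2),
    card_id = rep(sprintf("c%d", 1:5), 2)
  )
  rel <- tidyr::expand_grid(session_id = c("s1", "s2"),
                            card_id = sprintf("c%d", 1:5))
  rel$majority <- c("relevant", "relevant", rep("not_relevant", 3), # s1: 2/5
                    rep("relevant", 4), "not_relevant")             # s2: 4/5
  per_session <- relevance_rate_at_k(recs, rel, k = 5)
  expect_equal(per_session$rate[per_session$session_id == "s1"], 0.4)
  expect_equal(per_session$rate[per_session$session_id == "s2"], 0.8)

  sizes <- tibble::tibble(session_id = c("s1", "s2"), n_messages = c(7, 8))
  by_bucket <- relevance_by_bucket(per_session, sizes)
  expect_equal(by_bucket$rate[by_bucket$bucket == "5-10"], 0.6)

  rel_missing <- rel[-1, ]
  expect_error(relevance_rate_at_k(recs, rel_missing, k = 5), "c1")
})

test_that("bucket means stay within the member sessions' range", {
  withr::with_seed(9, {
    per_session <- tibble::tibble(
      session_id = sprintf("s%d", 1:40),
      n_scored = 5,
      n_relevant = sample(0:5, 40, replace = TRUE)
    )
    per_session$rate <- per_session$n_relevant / 5
    sizes <- tibble::tibble(session_id = per_session$session_id,
                            n_messages = sample(0:60, 40, replace = TRUE))
  })
  by_bucket <- relevance_by_bucket(per_session, sizes)
  joined <- dplyr::left_join(
    dplyr::mutate(dplyr::left_join(per_session, sizes, by = "session_id"),
                  bucket = bucket_sessions(n_messages)),
    by_bucket, by = "bucket"
  )
  ranges <- joined |>
    dplyr::group_by(bucket) |>
    dplyr::summarise(ok = all(rate.y >= min(rate.x) & rate.y <= max(rate.x)))
  expect_true(all(ranges$ok))
})

test_that("completion rates tally events and honor the zero-click rule", {
  ev <- generate_engagement_events(
    n_users = 20, clicks_per_user = 10,
    completion_probs = c(conversation = 1, random = 0), seed = 61
  )
  rates <- completion_rates(ev, algorithm)
  expect_equal(rates$rate[rates$algorithm == "conversation"], 1)
  expect_equal(rates$rate[rates$algorithm == "random"], 0)
  expect_equal(sum(rates$clicks), 200)

  # hand-tallied counts survive event shuffling
  shuffled <- ev[withr::with_seed(1, sample(nrow(ev))), ]
  expect_equal(completion_rates(shuffled, algorithm) |> dplyr::arrange(algorithm),
               rates |> dplyr::arrange(algorithm), ignore_attr = TRUE)

  none <- completion_rates(
    tibble::tibble(source = "library", clicks = 0, completions = 0))
  expect_true(is.na(none$rate))
})

test_that("completion events without a prior click are rejected", {
  ev <- tibble::tibble(
    user_id = "u1", source = "home", algorithm = NA_character_,
    card_id = "c1", event = "completion",
    timestamp = as.POSIXct("2021-06-01", tz = "UTC"),
    age_bin = "25-34", gender = "female"
  )
  expect_error(validate_events(ev), "completion without prior click")
})

test_that("difference tables subtract elementwise and check bucket labels", {
  alg <- tibble::tibble(bucket = c("0-5", "5-10"), rate = c(0.099, 0.433))
  ctl <- tibble::tibble(bucket = c("0-5", "5-10"), rate = c(0.028, 0.111))
  d <- difference_table(alg, ctl)
  expect_equal(d$difference, c(0.071, 0.322))
  expect_equal(difference_table(alg, alg)$difference, c(0, 0))
  withr::with_seed(3, {
    a <- tibble::tibble(bucket = letters[1:5], rate = runif(5))
    b <- tibble::tibble(bucket = letters[1:5], rate = runif(5))
  })
  expect_equal(difference_table(a, b)$difference, a$rate - b$rate)
  expect_error(difference_table(alg, ctl[1, ]), "bucket")
})
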