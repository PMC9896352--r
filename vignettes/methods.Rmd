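---
title: "Knowledge-based card recommendation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based card recommendation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contentrec)
```

`contentrec` recommends short self-care activities ("content cards") to
users of a digital mental-health app and evaluates how well those
recommendations land. This vignette is the package's own account of the
models it implements, the parameters that matter, what the synthetic data
emulates, and the choices made where the design was genuinely open.

## The onboarding recommender

New users answer two multi-select intake questions — how they are feeling
(7 answers) and which life areas it impacts (9 answers). These 16 answers
form the *label space* (`default_label_space()`); the catch-all answer
"Something else" appears under both questions and is flagged
non-informative.

A panel of expert annotators marks, for each card, every label the card
could help address. `aggregate_annotations()` pools a card's selections
into a weight per label: the fraction of that card's annotators who chose
the label. This is the simplest normalization consistent with weights in
[0, 1] — unanimity gives 1, an unselected label gives 0, and the weight is
invariant to annotator ordering. The denominator is by default the number
of distinct annotators observed for the card; when an annotation file can
omit annotators who selected nothing for a card, the panel size can be
pinned with `n_annotators`.

A user's response becomes a binary vector over the same space
(`response_to_vector()`), with catch-all answers contributing zero. Cards
are ranked by cosine similarity between the user vector and each card
vector; a zero-norm user vector (catch-all-only answers) is a signalled
error that the router turns into the random branch. Ties are broken by
ascending card id so rankings are reproducible.

### Diversity sampling

`category_diversify()` replaces ⌊n/3⌋ positions of the shelf, chosen
uniformly without replacement, each with a uniform draw from the replaced
card's category excluding cards already on the shelf; when nothing is
eligible the original card is kept. Three decisions here were open and are
ours:

* **The shelf, not the full ranking, is diversified.** Ranking scores
  every annotated card, so diversifying before truncation would leave no
  eligible replacements (every card would already be "in the list") and
  the step would be a no-op. `recommend_onboarding()` therefore ranks,
  truncates to `k`, then diversifies.
* **No duplicates.** A recommendation shelf showing the same card twice is
  a product absurdity, so replacements exclude cards already present.
* **Seeded stream.** The replacement draw is the onboarding recommender's
  only stochastic step; `seed` is a required argument and the same seed
  reproduces the shelf bit for bit.

Swapped-in cards carry an `NA` score: they were sampled, not ranked, and
pretending otherwise would misrepresent the ranking.

## The conversation recommender

After a coaching session the recommender works in three stages.

**Importance filtering.** Greetings, sign-offs and scheduling chatter
overlap heavily with card text while carrying no clinical content; left
in, they produce spurious matches. The default scorer strips a
configurable phrase blacklist (word-boundary, case-insensitive) and keeps
messages with at least `min_tokens = 5` remaining content tokens. Both
knobs live in `importance_config()`, and a custom `scorer` function
replaces the rule entirely — the plug-in point for a learned importance
model. If nothing survives, all messages are used: the app always shows a
shelf, so the filter must never leave the recommender with nothing.
Messages from both the coach and the user are kept and embedded.

**Embedding.** Texts are embedded by any `embedding_backend()`: a
declared dimension plus a deterministic batch function text → matrix. A
production deployment would plug in a multilingual paraphrase
sentence-transformer (mean-pooled final hidden layer); nothing in the
package requires one. Only the card *description* is embedded — titles are
display copy, descriptions are what states what the card does.

**Scoring.** The message-by-card cosine matrix is max-pooled per card:
score(card) = max over messages of cos(message, card). The maximum, rather
than the mean, means a single on-topic message is enough to surface a
card, which matches how one salient disclosure in a long session should
drive recommendations. Cards are sorted descending with ascending-id tie
breaks and truncated to `k`.

## Routing

`route_algorithm()` implements the serving decision: conversation-based
if the latest session ended within the past 60 days (inclusive, judged on
the session end time) and contains more than 15 messages (so 16 is the
minimal qualifying count, with both senders counted); otherwise
onboarding-based; otherwise — catch-all-only answers, or no onboarding at
all — random. Absent onboarding is not covered by the stated flow; we
route it to random, the only branch with no input requirement.
`recommend_cards()` additionally degrades gracefully at run time: a branch
that fails (empty session, missing card vectors, a broken backend) falls
through conversation → onboarding → random, so a shelf is always returned
and its `algorithm` column records the branch that actually produced it.

## Evaluation metrics

**Relevance.** Annotators grade recommended cards on a 3-level scale;
`binarize_relevance()` collapses somewhat/very to "relevant".
`majority_vote()` requires an odd panel (ties are undefined and erroring
beats inventing a tie-break). `relevance_rate_at_k()` is the fraction of a
session's top-5 cards majority-labeled relevant; `relevance_by_bucket()`
averages per-session rates within session-length buckets. Two open points
resolved here: buckets are half-open \[0,5), \[5,10), \[10,20), \[20,40),
\[40,∞) — the printed bucket labels overlap at their endpoints and a
partition is required for a decidable function — and per-bucket
aggregation is the unweighted mean of per-session rates (pooling across
sessions would weight long shelves more; neither convention is stated, so
we fix one and say so).

**Agreement.** `mar()` scores each annotator against the panel's majority
vote with per-class F1, macro-averages over the two classes per annotator,
and reports the mean of macro-averages as the overall majority agreement
rate. A class with no true positives and no support scores 0 — the
consequence is worth knowing: on an item set where every card is truly
relevant, a perfect panel scores macro-F1 0.5, not 1. Agreement studies
should grade a pool containing both classes, which is why the package's
end-to-end checks grade a random-control shelf alongside the algorithmic
one. `mar_aggregate()` exposes the aggregation half separately so a table
of per-class scores can be rolled up directly.

**Engagement.** `completion_rates()` is completions over clicks per
group, computed from a raw event log or from an already-tallied table;
zero-click groups get `NA`, never a division error. The denominator is
click events — "viewed" in the product sense of having opened the card. No
hypothesis tests are computed: observed rate differences across arms are
not causal claims (arms were not randomly assigned in the setting this
mirrors), and the package does not pretend otherwise.

## Synthetic data and the fixture backend

The generators exist so every pipeline stage is exercisable with planted,
recoverable truth:

* `generate_catalog()` assigns topics and categories round-robin and
  writes descriptions from the card's topic words plus filler. Topic word
  lists are pairwise disjoint (validated at construction), so a
  description contains words from exactly one topic.
* `generate_session()` mixes substantive messages (topic + filler words)
  with blacklisted small talk at `filler_ratio`; substantive messages have
  8 content tokens and therefore always survive the default filter.
* `generate_onboarding_annotations()` and
  `generate_relevance_annotations()` apply independent symmetric label
  flips per annotator, so `flip_prob = 0` reproduces planted truth
  exactly and agreement degrades monotonically in noise.
* `generate_engagement_events()` assigns clicks round-robin across arms
  (fixed, not multinomial, group sizes) and converts each independently
  with its arm's planted probability. The default completion
  probabilities (0.469 / 0.421 / 0.371 across the conversation,
  onboarding and random arms) and the demographic mix in
  `default_demographics()` mirror the magnitudes reported for a large
  consumer mental-health platform, so simulated streams live on a
  realistic scale.
* `fixture_backend()` embeds text as the normalized sum of per-token
  vectors drawn from a seeded hash of each lowercase token — a hashed
  bag-of-tokens model. It is deterministic, order-insensitive and
  download-free.

What the synthetic world does *not* emulate: paraphrase (the fixture
backend sees zero similarity between synonyms; a transformer backend is
precisely a paraphrase model), session topic drift, annotator bias that is
not symmetric noise, and the empirical session-length or demographic
distributions beyond configurable knobs. Passing planted-truth tests
therefore shows the pipeline's plumbing and arithmetic are right — not
that the fixture backend would rank real clinical text the way a
production embedding model does.

## Numerical and scale choices

Cosine similarity returns 0 when either vector has zero norm; similarity
matrices are clamped to [−1, 1] against floating-point spill; rates are
kept at full precision and rounded only for display. All seeds are 32-bit
integers; generators and the diversity sampler take explicit seeds, and
composite runs derive per-component seeds as small offsets from one master
seed.

Test and example problem sizes — catalogs of 8–30 cards, 50 sessions of
16–25 messages, 20,000 clicks per arm for rate recovery, 100 randomized
instances per brute-force comparison — were chosen so planted effects are
comfortably above sampling noise (binomial standard error ≈ 0.0035 at
20,000 clicks) while the full suite runs in well under a minute.

## Known limitations

The aggregation scheme for expert annotations is one defensible choice
among several; published worked examples of card vectors are not exactly
reproducible by any annotator-count fraction, so the fraction scheme is a
stated convention here, not a claim about any deployed system. The
importance filter is a rule, not a model. The router judges whichever
session is supplied as the latest one; it does not verify recency ordering
across a history. And none of the engagement comparisons support causal
inference — arm assignment in the real setting this mirrors was driven by
user state, not randomization.
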