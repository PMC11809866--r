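---
title: "Harm-aware contact recommendation: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harm-aware contact recommendation: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safefollow)
library(dplyr)
```

## The problem

Follow-graph platforms recommend new contacts from a user's extended
neighbourhood. For users vulnerable to harmful communities — the motivating
case is people at the *contemplation stage* of anorexia nervosa (AN), who
recognize a problem and are open to change but whose neighbourhood is
saturated with pro-eating-disorder content — a purely engagement-driven
recommender amplifies exposure to exactly the accounts that can hurt them.
`safefollow` implements a contact recommender that makes harmlessness a
first-class ranking signal: it filters the candidate neighbourhood with a
harmful-versus-harmless text classifier, weights every candidate's score by
its harmless-class probability, and reserves a quota of list slots for
pro-recovery accounts (recovery centres, clinicians, supporters) that would
otherwise never surface from the user's own neighbourhood.

Account types are `harmful`, `neutral` and `pro_recovery`; *harmless* is
defined as the union of neutral and pro-recovery and is always computed,
never stored.

## Candidate pools

For a target `u`, level 1 is the set of `u`'s followees that survive the
harmlessness filter (classifier probability at or above `threshold`,
default 0.5); level 2 are the followees of the retained accounts; the
candidates are the accounts reached at `depth = 3` hops. A candidate's
multiplicity is the number of level-2 accounts following it, and the pool
is a multiset: `occurrences_ratio()` is multiplicity over the pool total.
From the eligible candidates `pool_size = 100` distinct ids are sampled
uniformly under a seed, and the pre-sampling multiplicities of the sampled
ids define the pool total. We sample distinct ids but keep multiplicities
because an occurrence ratio over deduplicated counts would be the constant
`1 / |pool|` and carry no signal. The target itself and the accounts it
already follows are never eligible, the standard contact-recommendation
convention. Candidate ids are sorted before sampling so pools are
platform-independent, and the sampling uses a private seeded RNG stream
that never touches the caller's `.Random.seed`.

## Scoring

For a target `u` and candidate `c`:

* topology: the mean of the Jaccard similarity of followee sets and the
  occurrence ratio;
* content: the cosine between min–max-normalized topic-interest vectors
  (zero by convention if either vector is all zero);
* harmlessness: the harmless-class probability of the screening
  classifier;
* rank score: `harmlessness × mean(content, topology)` for general
  candidates. For pro-recovery candidates the topology term is dropped
  (`harmlessness × content`): such accounts are structurally distant from
  a harmful neighbourhood and network features would systematically
  depress them. Whether the harmlessness factor applies to the
  pro-recovery variant was genuinely open; we keep it by default (it is a
  probability near 1 for genuine pro-recovery accounts, so it mostly
  re-ranks impostors down) and expose
  `pro_recovery_uses_harmlessness = FALSE` for the bare-content variant.
* participants: survey participants have no platform network, so their
  score is `harmlessness × content` throughout.

The top-K list reserves `round(quota × K)` slots (rounded half away from
zero; `quota = 0.2` by default, so 3 of 15) for the best pro-recovery
candidates and merges both sets by descending score, ties broken by
ascending id so lists are reproducible. If fewer pro-recovery candidates
exist, the shortfall is backfilled with general candidates and a warning
is raised. With `quota = 0` and a constant scorer of 1 the system reduces
exactly to the plain content-plus-topology recommender, which is the
baseline the evaluation compares against.

## Interest vectors

Interests are estimated from three sources — an account's own posts, the
posts it liked, and the biographies of its followees — each capped at 200
items and combined with configurable weights (default equal at `(1, 1,
1)`, no published guidance to the contrary). Keyword occurrences are
mapped to topics through a deterministic `topic_vocabulary()`; the
original study used an external entity-extraction API, which we replace
with this pluggable mapping because an external API is neither
reproducible nor inspectable. Normalization is min–max: *global* (over
all entries of the cohort jointly) for platform accounts, *per-owner* for
survey participants whose 0–5 ratings are only comparable within a
respondent. Whether global normalization should be joint or per-topic was
ambiguous; we normalize jointly by default and expose `per_topic = TRUE`.
A degenerate range maps to zeros.

Survey profiles propagate each subcategory rating to the subcategory's
topics and, through a concept map, to concepts related to the
respondent's free keywords ("PlayStation" rated 4 also scores "game
console" at 4). Colliding propagations keep the maximum rather than the
sum so one enthusiastic keyword is not double-counted.

## Screening classifiers

Both screeners (contemplation-stage vs control; harmful vs harmless)
represent an account by the concatenation of its texts and are trained
with a stratified 70/30 split. Features are either a TF-IDF bag of
1–3-grams — raw term counts weighted by the smoothed inverse document
frequency `ln((1 + N)/(1 + df)) + 1` with L2-normalized rows — or 84
interpretable lexicon-ratio features in five groups (24 linguistic, 29
affective, 12 personal/biological, 10 suicide-risk, 9 eating-disorder).
The shipped lexicon file is a synthetic demonstration set with the same
group structure; the clinician-curated lists it stands in for are not
redistributable, so any serious deployment must supply its own YAML.
Class imbalance is corrected with SMOTE — synthetic minority points
interpolated uniformly on segments to one of the 5 nearest minority
neighbours — applied strictly to training data: inside each
cross-validation fold and to the full training split for the final fit,
never to the held-out test split. Classifiers are ridge logistic
regression (`glmnet`, lambda by 5-fold cross-validation), random forest
(`ranger`, 300 trees) and a linear-kernel SVM (`e1071`); all paths are
seeded and deterministic. The TF-IDF vocabulary and idf are fitted on the
training split only.

## Evaluation suite

Given an annotated list (per-candidate type label and followed flag):
precision@K, recall@K (follows in top K over all follows annotated, 0
when nothing was followed), and average precision computed as
`sum(P@i · rel(i)) / max(1, follows in top K)` — the AP denominator was
not published, so we normalize by the relevant items within the window
and isolate the convention in one function so it can be swapped. Twelve
type ratios cover suggestions (`PRSR`, `NSR`, `HSR`, `HLSR`), follows
over suggestions of the type (`*FRS`, 0 when the type was never
suggested) and follows over K (`PRFRK`, `HLFRK`, `HFRK`). The headline
measure APHR is the harmonic mean of AP and HLFRK, 0 when both are 0; at
cohort level it is applied to MAP and the mean HLFRK. All 0/0 conventions
resolve to 0, matching the zero cells of the published tables. Reported
tables round half-up to 2 decimals at the reporting layer only.

## The synthetic scenario

The study's data is access-restricted, so the package ships a seeded
generator that emulates its structure rather than its content:

* a stochastic block model over four groups (10 contemplation targets,
  60 harmful, 40 neutral, 12 pro-recovery) whose follow-probability
  matrix encodes intra-cluster homophily and the targets' documented
  attraction to harmful accounts (target→harmful 0.30 vs
  target→neutral 0.08);
* unigram text generation: each token is drawn from the account group's
  topical vocabulary with probability `delta` (topic from the group
  profile, keyword uniform within topic) and from a shared filler
  vocabulary otherwise. `delta = 0.8` by default — separable but not
  trivially disjoint; `delta = 0` is the null scenario where no
  classifier can beat chance;
* logistic follow decisions,
  `plogis(-1.2 + 2.5·content + 0.8·[harmful])`, expressing that simulated
  users follow what matches their interests and retain a residual
  affinity for harmful accounts.

The group sizes and probabilities were chosen once so that a target's
unfiltered 3-hop pool is majority-harmful while the filtered pool is
majority-harmless, the qualitative contrast the filtering step is
supposed to produce (the study reports 82% vs 30% harmful); the defaults
here give roughly 65% vs 42% under the default seed. What the generator
does *not* emulate: real language (no grammar, no code-switching, no
irony — classifier scores on synthetic text are upper bounds, not
forecasts), degree heterogeneity and reciprocity of real follow graphs,
and annotator noise in follow decisions. Passing tests therefore
demonstrate correctness of the machinery and the direction of the
filtering effect, not real-data effect sizes.

```{r pipeline, eval = FALSE}
res <- run_scenario_models(default_scenario(seed = 1))
res$reports |> select(model, K, P, MAP, HSR, HLSR, HLFRK, APHR)
autoplot(res$reports)
```

## Numerical choices and degenerate inputs

Ties everywhere break by ascending candidate id; reported rounding is
half-up (base R's `round()` is half-even, hence `round_half_up()`).
Empty documents featurize to zero rows; all-zero interest vectors have
content score 0; an empty candidate pool is a valid result for an
isolated or fully-filtered target, not an error; a singleton minority
class is rejected by SMOTE with advice to duplicate. Quota rounding is
half-up of `quota × K`. Cross-validated metrics reuse a training-split
featurization (the idf is unsupervised; only oversampling leaks labels,
and that is kept inside folds).

## Problem sizes used in the test suite

The shipped tests run the default scenario (122 accounts, about 1,800
edges, 12 texts-equivalent per account) across 10 seeds for the
planted-recovery properties, 100 random graphs of up to 30 nodes for
brute-force ranking equivalence, and 1,000 randomized annotation lists
for the metric identities — sizes chosen to make the full suite a
minutes-scale run on one core while keeping every check meaningful.

## Known limitations

The screeners are bag-of-words models over short synthetic texts; no
embedding or deep model is included by design (interpretability for
clinical review). The harmlessness filter inherits every bias of its
training labels, and a miscalibrated classifier shifts the whole ranking:
`harmlessness_score` multiplies the final score, so systematic
over-confidence on harmful accounts is the dominant failure mode to audit
before any deployment. The pro-recovery quota guarantees exposure, not
engagement. Nothing in this package is a clinical instrument.
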