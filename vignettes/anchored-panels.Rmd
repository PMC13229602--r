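---
title: "Anchored forced-choice panels: model, design decisions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored forced-choice panels: model, design decisions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorpanel)
```

## The measurement problem

A deployed black-box language model is a moving target: the vendor can
change it at any time, and the deploying organization usually has no
instrument for noticing. `anchorpanel` treats this as a psychometric
measurement problem. A fixed, versioned panel of two-alternative
forced-choice (2AFC) trials is administered to the model; the pattern of
pairwise winners, its internal consistency, and its stability across
re-administrations constitute a *behavioral signature* that can be archived
and compared over time. The item content (materials ordered by hardness,
plus abstract concepts) is deliberately low-stakes: the panel measures
whether the instrument still behaves like an instrument, not whether the
model is clinically safe.

Everything that could change the measurement — the prompt template bytes,
item labels, trial order, A/B positions, the JSON output schema, the
analysis configuration — is treated as part of the instrument. Run files and
templates are archived, hashed, and verified when baselines are reloaded.

## Scaling model

Each valid trial is a paired-comparison observation (winner, loser). Choices
are modeled with the Bradley–Terry model: with latent strengths
$\beta_i$,

$$P(i \text{ beats } j) = \frac{e^{\beta_i}}{e^{\beta_i} + e^{\beta_j}}
 = \sigma(\beta_i - \beta_j).$$

Strengths are estimated by maximizing the ridge-penalized log-likelihood

$$\ell(\beta) = \sum_{\text{obs}} \log \sigma(\beta_w - \beta_l)
 \;-\; \lambda \sum_i \beta_i^2,$$

with no intercept. For $\lambda > 0$ this objective is strictly concave, so
the maximizer is unique; the implementation uses a damped Newton iteration
(step-halving line search) and declares convergence when the gradient
max-norm falls below $10^{-8}$. Reported strengths are mean-centered — the
likelihood depends only on differences, and the anchoring step removes the
gauge anyway. The fitted scale is reported after the anchored rescaling

$$h_i = 100\,\frac{\beta_i - \beta_{\text{low}}}
 {\beta_{\text{high}} - \beta_{\text{low}}},$$

which pins the low anchor to 0 and the high anchor to 100. Scores outside
$[0,100]$ are legitimate (an item ranked beyond the anchors). If the two
anchors have (numerically) equal strengths the axis is undefined; this is
raised as an anchoring error and is itself a quality-control finding.

Uncertainty comes from a parametric bootstrap: each replicate redraws every
observation's winner Bernoulli from the fitted pair probability, refits with
the same $\lambda$, rescales, and the per-item 2.5/97.5 percentiles over
replicates form the 95% interval. The pinned anchors are exactly 0 and 100
in every replicate, so their intervals are degenerate by construction, and
interval bounds are deliberately *not* clipped to $[0,100]$. Replicates
whose refit fails are dropped and counted; more than 10% drops aborts the
interval rather than reporting a misleading one.

### Tunable parameters

* `l2_lambda` (default **0.1**, dimensionless): ridge weight. Large enough
  to keep strengths finite under perfectly separated data (a clean run *is*
  nearly separable), small enough that the anchored scores are dominated by
  the data; because anchoring is a ratio of strength differences, the
  roughly uniform multiplicative shrinkage largely cancels. The value is
  part of the instrument and is recorded in every fit and run signature.
* `bootstrap_reps` (default **1000**) with a single seeded generator;
  percentile method.
* Convergence tolerance $10^{-8}$ (gradient max-norm), Newton iteration cap
  200.
* Accuracy tie rule: an observation whose pair has exactly equal fitted
  strengths contributes 0.5 — the expected accuracy of a random prediction.

## The default panel

Ten material anchors spanning an intuitive hardness continuum (Marshmallow
… Steel, canonical ranks 1–10) and five abstract concept targets. The panel
definition inserts the axis definition text into the prompt and pins
Marshmallow = 0, Steel = 100.

The default plan has 190 trials. With 15 items there are only 105 unordered
pairs, so a 190-trial plan with exactly 64 repeated pairs *must* present
some pairs more than twice. The shipped composition — a reconstruction, not
a published design — presents every unordered pair once (50 concept–anchor,
10 concept–concept, 39 anchor–anchor, 6 catch), then re-presents a seeded
sample of 64 non-catch pairs a second time and 21 of those a third time:
$105 + 64 + 21 = 190$. The plan total is always
`sum(block_counts) + n_repeated_pairs × (reps_per_pair − 1) +
extra_presentations`, and every component is user-configurable.

Catch trials are defined as anchor pairs whose canonical rank gap is at
least 70% of the anchor span (six such pairs among ten anchors), so the
expected winner is unambiguous; passing means choosing the higher-ranked
anchor. Catch pairs are excluded from the repeat pool so that the
repeated-pair count stays exactly at the planned 64. A/B position is
randomized independently per presentation and the full plan is shuffled, all
deterministically from the spec's seed.

## Quality-control metrics

* **Repeated-pair agreement**: fraction of pairs with ≥2 presentations whose
  winner is identical across all of them. Unanimity is the default rule
  (strictest reading of "identical winners"); a majority rule is available
  for plans with >2 repetitions.
* **Confidence–distance correlation**: Pearson r between per-trial reported
  confidence and the absolute anchored-score difference of the two items,
  with a Fisher-z 95% interval (bootstrap optional). Catch trials are
  excluded by default — their extreme distances are attention checks, not
  measurements — with a switch to include them. Zero-variance inputs yield
  an explicit degenerate status.
* **Anchor-order check**: anchors sorted by canonical rank; each *adjacent*
  pair is tested for a fitted-score inversion. The denominator is the
  number of adjacent pairs (9 for 10 anchors). Other conventions exist
  (e.g. counting only non-pinned anchors gives 8); ours is fixed and
  documented so longitudinal counts are comparable.
* **Catch pass rate**, and ingestion anomalies (parse failures, orphans,
  duplicates, repairs) from the response reader.

Default flag thresholds: agreement < 0.95 → `LOW_REPEAT`; any inversion →
`ANCHOR_ORDER`; r < 0.6 → `WEAK_CONFIDENCE_CALIBRATION`; any failed catch →
`CATCH_FAIL`. The repeat and calibration cutoffs sit roughly midway between
the two regimes the simulator emulates (clean: agreement ≈ 1, r ≈ 0.8;
degraded: agreement ≈ 0.9, r ≈ 0.4), so either regime is classified
decisively; all are configurable.

Winner-reversal analysis across conditions (wrappers or prompt families)
collapses each condition to one majority winner per pair (exact ties are
indeterminate and leave the denominator), intersects determinate pairs, and
reports reversals and agreement to one decimal. Drift monitoring stores a
run signature (scale + QC + analysis config + instrument hash) and compares
a candidate signature against a baseline: review is triggered when any
item's score shift exceeds its baseline CI half-width, a new anchor-order
violation appears, or repeat agreement drops by more than 0.05.
Interval-scaled shift thresholds adapt to each item's own uncertainty;
mitigation and rebaselining are human escalations, never automatic.

## The simulated responder

`latent_profile()` equips every item with a true score $s_i$ on the latent
axis; choices follow $P(\text{choose } A) = \sigma((s_A - s_B)/\tau)$ — the
Bradley–Terry generative family itself, so pipeline runs on simulated data
are clean self-consistency tests — and confidence is
$\mathrm{round}(\mathrm{clip}(g\,|s_A - s_B| + c + \mathcal N(0,\sigma_c),
0, 100))$, generated from the *true* distance so that the calibration
metric tests recovery of a known monotone link.

`make_default_profiles()` freezes two study conditions:

* **clean** — true scores at the reference positions of the default items
  (anchors 0…100 in canonical order, concepts interleaved; minimum item
  separation 4.81 units), $\tau = 0.5$, confidence gain 0.9, offset 5,
  noise SD 14. Chosen a priori so that the worst-case single-comparison
  error rate is $\sigma(-4.81/0.5) \approx 10^{-4}$: expected repeat
  agreement ≈ 1 and fit accuracy ≈ 1 (the signature of a healthy frontier
  run), expected confidence–distance r ≈ 0.84.
* **degraded** — the same truths with the polycarbonate/steel latent scores
  swapped (guaranteeing anchor-order violations), $\tau = 6$ plus a 1.5×
  temperature boost on repeat presentations (expected repeat agreement
  ≈ 0.90), and confidence gain quartered (expected r ≈ 0.4): the signature
  of a weak on-premise run that must trip the QC flags.

These calibrations were computed analytically from the latent gaps before
any tests were written and are not tuned thereafter.

What the simulator does **not** emulate: linguistic behavior of any model
(schema violations, refusals, prompt-wording sensitivity), inter-session
drift, position bias, or content-dependent confidence quirks. Passing tests
on simulated data therefore demonstrate that the *analysis* is correct and
self-consistent under its own assumptions — not that any particular model
behaves this way. Real runs can and do violate the one-dimensional
Bradley–Terry assumption; the QC metrics exist precisely to notice that.

## Numerical and design choices

* Pair keys are the two item ids sorted lexicographically and joined with
  `"|"` — canonical and order-free.
* Trial ids are prefixed with an md5 fragment of the panel version, so two
  panel versions can never collide.
* Duplicate responses for a trial keep the first and count the rest;
  confidence 0 is a valid value, not an abstention; lenient parsing
  (stripping prose/code fences) is opt-in and always flagged, because parse
  robustness is part of the signature.
* Strict response parsing accepts exactly one JSON object per line with
  exactly the three schema keys; every rejection reason has its own error
  class so parse-failure modes can be tallied.
* The instrument hash is md5 over the template bytes concatenated with the
  run-file bytes, recomputed and verified whenever a signature is loaded.

## Test problem sizes

The shipped test suite runs entirely on simulated data: toy fits are checked
against an independent refining dense grid search of the same penalized
objective (≤4 items, tolerance $10^{-3}$); parameter recovery uses 20
clean-profile runs of the 190-trial default plan; interval calibration uses
200 simulated runs × 250 bootstrap replicates. The coverage study
deliberately uses a moderate choice temperature ($\tau = 15$) rather than
the clean profile: coverage is a property of the estimator's sampling
distribution, and a near-deterministic responder has almost no sampling
variability, which makes parametric-bootstrap intervals conservative by
construction (their measured coverage approaches 1). At $\tau = 15$ the
measured coverage of the 95% intervals is ≈ 0.95.

## Limitations

* One axis per panel; multi-axis studies are separate runs with
  independently anchored scales.
* No alternative paired-comparison families (Thurstone, Plackett–Luce),
  covariates, or order-effect terms.
* The reversal analysis is descriptive; no statistical test is attached to
  reversal counts.
* Flags are review triggers. Nothing in this package measures clinical
  safety, and a flag-free run is evidence of instrument stability, not of
  model quality.
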