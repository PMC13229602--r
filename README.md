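# anchorpanel

Anchored forced-choice quality-control panels for black-box language models.

Health systems increasingly deploy large language models they cannot inspect:
vendor updates silently change behavior, and there is no routine instrument
for noticing. `anchorpanel` implements a psychometric answer to that
operational problem — a versioned two-alternative forced-choice (2AFC) panel
that is re-administered to the model like a quality-assurance assay. Each
trial asks the model to compare two labeled items on a fixed axis (the
default panel: *hardness*, with ten reference materials and five abstract
concepts) and to return one line of JSON with its choice and a 0–100
confidence. The pairwise choices yield an anchored behavioral signature that
can be stored, versioned, and compared across reruns; the intended users are
quality/safety leads and ML engineers who need a cheap, repeatable sentinel
for behavioral drift, not a clinical benchmark.

## The model

Choices are scaled with the Bradley–Terry model,

> P(i beats j) = exp(βᵢ) / (exp(βᵢ) + exp(βⱼ)),

with latent strengths β estimated by maximizing the L2-penalized
log-likelihood Σ log σ(β_w − β_l) − λ Σ βᵢ² (damped Newton on the strictly
concave objective; λ = 0.1 by default and recorded in every run signature).
Fitted strengths are linearly rescaled so the two pinned anchors land at 0
and 100 (Marshmallow = 0, Steel = 100 in the default panel); other items may
legitimately fall outside [0, 100]. 95% intervals come from a parametric
bootstrap: winners are resimulated from the fitted probabilities, the model
is refit per replicate, and percentile bounds are taken on the anchored
scale. Around the scale sit the panel's QC metrics: repeated-pair agreement,
the confidence–distance correlation (Pearson r with a Fisher-z interval),
catch-trial pass rate, anchor-order violations, winner-reversal analysis
across wrapper/prompt-family conditions, and drift comparison against a
stored baseline signature.

A built-in simulated responder (logistic choice noise on latent item scores,
distance-linked confidence, configurable degradation modes) generates
response files with the exact statistical structure the analysis assumes, so
the whole pipeline is testable without querying any model.

## Worked example

Simulate a full 190-trial run of the default hardness panel with the clean
responder profile, fit the anchored scale, and compile the QC report:

```r
library(anchorpanel)

spec      <- default_panel()
plan      <- build_trial_plan(spec)                    # 190 trials, 64 repeated pairs
responses <- simulate_responses(plan, make_default_profiles()$clean, seed = 1)
dataset   <- join_responses(plan, responses)

scale <- fit_anchored_scale(dataset, spec, bootstrap_reps = 500, seed = 2)
glance(scale)
#> # A tibble: 1 × 7
#>   accuracy log_loss n_obs l2_lambda converged bootstrap_reps bootstrap_seed
#>      <dbl>    <dbl> <int>     <dbl> <lgl>              <int>          <int>
#> 1        1    0.110   190       0.1 TRUE                 500              2
```

Accuracy 1.0 means the fitted strengths reproduce every observed winner;
log loss 0.110 is the penalized model's mean surprise. The scale itself:

```r
scale
#> <anchored_scale> accuracy 1.000, log loss 0.1103, 190 observations
#> # A tibble: 15 × 7
#>    item_id       label               role    canonical_rank score ci_low ci_high
#>  1 marshmallow   Marshmallow         anchor               1   0     0        0
#>  2 life          Life                concept             NA  12.7  -5.35    29.0
#>  3 kindness      Kindness            concept             NA  20.2   3.24    35.3
#>  ...
#> 14 death         Death               concept             NA  90.5  75.6    115.
#> 15 steel         Steel               anchor              10 100   100      100
```

The anchors sit at exactly 0 and 100 with degenerate intervals (they are
pinned by the rescaling in every bootstrap replicate); concepts are placed
between and around them with honest uncertainty — note Life's lower bound
below 0. The QC report:

```r
compile_qc_report(dataset, scale, spec)
#> Quality-control summary
#>   Repeated-pair agreement: 100.0% (64/64)
#>   Confidence vs |score difference|: r = 0.794 (95% CI 0.734-0.842)
#>   Catch-trial pass rate: 100.0% (6/6)
#>   Anchor-order violations: 0/9
#>   Flags: none
```

Re-running with `make_default_profiles()$degraded` (an inverted anchor pair,
noisier choices, decalibrated confidence) yields agreement ≈ 0.89, r ≈ 0.34,
anchor-order violations, and the flags `LOW_REPEAT`, `ANCHOR_ORDER`,
`WEAK_CONFIDENCE_CALIBRATION`, `CATCH_FAIL` — the signature of a run that
should go to review. `build_run_signature()` / `save_signature()` persist a
baseline, and `compare_to_baseline()` turns a rerun into a drift report with
per-item deltas, reversals, and a triggered action.

A command-line wrapper over these functions is installed at
`inst/scripts/anchorpanel.R` (subcommands `design`, `render`, `simulate`,
`ingest`, `fit`, `qc`, `compare-conditions`, `baseline`, `compare`).

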