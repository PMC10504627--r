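# routinewatch

Passive smartphone monitoring produces continuous streams of GPS fixes, step
counts and app-usage events. In psychiatric follow-up cohorts these streams
carry a signal: a patient heading toward a crisis often changes their daily
routine first — less movement, more time at home, different phone use.
`routinewatch` implements a complete, tested pipeline that turns such streams
into day-level one-week risk alarms, for methodologists and clinical
researchers who want to study behavioral-change-based early warning on their
own (or simulated) cohorts.

## The model

Each monitored day is summarized as four 48-dimensional half-hourly vectors:
log distance walked, binary at-home occupancy, log step counts, and binary
app usage, with per-bin observation masks.

**Daily profiling.** Days are clustered per patient with a heterogeneous
mixture model: *K* ≤ 10 components, each factorizing over dimensions with
Gaussian margins on the 96 continuous bins and Bernoulli margins on the 96
binary bins,

  p(x | k) = ∏_{j∈cont} N(x_j; μ_kj, σ²_kj) · ∏_{j∈bin} p_kj^{x_j} (1−p_kj)^{1−x_j}.

Unobserved bins drop out of the product (exact marginalization). The model is
fitted by EM; *K* is chosen by BIC = −2·logL + #params·log(n). Each day then
carries a posterior probability vector over the selected profiles.

**Change-point detection.** A latent run length r_t counts the days since
the last behavioral change. Each behavioral pattern draws daily profiles from
an unknown categorical distribution with a Dirichlet prior, giving a
Dirichlet-categorical predictive (α_k + n_k)/(Σα + Σn) per run-length
hypothesis. With constant hazard *h*, the standard online filtering
recursion propagates P(r_t | data); profile uncertainty is handled by
averaging the recursion over sampled profile paths, and totally missing days
are marginalized exactly (predictive ≡ 1, hazard mixing only).

**Alarms and evaluation.** The cumulative probability that a change occurred
within the previous 7 days is P(r_t < 7). An alarm fires when it exceeds a
*stability threshold* τ; lower τ means higher sensitivity. Day-level
evaluation counts an alarm at day d as a true positive when a risk event
falls in (d, d+7]; pooling all patient-days at 50 thresholds equally spaced
in (0,1) yields the ROC curve and its trapezoidal AUC.

A synthetic cohort generator (raw 5-minute GPS tracks, per-bin step records,
app events; piecewise-constant behavioral patterns; risk events coupled to
planted change points; partial/total missingness) makes the whole pipeline
testable without any real data.

## Worked example

```r
library(routinewatch)

cfg <- pipeline_config(
  scenario = scenario_config(
    n_patients = 4, days_per_patient = 60,
    segments = list(list(start_day = 0,  profile_dist = c(0.9, 0.1)),
                    list(start_day = 30, profile_dist = c(0.1, 0.9))),
    p_event_given_change = 1, p_background_event = 0, rng_seed = 1),
  K_max = 2, n_restarts = 2, n_samples = 0, seed = 1)

res <- run_pipeline(cfg)

res$manifest$selected_K
#> [1] 2 2 2 2
round(res$change_prob[[1]][28:38], 3)
#> [1] 0.045 0.044 0.146 0.416 0.728 0.893 0.947 0.949 0.875 0.159 0.068
res$roc
#> <roc_result> 50 threshold(s), AUC = 0.793
```

Every patient's BIC selects the two planted profiles. The 7-day change
probability for patient 1 sits at its hazard-driven floor (~0.04) until the
planted pattern inversion at day 30, climbs to ~0.95 within four days, and
relaxes again once the change leaves the 7-day window — exactly the behavior
the stability-threshold rule needs. The pooled day-level AUC of 0.79 on this
4-patient toy cohort reflects a structural property of forward-window
day-level scoring: pre-change days inside the event window are causally
unpredictable, which caps attainable AUC well below 1 even for a perfect
detector (see the methods vignette).

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/pipeline.R", package="routinewatch"))') \
  run-all --config cfg.json --seed 1 --out-dir out/
```

Subcommands `simulate`, `preprocess`, `profile`, `changepoint`, `detect`,
`evaluate` expose the individual stages over JSONL/CSV artifacts.

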