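# correctmem

Simulation and dual-process modeling of memory for corrected fake news.

## The problem

When fake news is corrected, does repeating the misinformation (a *fake-news
reminder*) help or hurt later memory and beliefs, compared with just labeling
the correction — or labeling the fake news itself? Experiments on this
question use a three-phase headline paradigm: participants study real and
fake news headlines (Phase 1), then see real-news headlines that repeat or
correct them (Phase 2), and finally take a cued-recall test in which they
recall the real-news detail, rate their belief in it, judge whether the topic
had been corrected, and if so recall the fake detail (Phase 3). Sixty topics
rotate through four within-participant headline-type conditions (repetition,
unlabeled correction, labeled correction *or* labeled fake news, and
reminder + labeled correction) across four counterbalance lists.

`correctmem` is for researchers who run, simulate, or reanalyze such
experiments. It provides, end to end:

* a **design generator** for the counterbalanced lists and constrained
  presentation orders (no more than 3 consecutive same-condition topics,
  condition mean list positions within 2 of the grand mean);
* a calibrated **trial-level simulator** with crossed participant and topic
  heterogeneity on the logit scale and ordinal belief ratings;
* **response coding** into real recall / intrusion / other categories and the
  conditional classification classes;
* **mixed-effects analyses** (lme4/emmeans) of recall, intrusion, fake-recall
  probabilities and belief ratings, with crossed random intercepts and
  Tukey-adjusted pairwise contrasts;
* a **hierarchical Bayesian multinomial processing tree (MPT)** separating
  recollection and familiarity, fit by MCMC (JAGS).

## The model at its core

Cued recall of a corrected topic is assumed to require recollection (`r`) of
the correction to override the familiarity (`f`) of the fake headline:

    P(real recall) = r
    P(intrusion)   = (1 − r) · f
    P(other)       = (1 − r) · (1 − f)

Per participant `p` and condition `c`, category counts are multinomial with
parameters `invlogit(mu[θ,c] + delta[θ,p,c])` for `θ ∈ {r, f}`, with
logit-normal participant effects whose recollection and familiarity
components are correlated (latent-trait structure). Priors:
`mu ~ N(0, 1.5²)`, `sigma ~ Half-Normal(1)`, `rho ~ U(−1, 1)`. Population
estimates are posterior means of `invlogit(mu)` (the median-participant
probability), and condition contrasts are computed draw-wise on the
probability scale; a difference is *credible* when its 95% central credible
interval excludes zero.

## Worked example

Simulate one Experiment-1 dataset at the default calibration (96
participants × 60 topics), estimate condition-level recall, and fit the MPT:

```r
library(correctmem)

cfg <- default_config(1)
trials <- simulate_dataset(cfg)

fit_binomial_mixed(trials, "real_recalled")
#> Mixed-model estimates for `real_recalled` (probability scale)
#>  condition estimate ci_low ci_high    n
#>        REP    0.795  0.753   0.831 1440
#>         UC    0.276  0.232   0.325 1440
#>         LC    0.412  0.358   0.468 1440
#>       FRLC    0.542  0.485   0.597 1440
#> 6 pairwise contrasts (tukey-adjusted)

post <- fit_hierarchical(tabulate_mpt(trials), seed = 2)
post
#> Hierarchical MPT posterior (4 chains x 1000 draws, seed 2)
#>   r[UC] = 0.288 [0.250, 0.325]
#>   r[LC] = 0.419 [0.379, 0.463]
#>   r[FRLC] = 0.540 [0.497, 0.583]
#>   f[UC] = 0.347 [0.305, 0.390]
#>   f[LC] = 0.140 [0.112, 0.170]
#>   f[FRLC] = 0.137 [0.108, 0.169]
#>   max R-hat 1.007, min ESS 299

d <- credible_difference(post, "r", "LC", "UC")
sprintf("r(LC) - r(UC) = %.3f [%.3f, %.3f], credible = %s",
        d$mean, d$ci[1], d$ci[2], d$credible)
#> "r(LC) - r(UC) = 0.131 [0.075, 0.191], credible = TRUE"
```

Reading the output: recall is best for repeated real news (0.795), worst for
unlabeled corrections (0.276), and reminders beat labels (0.542 vs 0.412) —
the ordering the calibration encodes (generating values 0.76, 0.25, 0.40,
0.51). The MPT attributes the reminder and label advantages to recollection
(`r` rising from 0.29 to 0.54 across correction conditions) while
familiarity is highest for unlabeled corrections (0.35 vs ≈ 0.14), and the
label-vs-no-label recollection contrast of 0.131 [0.075, 0.191] recovers the
generating gap of 0.15.

`run_pipeline(experiment = 1, seed = 11, out_dir = "results")` chains all
stages (design → simulate → code → mixed models → conditional models → MPT →
beliefs) and writes CSV outputs plus a `manifest.json` with seeds, config
hash, and stage status. A thin CLI wrapping the same functions is installed
at `inst/cli/correctmem` (verbs: `design`, `simulate`, `code`, `analyze`,
`fit-mpt`, `recover`, `run`).

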