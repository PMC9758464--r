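---
title: "Models and design choices behind correctmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind correctmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(correctmem)
```

`correctmem` implements the computational core of a two-experiment paradigm
for studying fake-news corrections: how reminders of fake news and veracity
labels affect later memory for corrected real-news details and beliefs in
them. This vignette explains the generative model, the statistical models,
and the design decisions that were genuinely open, in enough detail that a
reader could re-derive or replace any component.

## The paradigm and its design constraints

Each participant works through 60 news *topics* in three phases: exposure to
real and fake headlines (Phase 1), corrections and repetitions (Phase 2),
and a cued-recall test with belief ratings (Phase 3). Topics are rotated
through four within-participant headline-type conditions — repetition
(`REP`), unlabeled correction (`UC`), labeled correction (`LC`, Experiment
1) or labeled fake news (`LFN`, Experiment 2), and fake-news reminder before
a labeled correction (`FRLC`) — in sets of 15, by a Latin square over four
counterbalance lists, so every topic serves every condition across lists.

`build_design()` produces presentation orders under two constraints: no more
than three consecutive same-condition topics, and each condition's mean list
position within 2.0 positions of the grand mean (30.5 for 60 items). The
2.0-position tolerance is our operationalization of "equated" average list
position: tight enough that serial-position effects cannot differ
meaningfully between conditions (2 positions out of 60 shifts expected
recency/primacy by a negligible amount), loose enough that orders satisfying
both constraints exist in abundance. Orders are found by rejection sampling
with local swap repair of over-long runs, bounded at 10,000 restarts;
exceeding the bound raises an error, which signals an impossible constraint
configuration rather than silently relaxing a constraint. One fixed order is
generated per counterbalance list (the alternative — a fresh order per
participant — is unstated in the paradigm's description; a shared order per
list is the simpler reading and is what the generator assumes).
Fake-news reminders are modeled as an attribute of `FRLC` trials rather
than separate list slots, because a reminder immediately precedes its
correction and therefore shares its serial position for balancing purposes.

## The generative model

`simulate_dataset()` draws one long-format dataset (one row per participant
by topic) from an explicit dual-process model, so that every downstream
analysis has a known ground truth.

On correction trials, *recollection* fires with probability
$\mathrm{logit}^{-1}(\mathrm{logit}(r_c) + u_p + w_i)$, where $r_c$ is the
condition-level recollection probability and $u_p \sim N(0,
\sigma_p^2)$, $w_i \sim N(0, \sigma_i^2)$ are participant and topic
intercepts on the logit scale. A recollected trial yields correct real-news
recall. Without recollection, *familiarity* fires at
$\mathrm{logit}^{-1}(\mathrm{logit}(f_c) + u_p + w_i)$ and produces an
intrusion — the fake detail reported as the real one; otherwise the trial is
`OTHER`. Correction classification is conditionally independent given
recollection (0.9 when recollected, 0.2 otherwise), and fake-news recall is
prompted only after a "yes" classification, with per-condition probability
(highest, 0.75, in the reminder condition). Repetition trials only have a
recall outcome; intrusions are structurally impossible there.

Belief ratings use a thresholded latent Normal: latent mean per response
category and condition, participant belief intercept (SD 0.5), residual SD
1.0, cutpoints at 1.5, 2.5, ..., 5.5 mapping to the 1-6 scale. This is the
simplest ordinal generator whose means can still be meaningfully analyzed
by the Gaussian mixed models used downstream. Phase-1 familiarity and
belief ratings come from the same mechanism with veracity-level means (real
news more familiar and more believed than fake), and labeled fake news in
Experiment 2 given a markedly lower belief mean.

### Calibration

The published results report condition *differences* with intervals, not
absolute parameter levels, so the calibration anchors are package choices
and the differences are the constraint:

| quantity | Experiment 1 | Experiment 2 |
|---|---|---|
| recollection $r$ | UC 0.25, LC 0.40, FRLC 0.51 | UC 0.28, LFN 0.33, FRLC 0.51 |
| familiarity $f$ | UC 0.30, LC 0.12, FRLC 0.12 | UC 0.15, LFN 0.12, FRLC 0.12 |
| repetition recall | 0.76 | 0.70 |

These encode $r_{LC}-r_{UC}=0.15$, $r_{LFN}-r_{UC}=0.05$, a smallest
reminder advantage of 0.11 across experiments, and
$f_{UC}-\tfrac{1}{2}(f_{LC}+f_{FRLC})=0.18$ in Experiment 1. Heterogeneity
defaults are $\sigma_p = 0.8$ and $\sigma_i = 0.5$ on the logit scale —
values in the range typically estimated for by-participant and by-item
intercepts in recall data, and large enough that interval widths of the
fitted models resemble the published ones. All calibrated probabilities are
*conditional* (random effects at zero), so that the inverse-link
fixed-effect estimates of the mixed models and the MPT's
median-participant estimates recover them directly; that convention is
used consistently on both the generating and the estimating side.

Sample sizes default to the study's: 96 participants, distributed
round-robin over the four counterbalance lists.

### What the generator does not emulate

Real datasets have features the generator deliberately omits: topic content
effects (some topics are intrinsically memorable), the
qualitative/quantitative correction distinction, free-text answers that
need human scoring, attention lapses, and any dependence of belief on the
specific detail recalled. Passing recovery tests therefore shows that the
estimators are correct and well calibrated *for this data-generating
process* — it validates the pipeline, not the substantive conclusions of
any particular real dataset.

## Mixed-effects analyses

`fit_binomial_mixed()` fits logit-link models with crossed random
intercepts for participants and topics via `lme4::glmer` (Laplace
approximation, bobyqa optimizer), and `fit_gaussian_mixed()` fits belief
ratings via `lmerTest` with Satterthwaite degrees of freedom. Estimates are
reported as the inverse link of the fixed-effect predictor at random
effects zero, with Wald intervals, through `emmeans`; population-averaged
(marginal) probabilities are available behind a flag using the standard
logit-normal shrinkage approximation. All-pairs contrasts default to Tukey
adjustment — the conventional choice for a family of all pairwise
comparisons; Holm and unadjusted variants are available.

Degenerate inputs are surfaced, never absorbed: constant outcomes within a
fixed-effect cell raise a complete-separation error before fitting,
optimizer warnings are captured into the result's `convergence` field and
re-raised as a warning, and empty condition-by-classification cells in the
conditional models are flagged and excluded from estimates and contrasts.
The conditional intrusion models drop the classified-and-fake-recalled
cells, where an intrusion would be a redundant report of a detail the
participant had just recalled at the fake-recall prompt.

## The hierarchical MPT

The dual-process multinomial processing tree assumes recollection of the
correction overrides familiarity of the fake headline:

$$P(\text{real recall}) = r,\qquad
  P(\text{intrusion}) = (1-r)f,\qquad
  P(\text{other}) = (1-r)(1-f).$$

The tree is saturated per condition (two free parameters, three
categories), so it cannot misfit at the category level; the inferential
content lies in the hierarchy. Per participant $p$ and condition $c$ the
count triple is multinomial with parameters at
$\mathrm{logit}^{-1}(\mu_{\theta c} + \delta_{\theta p c})$ for $\theta \in
\{r, f\}$. Priors are weakly informative: $\mu \sim N(0, 1.5^2)$ on the
logit scale (near-uniform on the probability scale), $\sigma \sim$
Half-Normal(1), $\rho \sim U(-1, 1)$.

Two hierarchy choices deserve explanation because both depart from the most
minimal model:

* **Per-condition participant effects.** With a single participant effect
  shared across conditions, condition contrasts cancel it exactly and their
  posterior intervals collapse to binomial width (about $\pm 0.03$ here) —
  far narrower than the interval widths such experiments actually produce,
  and narrow enough to declare every small contrast credible. Per-condition
  effects keep between-participant variability in the contrasts, matching
  the width regime of the published intervals (half-widths 0.06-0.09).
* **Correlated recollection and familiarity effects** (latent-trait
  structure, correlation $\rho$ shared across conditions). This is not
  cosmetic: the number of trials informing a participant's familiarity is
  their number of *non-recollected* trials. When the same ability drives
  both processes, cluster size is informative, and an independence
  hierarchy systematically underestimates the familiarity locations — in
  our replicate studies by about $-0.02$ with interval coverage dropping to
  0.70-0.75. With the correlation in the model, bias falls below 0.01 and
  coverage returns to the nominal range.

Sampling is MCMC via JAGS (4 chains, 1000 post-warmup draws, 1000
adaptation and 1500 burn-in iterations by default), with the participant
effects non-centered ($\delta = \sigma z$, $z \sim N(0,1)$): the centered
form mixes poorly on $\sigma_f$ when per-cell information is weak (split-
$\hat R$ up to 3 in our checks; non-centered stays below 1.02 at study
scale). Convergence is gated on split-$\hat R \le 1.05$ — exceeding it
raises an error carrying the diagnostics rather than returning a silently
bad fit. Divergent-transition counts are a Hamiltonian-Monte-Carlo concept
with no analogue under JAGS's conjugate/slice samplers, so $\hat R$ and
effective sample size are the reported diagnostics.

Population estimates are posterior means of
$\mathrm{logit}^{-1}(\mu)$ — the median-participant probability — and
condition differences are computed draw-wise on the probability scale
(`credible_difference()`), with "credible" meaning the 95% central
credible interval excludes zero. The familiarity contrast for unlabeled
corrections is taken against the *average* of the other two correction
conditions, the reading consistent with a single pooled estimate for "all
other corrections". The closed-form moment estimator
(`moment_estimates()`, the exact inverse of the tree at pooled
frequencies) is kept as an independent oracle: in the no-heterogeneity
limit the hierarchical posterior means must agree with it, and the test
suite enforces that to within 0.02.

## Numerical and testing choices

* Problem sizes in the test suite: unit tests run at 6-96 participants
  with short chains (2 x 400 draws); the study-scale checks run at the full
  96 participants with 4 x 1000 draws, and the replicate coverage study
  uses 20 replicates at 2 x 500 draws. The no-heterogeneity oracle
  comparison uses 2000 participants for raw frequencies and 200 for the
  Bayesian fit.
* The law-of-large-numbers check on the generator holds to within a 0.01
  absolute tolerance at 2000 participants; the oracle agreement to 0.02;
  replicate coverage is accepted at 0.85 or above, the usual allowance for
  a 20-replicate binomial estimate of a 95% rate.
* Tie-breaks and degenerate cases: `r = 1` forces universal recall and an
  undefined moment estimate of `f` (flagged, not silently imputed);
  `n_replicates = 0` recovery requests return an empty report; repetition
  trials raise on any attempt to assign a conditional class.
* Seeds propagate explicitly: the design, the simulator, and each MCMC
  chain derive their RNG state from user-supplied integers, and identical
  seeds reproduce byte-identical datasets and draws.

## Known limitations

The adopted tree is the minimal structure consistent with the dual-process
assumption; richer trees that also model classification and fake-recall
responses as category splits would use more of the data and could be
substituted behind the same interface. The belief analyses treat ratings
as Gaussian, as the reported t statistics imply, although the generator is
ordinal; an ordinal analysis model is a natural extension. Random slopes
(condition-by-participant) are not implemented in the mixed models — only
crossed random intercepts, as in the analyses the pipeline mirrors — and
the MPT's latent-trait correlation is shared across conditions rather than
estimated as a full correlation matrix.
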