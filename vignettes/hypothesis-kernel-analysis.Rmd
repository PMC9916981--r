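---
title: "Hypothesis kernel analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypothesis kernel analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hka)
```

## The problem

Decades of research on facial expressions of emotion have produced competing
*qualitative* hypotheses of the form "happy is expressed with Action Units 6
and 12". Such hypotheses cannot be compared directly: they differ in how many
AU configurations they propose per emotion, whether AUs are optional or
mutually exclusive, and which emotions they cover. `hka` converts them into
*predictive classifiers* that share a common currency — out-of-sample
predictive performance on forced-choice categorization behavior — and then
closes the loop: it explains performance by causally ablating AUs, and uses
those explanations to construct improved, culture-accented models.

## The model

### AU space and recoding

Stimuli and hypotheses live in a common 33-dimensional amplitude space. The
generative AU vocabulary contains compound labels (AU1+2, AU6+12, AU12+25)
and bilateral labels (e.g. AU12, meaning both sides of the face). To make
every coordinate an independent variable, compounds are expanded into their
constituents and eight AU numbers (2, 6, 7, 10, 11, 12, 14, 20) are split
into left/right variables, yielding the canonical set returned by
`au_labels()`. Amplitudes lie in $[0,1]$ (0 = not active, 1 = maximally
active). When two raw labels reach the same canonical variable the maximum
amplitude wins by default ("active" semantics); a clipped sum is available.

### From hypothesis to classifier

A hypothesis model assigns each category $q$ one or more binary (or, for
data-driven models, weighted) configuration vectors $m_{q1}, \dots, m_{qK}$
over the 33 AUs. Given a stimulus vector $s$, the category score is the
similarity of the *best-matching* configuration,

$$ z_q(s) = \max_k \; \cos(s, m_{qk}), $$

with $\cos(u,v) = u^\top v / (\lVert u\rVert\,\lVert v\rVert)$ and
$\cos(u, v) = 0$ whenever either norm is zero (a neutral face resembles
nothing). The max rule means a model with several configurations for one
emotion is scored by whichever set the stimulus resembles most. Softmax
normalization turns scores into a probability vector,
$p_q \propto \exp(\beta z_q)$, over the model's covered categories.

### Scoring against behavior

Performance is the one-vs-rest AUROC, computed per participant and category:
the probability that a randomly chosen trial the participant labeled $q$
receives a higher category-$q$ score than a randomly chosen trial labeled
otherwise, ties counting one half (the Mann–Whitney convention). Chance is
0.5 and a perfect ranker attains 1 regardless of class imbalance. Cells with
a single response class are undefined; they are skipped and recorded, never
imputed.

**Ranking column.** AUROC is rank-based, so any strictly monotone transform
of the score column leaves it unchanged. For the one-vs-rest problem
"category $q$ versus the rest" the natural ranking score is the margin

$$ r_q(s) = z_q(s) - \max_{q' \neq q} z_{q'}(s), $$

which is exactly the quantity the binarized two-class softmax is monotone
in, at any $\beta > 0$. `hka()` therefore ranks by margin by default: the
inverse temperature $\beta$ (default 1) affects *probability calibration
only* and provably cannot move any AUROC, and noiseless argmax responders
are scored exactly 1. The full multiclass softmax probability column is
available via `ranking = "prob"`; note that for three or more categories it
is *not* a monotone transform of the per-category score (its denominator
varies across trials), so with that option AUROC acquires a mild,
usually negligible, $\beta$ dependence.

## The noise ceiling

If different people categorize the *same* AU pattern differently, no fixed
stimulus-based model can attain AUROC 1. The ceiling estimates the best
achievable score from between-participant inconsistency on repeated stimuli.
The optimal stimulus-measurable score for "category $q$ versus rest" is the
conditional probability $P(y = q \mid s)$, so the ceiling is the AUROC of
its empirical estimate.

Two finite-sample biases need care, and `noise_ceiling()` controls both:

- **Self-leakage.** Scoring a trial with a conditional distribution that
  includes the trial's own response lifts the ceiling of even
  stimulus-independent labels well above chance (about 0.60 at 60
  observations per stimulus in our simulations). Each trial is therefore
  scored by the leave-one-response-out distribution of its stimulus group.
- **Within-stimulus pairs.** Any stimulus-based score is constant across
  trials of an identical stimulus, so a positive–negative pair inside one
  stimulus group is an irreducible tie; it is counted one half. (Naive
  leave-one-out instead mis-ranks every such pair downward.)

With both controls the estimator hits the analytic value in closed-form
fixtures (a two-stimulus Bernoulli mixture with $P(A\mid s_1) = 0.9$,
$P(A \mid s_2) = 0.1$ gives exactly 0.90), saturates at 1 for deterministic
raters, and sits at 0.5 for stimulus-independent labels. Stimuli observed
once fall back to their own label — optimistic — so the singleton fraction
is always reported and a warning is raised above 50%. A conservative
`leave_one_participant_out` mode scores each participant's trials from other
participants' observations only. The bootstrap SD resamples observations
within stimulus groups (`n_boot` default 1000). Whether distributions pool
cultures or condition on them is a named option (`grouping`), since either
choice is defensible.

## Explanation and exploration

`ablation_map()` removes each canonical AU present in a category's
configurations (both laterals when a bare number is ablated), re-scores only
that category, and records the participant-mean change
$\Delta = \mathrm{AUROC}_{\text{ablated}} - \mathrm{AUROC}_{\text{original}}$,
averaged over the models containing the AU. Cells for AUs in no model are
undefined, never zero. An AU with negative mean $\Delta$ is
*performance-critical*, positive mean $\Delta$ *performance-detrimental*;
`derive_accents()` applies this strict sign rule with an optional dead-zone
$\varepsilon$ (default 0 — no threshold is prescribed, and the dead-zone is
exposed for users who want to ignore hairline effects).

`optimize_model()` then adds every critical AU to, and removes every
detrimental AU from, each configuration of the category, per culture.
Deduplication follows; emptied configurations are dropped. If a category
would lose *all* configurations the model keeps the original configuration
with the fewest detrimental AUs and flags the category — the least-affected
configuration is the most defensible fallback when the edit rule
self-destructs. Ablation edits the target category only; removing an AU from
all categories simultaneously is a different experiment and deliberately not
implemented.

Everything upstream of optimized-model evaluation is cross-validated by
`split_train_test()`: participants split 2/3 : 1/3 per culture (40/20 at the
study's 60), face identities 50/50, and stimulus keys 50/50, so test trials
contain unseen AU combinations *and* unseen faces from unseen participants.
Trials off the diagonal (e.g. a train participant viewing a test stimulus)
are dropped and the dropped fraction reported — with fully crossed random
stimuli this discards roughly three quarters of trials, the price of
treating participant, face and stimulus as crossed random factors.
`hk_explore()` asserts the disjointness invariants inside the pipeline
before any test-set evaluation. Culture comparisons are two-sided pooled-
variance t tests on model-averaged per-participant AUROCs with pooled-SD
Cohen's d (first culture minus second); no multiple-testing correction is
applied, which the output flags.

## The data-driven estimator

`fit_participant_model()` screens each (category, AU) cell by the
point-biserial Pearson correlation between AU amplitude and the binary
category indicator, with the two-sided p-value from the $t$ transform on
$n-2$ degrees of freedom; a cell is marked significant at uncorrected
$\alpha = 0.05$. By default a *positive* correlation is also required: a
significantly *negative* amplitude–choice relation is evidence the AU does
not belong in the category's template. (The sign rule is switchable; the
screening literature is silent here and the choice is documented rather
than hidden.) Per-participant binary matrices are then aggregated: weighted
mode assigns each AU the proportion of participants in which it was
significant (an AU significant in 9 of 10 participants gets weight 0.9);
majority mode binarizes at a strict "more than half" threshold.
`lopo_evaluate()` cross-validates by leave-one-participant-out: each fold
aggregates the other participants' fits and scores the held-out participant.
Weighted configurations enter the cosine kernel as continuous coordinates.

## The behavior simulator

`simulate_experiment()` emulates the study design so that every stage runs,
and is validated, without any external data: per culture (default two,
labeled WE and EA), 60 participants each categorize 1200 random-AU
animations. Stimuli activate $k \sim \mathrm{Binomial}(5, 0.6)$ generative
labels (zero draws resampled — an expressionless face cannot be
categorized) with peak amplitudes uniform on $(0,1)$; six temporal
parameters per AU are generated for structural fidelity and ignored by all
analyses, which use peak amplitude only. Eight base faces per culture tag
each stimulus. The default 1200 trials per participant is half the
original design's 2400; it keeps a full prediction–explanation–exploration
cycle within desk-scale runtime while leaving all power checks comfortably
passing, and is stated wherever results depend on it. A shared block of 40
repeated stimuli per culture (matching the order of magnitude of repeats per
participant in the original design) supports noise-ceiling estimation.

The generative vocabulary has 42 labels, matching the reported size of the
original generator. Because the original list is not published in full, the
bundled vocabulary is a declared stand-in: the 3 compounds, the 25 plain
AU numbers, and unilateral labels for 7 of the 8 lateralized numbers
(AU11's unilaterals are omitted to reach the reported count; AU11 remains
reachable bilaterally, so all 33 canonical variables occur).

Responders implement the generative perceiver the framework presupposes:
each carries a personal hypothesis model — the culture's base model,
optionally accent-edited (AUs added/removed per category) and perturbed by
per-(category, AU) idiosyncratic toggles with probability $\pi$ — scores
stimuli by the same kernel, answers "other" when the best score falls below
a threshold $\tau$, lapses uniformly with probability $\lambda$, and
otherwise samples from $\mathrm{softmax}(\beta_p z)$ (via Gumbel-max, so
$\beta_p = \infty$ is the argmax). Defaults $\beta_p = 10$, $\lambda = 0.1$,
$\tau = 0.2$, $\pi = 0$ produce behavior that is clearly stimulus-driven but
far from deterministic — about 5% "other" responses and model AUROCs in the
0.7–0.9 range, the regime the method is meant for.

What the simulator does *not* emulate: facial geometry and rendering,
temporal AU dynamics, intensity ratings, face-identity appearance effects,
and any perceiver covariates beyond the culture label. Passing recovery
tests on simulated behavior therefore demonstrates the estimators are
correct and well-calibrated under the stated generative assumptions — not
that those assumptions exhaust real categorization behavior.

## Numerical choices and degenerate inputs

- AUROC uses average ranks; exact equality with an $O(n^2)$ pairwise oracle
  is enforced in tests, including ties.
- Zero-amplitude stimuli score 0 against every configuration, giving uniform
  predictions.
- Stimulus keys round amplitudes to 6 decimals (configurable) before
  canonical-string hashing; equal AU patterns always collide.
- Ablating an AU absent from a category is an error (distinct from a zero
  effect); ablating the last AU of a category's only configuration flags the
  category non-evaluable rather than silently returning an empty model.
- Registry entries containing AU numbers outside the canonical space (one
  published disgust entry lists AU19, which the recoded space cannot
  represent) drop the unmappable number and record it on the model object;
  strict constructors reject it.
- All randomness flows through explicit seeds; splits, simulations and
  bootstraps are bit-reproducible given the seed, and the CLI writes a
  provenance record (version, parameters, seed, input hashes) next to every
  artifact.

## Problem sizes used by the test suite

Unit tests run on tables of tens to a few thousand trials. The end-to-end
validation uses the full study geometry — 2 cultures × 60 participants ×
1200 trials — for the planted-accent recovery check, 40 × 1200 for
data-driven model recovery, and 60 observers × 200 repeated stimuli for the
noise-ceiling chance calibration. A complete run of the suite takes on the
order of one to two minutes on a single core.

## Known limitations

- The conversational-signal registry ships named but empty slots: the
  published configuration tables for those five studies are not bundled, so
  users must supply specifications; all machinery (subset category coverage,
  binary-model AUROC symmetry) is in place and tested.
- The plug-in ceiling remains optimistic where stimuli are observed once;
  use repeated-stimulus designs, watch the reported singleton fraction, or
  switch to the leave-one-participant-out mode.
- One explanation→exploration pass is implemented; iterative re-ablation of
  optimized models is out of scope.
- Culture comparisons are uncorrected for multiple testing by design, and
  labeled as such.
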