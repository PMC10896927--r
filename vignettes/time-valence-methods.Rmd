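---
title: "Models and methods behind chronoval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chronoval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoval)
```

`chronoval` studies the mental association between deictic time (past vs
future) and emotional valence (negative vs positive): an
interactive-activation model of the reaction-time *match effect*, seeded
generators that emulate the kinds of experiments used to measure it, and the
analysis machinery to estimate and test the effects. This vignette explains
the models, the parameter choices, and the design decisions — including what
the synthetic data can and cannot tell you about real experiments.

## The interactive-activation model

Four nodes represent past time (1), future time (2), negative valence (3)
and positive valence (4). Within each domain the two nodes are antagonists
(mutual inhibition, weight −β); across domains the agonist pairs excite each
other (weight +γ). Variant `model1` has both agonist pairs (past–negative
and future–positive); `model2` removes the past–negative links, encoding the
hypothesis that the association is carried solely by a future–positive link
(an "optimistic" asymmetry). A stimulus injects a constant input $I$ into
its node.

Node activations evolve by a bounded discrete (Euler) update. With output
$O_j = \max(a_j - \mathrm{rest}, 0)$ — only supra-rest activation propagates,
the standard interactive-activation convention that also prevents runaway
inhibition — and net input $n_i = \sum_j w_{ij} O_j + I_i$:

$$\Delta a_i = \begin{cases}
\mathrm{step}\cdot[n_i(\mathrm{max}-a_i) - \mathrm{decay}(a_i-\mathrm{rest})] & n_i \ge 0\\
\mathrm{step}\cdot[n_i(a_i-\mathrm{min}) - \mathrm{decay}(a_i-\mathrm{rest})] & n_i < 0
\end{cases}$$

with activations clipped to $[\mathrm{min}, \mathrm{max}]$. Two response
accumulators integrate the node outputs; under the *match* wiring response A
receives $O_1 + O_3$ and B receives $O_2 + O_4$, under *mismatch* A receives
$O_1 + O_4$ and B receives $O_2 + O_3$. A response is emitted when an
accumulator reaches the threshold.

Defaults: γ = 0.10, β = 0.10, I = 0.40, rest = 0, min = −0.2, max = 1.0,
decay = 0.10, step = 0.1, gain = 1.0, threshold = 0.5, max_steps = 2000.
These are conventional interactive-activation ranges that produce the
qualitative response-activation curves of interest; every one of them is a
plain field of `ia_network()` and can be overridden (subject to the
variant's sign pattern, which is enforced).

Numerical choices worth knowing:

* The update is deterministic and bit-reproducible; there is no stochastic
  (noisy-accumulator) variant, and no parameter fitting to empirical RT
  distributions — the model is a qualitative account.
* The discrete crossing step is quantised, so the trace also records a
  *continuous* crossing time obtained by linear interpolation of the winning
  accumulator across the threshold. Predictions and the match effects use
  the interpolated time. Under repeated halving of `step` the interpolated
  crossing times converge first-order (successive relative changes at the
  defaults: about 1.0%, 0.5%, 0.25%), as expected for an explicit Euler
  scheme; the test suite checks that the successive changes shrink and end
  below 1%.
* Crossing times are in simulation steps / model time. `steps_to_ms()`
  provides an affine display mapping only; the model makes no claim about
  absolute milliseconds.
* Response accumulators do not leak; a leak-free accumulator is the simplest
  assumption consistent with the wiring diagram.

Under `model1` defaults both response categories show a strictly positive
match effect. Under `model2`, a past/negative stimulus leaves nodes 3 and 4
exactly at rest (nothing excites them), so the match and mismatch wirings
integrate identical outputs and the past/negative match effect is exactly
zero, while future/positive keeps its full effect — the qualitative
signature separating the two hypotheses.

```{r ia}
predict(ia_network("model1"))
predict(ia_network("model2"))
```

## The reaction-time generator

`generate_rt_experiment()` emulates factorial Match × Congruency × Domain
block designs. Three canonical designs are provided: a manual-response
design with Match between subjects (each subject runs a fully congruent and
a fully incongruent block, or the two mixed blocks of the mismatch group)
and two vocal-response designs with Match within subjects over four
alternating blocks and no spatial congruency factor.

The trial model is additive on the millisecond scale:

$$\mu = \mathrm{base\_rt} + \mathrm{match} + \mathrm{congruency} +
\mathrm{domain} + \mathrm{practice}\cdot(\mathrm{block}-1) + b_{subject} + b_{item}$$

with normal subject and item intercepts and a shifted-lognormal residual:
RT = shift + Lognormal(meanlog, sdlog) with meanlog chosen so that the
per-trial expectation equals μ exactly. The shifted lognormal is
right-skewed and strictly positive — the two properties real RT
distributions reliably show — and its moment calibration is closed-form.
With `sdlog = 0` the generator is degenerate and every RT equals μ, which
the tests exploit for exact-value checks. If an extreme subject/item draw
pushes μ to the distribution's lower bound the latent mean is floored 1 ms
above the shift; this confines calibration bias to the deep tail instead of
aborting a run.

Default magnitudes are calibrated to the canonical manual-response
experiment: base 680 ms for a match/congruent/valence trial, match effect
170 ms, congruency effect 48 ms, domain effect 158 ms (time words slower),
subject SD 100 ms, item SD 40 ms, sdlog 0.3, shift 200 ms, error rates 4%
plus 4 percentage points on mismatch trials. Errors are independent
Bernoulli draws given the condition — RT and accuracy are analysed
separately, so the generator does not model a latent speed–accuracy
mechanism, and passing tests say nothing about trade-off dynamics in real
data. Block order is counterbalanced by reversing the base order for
alternate subjects; trial order within a block is a uniform shuffle (no
further sequencing constraints are modelled). Experiment halves derive from
each subject's own presentation order (first 50% of blocks).

What the generator deliberately does not emulate: response-device artifacts
(voice-key onsets), participant replacement rules, practice-trial feedback,
sequential effects (post-error slowing, first-trial effects), or any
dependence between RT and accuracy. Conclusions from synthetic-data tests
transfer to real data only insofar as the additive-effects-plus-skewed-noise
model holds.

## Permutation inference for condition effects

The estimand of `estimate_effect()` is the difference of the two level
means, computed on subject-level means with items averaged first
(item → subject → condition), so each subject is one exchangeable unit. The
permutation null flips each subject's level labels (within-subject factors)
or reassigns subjects to groups (between-subject factors);
$p = (1 + \#\{|T^\pi| \ge |T|\})/(1 + B)$ with $B = 5000$ by default and a
mandatory seed. This replaces mixed-effects likelihood-ratio testing: it is
assumption-light, exact under exchangeability, and estimates the same
level-mean contrast. An off-the-shelf mixed-model fitter (`lme4`) is listed
in Suggests purely for cross-checking.

One subtlety the package is explicit about: the *domain* contrast compares
time words with valence words, which are disjoint item sets. Item-level
sampling variation therefore produces a genuine, sample-specific domain
difference that is shared by every subject — the null is not
subject-exchangeable, and a subject-level permutation test will (correctly,
from its own point of view) reject more often than α. This is the classic
language-as-fixed-effect problem, and it is why crossed mixed models or
minF′ exist. Match and congruency are counterbalanced within items, so item
effects cancel and their nulls remain exchangeable under item variance. The
null-calibration tests accordingly run match and congruency under the full
default noise and the domain factor under a design without item variance
(its exchangeable null); a domain test on real data should treat items as a
random factor.

Outlier filtering removes RTs strictly below 250 ms or strictly above
2000 ms (boundaries retained); the filter runs before accuracy partitioning,
and the report records counts and fractions of both tails. RT cell means use
correct trials only; percentage correct uses all retained trials. The
half-split report prints both the RT and the accuracy match effect as
mismatch − match, so a more accurate match condition appears as a negative
accuracy difference.

## Rating surveys and the mixed ANOVA

`generate_ratings()` emulates a two-age-group survey where every participant
rates 15 past-related and 15 future-related words on a 1–7 scale. A rating
is a normal draw around the word category's mean plus a participant
intercept, rounded to the integer scale and clamped to [1, 7]. Group sizes
default to 826 younger and 221 older participants.

`mixed_anova()` computes the classical 2 × 2 mixed-design ANOVA from sums of
squares: the between-subject stratum on participant averages, the
within-subject stratum on each participant's future − past difference.
Degrees of freedom derive from the design — (1, N − 2) for all three
effects. The standardised time effect is defined on the within-subject
difference scores, $d = \bar D / s_D$, the natural companion of a paired
contrast; the report documents this because "Cohen's d" alone is ambiguous
between the paired and the pooled-SD convention.

`calibrate_rating_params()` places the two category means symmetrically
about the scale centre so that the true standardised difference equals a
target d. Because ratings are rounded to integers, the per-rating variance
used in the calibration is $\sigma_w^2 + 1/12$ (Sheppard's correction for
grouping); clamping at the scale ends adds a small residual bias (the means
sit near the scale centre, so under 2% of draws clamp). Replicate
simulation at the default group sizes shows the mean recovered d within
about 0.01 of the target with a per-replicate SD of about 0.033.

## Corpora and distributional-semantic models

`generate_corpus()` builds token documents over four category word lists
plus fillers, with a designed time–valence association controlled by
`association_strength` through two mechanisms. *Themed documents*: with
probability equal to the strength, a document is themed around a covered
category pair (past–negative and/or future–positive) and samples those two
categories at `theme_boost` (default 4) times the baseline rate — partner
words thereby share document and window contexts. *Adjacency*: any covered
time word is followed by a partner-category word with probability equal to
the strength, so at strength 1 every time-word occurrence is accompanied by
its partner category. Both mechanisms are needed because the two model
recipes are sensitive to different statistics: document/window co-occurrence
(LSA, and the pair-count table) versus shared context profiles (HAL, whose
cosine is a second-order similarity — direct adjacency alone inflates vector
norms without creating shared context mass and does not reliably move HAL
cosines). With `direction = "none"` both mechanisms are off and the four
category-pair co-occurrence rates are exchangeable.

`build_lsa()` reduces the word-by-document count matrix by truncated SVD
(vectors are left singular vectors scaled by singular values; optional
log-entropy weighting, off by default since raw counts are the simpler
contract). `build_hal()` counts context words within a window (default 5),
summed over directions, unweighted by default with an optional linear
distance ramp. Tokens are case-folded; there is no stemming. A neural
(word2vec-style) recipe is deliberately not implemented; the recipe slot is
left to the two count-based models. Cosine similarity raises an error on
zero vectors rather than silently returning 0.

`category_anova()` runs the 2 × 2 ANOVA (time × valence) on pair-level
cosines. An important caveat, which the package verifies rather than hides:
pairs sharing a word are positively correlated (a word's idiosyncratic
context profile enters all its pairs), so the pair-level F test is
anticonservative under the null — replicate simulation shows rejection rates
of 0.15–0.35 at α = .05 under `direction = "none"`, and the inflation does
not shrink with corpus size because the word-level intra-class correlation
is structural. The chi-square test on the 2 × 2 pair-count table, by
contrast, is exactly calibrated. Conclusions from pair-level cosine ANOVAs
(in this package or elsewhere) should therefore rest on effect direction
and magnitude, or on word-level aggregation, not on the pair-level p-value.

## Problem sizes used by the test suite

The suite favours a few deep parameterised checks per operation. Replicate
counts and sizes are chosen to keep Monte-Carlo tolerances honest at
desk-scale run times: 200 replicate experiments (12 subjects, 4 items per
category) for null rejection rates, 100 replicates (40 subjects) for
match-effect recovery, 20 replicate surveys at full group sizes (826 + 221)
for the d calibration, and 100 replicate corpora (60 documents × 30 tokens)
for the DSM null checks. Tolerances derived from replicate simulations are
quoted in the tests next to the replication that produced them.

## Known limitations

* The interactive-activation model is qualitative: no noise, no parameter
  fitting, no mapping of steps to milliseconds beyond an affine display
  convenience.
* Permutation inference treats subjects as the only random factor; the
  domain contrast needs item-level modelling on real data (see above).
* The rating generator's integer scale makes the d calibration approximate
  at the third decimal (Sheppard-corrected, clamping-biased).
* The corpus generator produces exchangeable-by-design nulls and
  block-themed associations; real corpora have Zipfian frequencies,
  syntax, and topical structure none of which are modelled.
* The pair-level cosine ANOVA's p-values are anticonservative by
  construction (shared-word correlation); direction and cell means are the
  trustworthy outputs.
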