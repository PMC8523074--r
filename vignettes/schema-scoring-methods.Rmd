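---
title: "Automatic schema scoring of thought records: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic schema scoring of thought records: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schemascore)
```

## The problem

Cognitive therapy works with *thought records*: structured forms on which a
person notes a triggering situation, the emotion it caused, and the
automatic thought behind it. The *downward arrow technique* (DAT) then
iterates on that thought ("and why would that be upsetting?") to surface
the underlying maladaptive *schema* — a core belief about the self, other
people, or the future. Each utterance in the resulting chain can be scored
against nine schema categories (attachment, competence, global
self-evaluation, health, power and control, meta-cognition, other people,
hopelessness, others' views on self) on an ordinal 0–3 scale, where 0 means
the utterance has nothing to do with the schema and 3 that it corresponds
to it completely. Several schemas can be present in one utterance, and an
all-zero vector (no schema) is legal, so the task is *ordinal multi-label
scoring* of short free text.

`schemascore` implements this scoring task end to end — corpus handling,
linguistic preprocessing, utterance representation, distribution-matched
data splitting, three families of scoring models, rank-correlation
evaluation — together with three downstream analyses: whether scoring
accuracy improves with DAT depth, whether schema patterns transfer from
scripted (closed) to real-life (open) thought records, and whether schema
summaries predict mental-health scale scores.

## Utterance representation

Text is preprocessed by lower-casing, normalizing sentence-end marks and
comma spacing, whitespace tokenization, rewriting misspellings and
contractions through small frozen maps, removing numerals (the default
policy; spelling out single digits is available), stripping punctuation,
and removing stop words. The stop-word list and both rewrite maps are
frozen snapshots committed to the package rather than resolved from any
external resource at run time, so tokenization is machine-independent.
Coverage of the maps is deliberately modest: reproducibility is preferred
over dictionary completeness, and all three lists are overridable through
`prep_config()`.

Each in-vocabulary token is mapped to a word vector, the vector is
L2-normalized, and the utterance is represented by the element-wise mean of
its normalized token vectors. By the triangle inequality this
representation always has norm at most 1, with equality only when all
contributing vectors coincide. Out-of-vocabulary tokens are skipped and
counted; an utterance with no in-vocabulary token is represented by the
zero vector, kept, and flagged (`all_oov`), with its cosine similarity to
anything defined as 0. Word vectors can come from a pretrained table in the
standard GLoVE plain-text format (`read_glove_text()`, duplicate tokens
keep the first occurrence) or from the deterministic offline backend
(`offline_embeddings()`), which derives a unit vector from a hash of the
word and a seed. The offline backend carries no distributional knowledge of
English; it gives every word a fixed random direction, which is exactly
what the lexicon-driven synthetic corpus needs and nothing more.

## The synthetic corpus generator

The generator emulates the structure of the study design the package
analyses: each participant completes two interpersonal closed records, two
achievement closed records, and one open record (whose scenario type is
sampled). Record depth is drawn from a distribution concentrated on depths
1–4 (default `c(.25, .30, .25, .12, .05, .03)` over 1–6); records whose
emotion is happiness (probability 0.05) have no DAT chain and therefore
depth 1.

Each participant has a latent propensity $\theta_s \in [0,1]$ per schema,
drawn from per-schema Beta priors. Scores are emitted by a *gated
ordered-logistic* mechanism: with base activation
$a_s = 4\,\theta_s + \text{boost}_s$, a schema with non-positive base
activation is a structural zero at every depth, and otherwise the ordinal
location is $a_s + \gamma\,(d-1)$ with depth gain $\gamma = 0.3$ and
cutpoints $(3.0, 4.2, 5.0)$. The gate is the simplest monotone mechanism
consistent with two requirements: a degenerate configuration (all-zero
propensities, zero boosts) must produce exactly all-zero score vectors,
and the expected score of an active schema must increase with depth —
the synthetic analogue of the DAT converging toward schema language.
Scenario boosts of 2.0 for attachment in interpersonal scenarios and
competence in achievement scenarios create two high-frequency, learnable
schemas; the Beta priors are set so that every schema remains
majority-zero, echoing the heavy zero-dominance of real score tables.
These defaults were fixed once, at design time, and the test suite pins
them.

Utterance text is drawn from a mixture of nine pairwise-disjoint schema
lexicons plus a neutral lexicon, with mixture weights equal to the
utterance's schema scores (neutral weight 2). The lexicons are fixtures
themed on typical schema vocabulary, not claims about English. Because the
lexicons are disjoint and the offline embeddings give each word a stable
random direction, averaged utterance vectors of schema-heavy utterances
cluster, which is what makes the corpus learnable by the scoring models.
What passing tests on this corpus do **not** show: robustness to natural
synonymy, spelling variation, multi-topic sentences, or any other property
of real clinical text. The generator's purpose is to make every pipeline
stage testable offline with known ground truth, not to imitate language.

Participant-level mental-health scale scores (HDAS depression and anxiety,
BDI, and the two cognitive-distortion subscales) are generated as a linear
function of the participant's schema summary counts (see below) plus
Gaussian noise, so the scale regressions have a known planted truth.

## Splitting

The data are split into training (72.25%), validation (12.75%) and test
(15%) sets at the utterance level. Rather than a single random draw, 1000
candidate test sets are drawn uniformly and scored on three distributional
criteria against the full corpus: the nine per-schema nonzero-score
proportions (mean absolute difference), the proportion of utterances from
open records (absolute difference), and the depth histogram binned 1..6+
(total-variation distance). The minimum-deviation candidate wins, ties
keeping the first drawn; the procedure then repeats on the remainder for
the validation set. Set sizes use round-half-away-from-zero, so at
$N = 400$ the sizes are exactly 60/51/289. Sampling is at the utterance
level, so utterances of one record may straddle subsets; a record-level
option is not offered because the analyses pin utterance-level splitting.
The per-schema criterion uses presence (score > 0) proportions by default;
the full 4-level histogram is available behind `schema_criterion =
"histogram"`.

## Scoring models

**kNN.** Cosine similarity between averaged utterance vectors, $k = 4$ for
classification and $k = 5$ for regression (the values selected on the
validation set in the original evaluation). Classification combines the
$k$ neighbours' scores per schema with a conservative mode — the most
frequent score, and the *lowest* of the co-modal ones — and regression
averages them. Similarity ties are broken by training index order, which
makes predictions fully deterministic.

**SVM.** One support-vector machine per schema with an RBF kernel on
features standardized by training moments only; classification treats the
four scores as nominal classes (one-versus-one), regression fits a real
score clipped to $[0, 3]$ (the clipping is a range-sanity extension; raw
fits can leave the scale). Cost and bandwidth stay at the library
conventions (cost 1, $\gamma = 1/d$) and are recorded in the fit object. A
schema whose training scores are constant cannot be fit: its prediction is
that constant and the schema is flagged, surfacing downstream as an
*undefined* correlation — the nan convention.

**Recurrent networks.** An embedding-lookup layer (frozen; initialized
from the embedding table) feeds a bidirectional LSTM of 100 units per
direction whose concatenated final states drive the output head: nine
independent networks with four-way softmax heads (per-schema variant,
categorical cross-entropy) or one network with nine sigmoid outputs
(multi-label variant, elementwise cross-entropy against scores scaled to
$[0,1]$). Training uses minibatches of 32, dropout 0.1 on the recurrent
output, and Adam at its conventional rate ($10^{-3}$); sequences are
padded or truncated to the 95th percentile of training lengths, and an
empty sequence becomes a single null token. Per epoch the validation
metric (mean absolute error for the multi-label head, cross-entropy for
the per-schema heads) is evaluated and the best epoch's weights are kept.
The networks are implemented directly in matrix code — forward pass,
backpropagation through time, Adam — and the gradients are validated
against numerical differentiation in the test suite.

Network training is stochastic by design. The unit of reproducibility is
the *median-of-restarts* protocol: train 30 times (restart $r$ seeded with
`seed + r`), predict the test set with every restart, score each restart
by the mean over schemas of the per-schema Spearman correlation (undefined
schemas excluded), sort ascending, and keep the restart at rank
$\lceil n/2 \rceil$ — the lower middle for even $n$. Restarts whose loss
becomes non-finite are flagged and excluded from selection.

## Evaluation

The headline statistic is the Spearman rank correlation (mid-rank ties,
Pearson on ranks), per schema over the test set, with a seeded percentile
bootstrap over utterance resamples (default 1000, 2.5/97.5 percentiles). A
constant prediction or constant truth makes the correlation undefined;
undefined results are reported as such with no interval, never as 0.
Because the statistic is rank-based, the multi-label network's $[0,1]$
outputs are evaluated raw — no rescaling to 0–3 is performed, and the test
suite asserts invariance to affine transformations.

Per-utterance *scoring accuracy* is the Spearman correlation between the
predicted and manual nine-schema vectors of one utterance; utterances with
a constant truth vector (mostly all-zero, no-schema utterances) have
undefined accuracy and are excluded from the depth analysis with their
count reported.

Inter-rater reliability uses weighted Cohen's kappa on the fixed 0–3 scale,
$\kappa = 1 - \sum w O / \sum w E$, with linear disagreement weights by
default (quadratic available). When both raters use a single identical
category the statistic is undefined and flagged.

## The three downstream analyses

**Depth.** Scoring accuracy is modelled by a three-level linear model:
random intercepts for participants and for records nested in participants,
with depth as the only fixed effect. Both the null and depth models are
fit by maximum likelihood (not REML) so the likelihood-ratio test between
them is valid; the fit uses lme4 with singular-fit warnings tolerated,
since small simulated corpora legitimately produce near-zero variance
components. Calibration is checked by simulation from the same
random-intercept model (`simulate_accuracy_data()`): the type-I error of
the LRT is measured over 200 null replicates of 60 participants each — a
size at which the asymptotic test is well calibrated — and slope recovery
over 100 replicates of 300 participants with a planted 0.05-per-step
effect.

**Transfer.** For each participant, the two closed records matching the
open record's scenario type are identified; the predictor is the mean of
the two per-record maximum scores for a schema, the outcome the open
record's maximum. Nine simple OLS regressions (with intercept) report $b$,
95% CI, $t$, $p$, $F$ and adjusted $R^2$; a zero-variance predictor is
flagged rather than fit. Open-record scenario-type labels are taken from
the corpus table — the package builds no scenario classifier.

**Scales.** Per participant, record and schema, the maximum utterance
score is binarized (3 maps to 1, everything else to 0) and summed over
records, giving a 0–5 summary count. Five OLS models (one per scale, with
intercept — the conventional choice) regress the scale scores on the nine
summary counts simultaneously; significance uses the Bonferroni threshold
$\alpha = 0.05/5 = 0.01$. Standardized slopes come from a z-scored refit.
Collinear summary columns are tolerated (OLS proceeds); the noiseless
planted configuration recovers the generator's weight matrix to machine
precision, which the tests assert at $10^{-8}$.

## Numerical choices and degenerate inputs

* Undefined correlations and kappas propagate as explicit undefined
  values, never silently as zero.
* The all-out-of-vocabulary utterance contract (zero vector, similarity 0,
  flagged) runs through every consumer.
* Split-size rounding is half-away-from-zero; the 15%/12.75%/72.25%
  identity is exact when $N$ is divisible by 400.
* Deviation ties across candidate draws keep the first-drawn candidate.
* kNN similarity ties break by training index; co-modal classification
  scores take the lowest value.
* All randomness flows from explicit integer seeds in the stage
  configurations; identical configurations reproduce bit-identical
  corpora, splits and (per restart) network weights.

## Problem sizes used by the checks

The test suite and the acceptance script size their computations as
follows: the scoring benchmark uses the default 300-participant corpus
(about 3,700 utterances); LRT calibration uses 200 null replicates of 60
participants and 100 recovery replicates of 300 participants; regression
coverage uses 100 replicates at $n = 300$; kappa's null behaviour uses
20,000 paired ratings; network tests use small separable vocabularies with
reduced units and epochs, since their purpose is correctness of the
training machinery rather than benchmark performance.

## Known limitations

* The synthetic corpus is lexicon-driven; results on it bound nothing
  about natural clinical text.
* The offline embedding backend encodes no semantics; with it, model
  quality reflects lexicon separation only. Pretrained vectors can be
  substituted through `read_glove_text()`.
* The recurrent implementation is plain R matrix code: correct and
  reproducible, but not fast; the 30-restart protocol at full size is a
  long computation.
* Ordinal structure is handled by the models only implicitly
  (classification discards order, regression assumes equidistance), as in
  the modelling approach the package follows.
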