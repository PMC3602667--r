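---
title: "Methods: high-sensitivity case identification from free-text EMRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-sensitivity case identification from free-text EMRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casefinder)
```

# The task and its data model

The package targets the second step of the epidemiological case-identification
workflow: a broad keyword query has already retrieved candidate patients from
an EMR database, and the goal is to separate true cases from non-cases with
high sensitivity so that manual validation can be limited to the patients the
classifier keeps.

The unit of labeling is the **patient**. Each patient carries free-text
entries (visit notes, specialist letters) and a binary gold label assigned by
an annotator who reviewed the whole record. Exactly one entry per patient is
the **seen** entry — the evidence entry for positives, a random entry for
negatives. The remaining entries split by label: non-seen entries of negative
patients (**implicit**) are safe additional negative examples, because the
annotator found no evidence anywhere in the record; non-seen entries of
positive patients (**unseen**) have unknown evidence status and are excluded
from training. All entries, of every role, are used at test time, and a
patient is predicted positive iff at least one entry is — the unique
aggregation rule consistent with how gold labels are defined.

# The pipeline

## Assertion filtering

Clinical text is full of negated ("geen hepatitis"), speculative
("waarschijnlijk", trailing "?"), and differential ("cholecystitis of
cholelithiasis") statements. The filter works on sentences demarked by the
terminator set `{. ! ? : ;}`:

1. sentences containing an *alternatives* keyword as a whole token are
   dropped entirely;
2. sentences terminated by `?` are dropped (attributed to the speculation
   rule: a trailing question mark marks the whole statement as tentative);
3. in the remaining sentences, everything after the *first* negation or
   speculation keyword is removed, up to the sentence end. The keyword
   itself is retained: a literal reading of "words between the keyword and
   the sentence end", and retained negation tokens give classifiers a usable
   negative-context feature.

Commas are deliberately not terminators: a clause such as
"cholelithiasis, schrompelnier li?" must count as one sentence so that the
question mark governs the evidence inside it. Ordering matters only in that
whole-sentence removal precedes span truncation, which prevents the span
rule from acting on text that is discarded anyway. The filter is idempotent
and can only remove tokens, two properties the test suite checks on random
text. Keyword matching is on whole lowercase tokens, never substrings
("geenszins" does not trigger "geen"). The shipped lexicons are Dutch
(editable plain-text files under `inst/extdata/lexicons`); the mechanism is
language-agnostic.

Scope resolution, double negation, and dependency parsing are out of scope;
the filter is intentionally the simple keyword device whose failure modes
the error taxonomy measures.

## Featurization

Filtered text is lowercased, split on non-alphanumeric runs, and encoded as
binary presence vectors. Features are screened per training fold by the 2×2
Pearson chi-square statistic (1 df, closed form `n(ad−bc)²/((a+b)(c+d)(a+c)(b+d))`,
no continuity correction) between token presence and example label; tokens
with p < 0.05 (raw, no multiplicity correction) are kept. Degenerate margins
score 0 with p = 1. The screen is a heuristic volume filter, not an
inferential claim, which is why no correction or minimum-count guard is
applied. Document frequency is counted over training *examples* (entries),
the classifier's unit.

One ordering decision deserves a note: the vocabulary is screened on the
assembled training fold *before* under-/over-sampling is applied. Screening
after over-sampling is pathological — duplicated positive rows multiply a
token's positive document count, so arbitrary background tokens of positive
entries pass the screen and the duplication sweep degrades rather than
helps. Sampling therefore reshapes the class balance inside a fixed feature
space.

## Set expansion and modified random sampling

Training sets come in two variants: seen entries only, or seen plus
implicit (set expansion). Two sampling strategies shift the imbalance ratio
(negative/positive examples):

* **Under-sampling** removes `pct`% of the *implicit* entries (expansion
  mode) — every negative patient keeps at least its seen entry — or of the
  seen negative entries (no-expansion mode), which deletes negative
  patients from training. Positives are never removed. Removal counts are
  rounded half away from zero; the printed ratios are insensitive to the
  rounding rule at realistic sizes.
* **Over-sampling** appends 1–10 exact copies of every positive example,
  deterministically.

Ratios are displayed rounded to the nearest integer at ≥ 1 and to one
decimal below 1, the convention that reproduces every published ratio from
the two data-set shapes (42, 16, 1363, 0.5, ...) by pure arithmetic.

## Learners

MyC, the in-package tree, splits ID3-style on the unused feature with the
largest chi-square statistic at each node, stops when a node is pure, no
feature reaches p < 0.05, or no features remain, and labels leaves by
majority with ties toward positive. No feature repeats on a path, bounding
depth by the feature count. Split scores depend only on counts, so training
is order-invariant. The other three families are deliberately thin wrappers
behind a common train/predict contract: a CART tree (rpart, grown deep with
`minsplit = 2`, `cp = 1e-4`, no pruning — the interpretable-tree slot), a
linear-kernel soft-margin SVM with c = 4 (the margin slot), and a small
greedy sequential-covering rule list (the rule-inducer slot). Their internal
algorithms are not this package's contribution; any conforming learner can
back those slots.

## Cost-sensitive meta-learning

MetaCost wraps any base learner: train on `n_resamples` bootstrap samples
(default 10, the conventional bagging count), estimate P(positive|x) for
every training example from the ensemble, relabel each example to the class
minimizing conditional risk Σ_j P(j|x)·cost(i,j), and retrain on the
relabeled data. The false-negative cost is swept over
{1, 10, 25, 50, 100, 200, 400, 800, 1000} with the false-positive cost fixed
at 1. All ensemble members vote on every example (no out-of-bag exclusion),
the simpler documented variant.

One design choice was made against the obvious reading and is worth
defending. With *hard* 0/1 votes and a deterministic, well-separated base
learner, most training examples receive a unanimous vote: P(positive|x) is
exactly 0 for nearly all negatives, and an example at probability 0 can
never be relabeled at any finite cost. The cost sweep would then be inert —
no saturation toward sensitivity 1.0 / specificity 0.0 at prohibitive
costs, which is the documented signature of the procedure. The default
(`vote = "prob"`) therefore averages per-model class-probability estimates
(Laplace-smoothed leaf and rule frequencies, Platt-scaled margins), which
keeps every probability strictly inside (0, 1); with a training set of n
examples the smoothed minimum 1/(n+2) guarantees that a cost of 1000
relabels everything positive for n < 999, reproducing the saturation rows.
Hard voting remains available as `vote = "hard"`. With unit costs, either
variant leaves every correctly-voted example's label unchanged.

Ties everywhere — leaf majorities, risk comparisons — resolve toward the
positive class: the artifact's stated objective is sensitivity-first.

## Evaluation

Cross-validation is at the subject level: patients, not entries, are
partitioned into k = 5 folds (sizes differing by at most one), so no
patient's entries can span train and test. Confusion counts are pooled over
folds (micro-average) — the convention that yields a single
sensitivity/specificity pair per configuration without extra variance
machinery; with balanced folds the difference from fold-averaging is
second-order. Inter-annotator agreement is Cohen's kappa with the
large-sample standard error `sqrt(p_o(1−p_o)/(n(1−p_e)²))` for its 95% CI.

False negatives are assigned to exactly one of four causes by a fixed
cascade: (1) the sidecar marks the gold label itself erroneous; (2) the
evidence token is present before filtering but absent after; (3) the
sidecar marks the surface form a spelling variant; (4) otherwise the
evidence simply was not in the learned model. The order checks the cheapest
certain causes first; the published taxonomy is mutually exclusive but
unordered, so the cascade is this package's convention.

# The synthetic corpus generator

Real corpora of this kind live in access-restricted GP databases, so the
generator is a first-class module: it must produce corpora on which the
pipeline's documented behaviours — filter failure modes, feature-screen
volume reduction, sensitivity/specificity movement under resampling and
cost — are all observable and testable against a known ground truth.

Text is synthetic token sequences, not prose: the pipeline is purely
lexical, so token-level structure suffices and keeps every planted signal
auditable. Each entry is a Zipf-weighted background sentence (vocabulary of
100 tokens, ~12 tokens per entry) that carries a negation/speculation
keyword at rate 0.15 and a trailing question-mark sentence at rate 0.05 in
*both* classes — without this, retained negation keywords would become
spurious positive markers. Positive seen entries add an evidence sentence
(one of five disease tokens; its fixed misspelled variant at rate 0.10;
negated or speculative at rate 0.15, realized half by keyword prefix and
half by `?`-termination, exercising both filter pathways) plus two
disease-context terms from a shared pool of eight (symptoms, organs,
examinations). Non-evidence entries of either class contain a negated
evidence mention at rate 0.10 — the reason such patients matched a broad
query at all — and an unnegated context term at a low circumstantial rate.

The context terms are the load-bearing calibration. They are the only
genuinely *overlapping* features: strongly associated with positives but
present in a small fraction of negative entries. Their leaves are where
class imbalance bites — with full set expansion the negative mass makes
them majority-negative, so negated and misspelled positives (whose evidence
the filter removed or the fold vocabulary lacks) are missed at baseline;
under-sampling, duplication, or a rising false-negative cost flips those
majorities, recovering sensitivity at a measurable specificity price. The
circumstantial rate is set so that the flip happens *inside* the published
sweep grids rather than before or after them, emulating the source data's
regime where baseline sensitivity sat well below 1 and rose under every
imbalance treatment. The background vocabulary size is the other side of
that calibration: the chi-square screen falsely admits about 5% of
background tokens, and when such chance features are plentiful a heavily
duplicated positive set lets trees split mixed leaves apart on them —
memorizing training positives instead of shifting leaf majorities — so the
vocabulary is kept at 100 types, which leaves a handful of chance features
(enough to exercise the screen and the error taxonomy) without drowning
the majority-shift mechanism. Default patient counts are 50 positive /
450 negative (the 500-patient condition used by the trend tests) with a
mean of 6 entries per patient.

Shape presets reproduce the two published data-set skeletons exactly
(hepatobiliary: 656/317 patients, 61,179 unseen / 27,276 implicit entries;
renal: 237/3,751 with 58,022 / 319,204), distributing entry totals evenly
with a randomized remainder; a `scale` argument shrinks all counts
proportionally, since the full renal shape approaches 400,000 entries. The
sidecar records, per patient, the evidence entry, surface form, and
negation/misspelling/label-error flags; label errors (default rate 0) are
realized as speculative-only mentions, matching the published example of an
annotator accepting a "waarschijnlijk" statement.

What the generator does **not** emulate: natural word order and grammar,
entry dates and longitudinal structure, coded fields, annotator
disagreement beyond the single label-error flag, and realistic misspelling
processes (variants are fixed forms, not edit noise). Passing tests on this
corpus therefore demonstrate that the pipeline's machinery behaves as
documented under the assumed lexical structure — not that any particular
sensitivity level would be attained on real clinical text.

# Numerical conventions and problem sizes

* Rounding of sampling counts and display ratios is half-away-from-zero.
* Chi-square computations are in double precision throughout (squared
  integer products overflow 32-bit integers at realistic counts).
* Degenerate training inputs (single-class folds after sampling, empty
  vocabularies) yield a constant majority model with ties toward positive.
* Every random step — generation, folds, sampling draws, bootstraps — is
  reproducible from explicit seeds; fixed-seed generation is bit-identical.
* The test suite runs the trend checks at 500 patients × 10 seeds across
  the three published grids (under-sampling 0–90%, duplications 0–10, the
  nine-step cost grid), the saturation check on a 0.05-scaled renal shape,
  and the exact-count preset check on the full hepatobiliary shape; these
  sizes keep the whole suite in the minutes range on one CPU while leaving
  every qualitative claim testable.

# Known limitations

* The assertion filter truncates to the sentence end from the first
  keyword; intervening conjunctions do not stop the span, and double
  negations are not detected.
* MyC's significance stop can still fragment nearly-pure nodes on sparse
  chance co-occurrences; this is inherent to greedy trees at modest sample
  sizes and is visible as seed-to-seed jitter in the sweep curves.
* Pooled (micro-averaged) metrics slightly favour larger folds when fold
  sizes differ by one patient.
* The kappa interval uses the standard large-sample approximation, which is
  anticonservative for tables with near-empty cells.
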