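---
title: "Rule-based classification of protein indels: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based classification of protein indels: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelrules)
```

This vignette is the package's own account of the science it implements:
the annotation model for non-frameshifting protein indels (NFS-Indels),
the rule-induction algorithm, the parameter-selection procedure, and the
design decisions taken where more than one reasonable convention exists.

## The classification problem

An NFS-Indel inserts or deletes 1–6 whole amino acids (3–18 coding base
pairs — longer events are rare and are rejected by the readers). The task
is two-class: *deleterious* (disease-associated) versus *neutral*. The
model is a set of conjunctive rules over categorical parameters; a
variant is predicted deleterious iff at least one rule covers it. The
rules only characterise the deleterious class, so uncovered variants
default to neutral — the method is deliberately asymmetric, trading
specificity for sensitivity and interpretability.

## Annotation model

Each variant is described by 45 categorical parameters
(`feature_schema()`), computed from a `protein_context()` holding the
reference sequence, per-residue tracks (disorder probability, solvent
accessibility, secondary structure, conserved-residue flags) and
annotated intervals (conserved core blocks, Pfam/Prosite/UniProt/
alignment-derived domains). The tracks are *inputs*: the package does not
predict disorder, accessibility or secondary structure from sequence, and
does not build alignments.

### Physico-chemical codes and semantics

Each amino acid carries four small-integer codes (`aa_property_table`):
volume 1–5, hydrophobicity 0–3, charge −1/0/+1, polarity 0/1. For an
indel, the *total* is the sum of codes over its residues and the
*average* is the total divided by length. Both are mapped to semantic
labels (`very_small` … `very_large`, `hydrophilic` …
`very_hydrophobic`, …): averages are rounded half away from zero to the
nearest code; totals are first divided by the indel length so that they
live on the same per-residue scale (the label set is defined only on
that scale; the raw total is retained for the perturbation computation).
Codes falling outside a scale after rounding are clamped to the nearest
end with a warning. Volume scales are sometimes numbered 0–4 and
sometimes 1–5 in the literature; this package's per-residue table uses
1–5 and assigns labels by rank, lowest code = `very_small`, so the
labels are invariant to the numbering origin.

### Local scopes and perturbation

Three scopes of the reference sequence are compared against the indel
residues (`local_sequences()`), for an indel of length *n*:

* **site** — the *n* residues that take the place of a deletion (the
  residues immediately downstream of the deleted span), or the *n*
  original residues at an insertion position. At the C-terminus, where a
  deletion has no downstream residues, the site falls back to the *n*
  residues upstream.
* **environment** — the *n* flanking residues on *each side* of the
  indel span (2*n* residues). "n flanking amino acids" is ambiguous
  between *n* total and *n* per side; this package uses *n* per side and
  documents it so users can compare conventions.
* **region** — 2*n* flanking residues per side.

All scopes are truncated at the protein termini. The perturbation for a
property and mode is `d = x_s − x_i` (scope summary minus indel summary;
negative means the indel residues carry the larger value), rounded half
away from zero, clamped to ±2 and labelled `two_less` … `two_more`. Two
properties follow by construction and are enforced by tests: `d = 0`
("equal") when the indel residues equal the site string, and
antisymmetry — swapping indel and site residues negates `d`.

### Structural and positional bins

Per-residue tracks are aggregated over the site span by arithmetic mean
(the convention this package fixes for multi-residue indels). Bins, with
the boundary conventions this package fixes (strict inequalities alone
would leave the boundaries unassigned, and a deterministic convention is
required):

* disorder probability P: `structured` (P < 0.4), `semi_disorder`
  (0.4 ≤ P ≤ 0.7 — boundaries to the middle bin), `disorder` (P > 0.7);
* accessibility R: left-closed bins at 30/60/90/120, `fully_buried` …
  `fully_exposed`;
* secondary structure: the states over the site residues plus one
  residue of context per side (the minimal window that can witness a
  transition). All coil → `coil`; coil plus exactly one non-coil state →
  `two` (a transition zone); otherwise the majority non-coil state, ties
  broken toward `strand`, the more drastic disruption;
* relative indel position: span midpoint over protein length, with
  `n_terminal` at ≤ 0.10 and `c_terminal` at ≥ 0.90. For insertions the
  anchor is the gap before the `position` residue (midpoint
  `position − 0.5`); the before-residue convention for insertion
  coordinates is this package's choice, stated rather than inherited.

Conservation and functional flags are closed-interval intersections of
the site span with each interval class.

## Parameter selection

The discriminative power of a parameter is `x = Σᵢ |fnᵢ − fpᵢ|`, the L1
distance between the within-class value distributions (0 to 2). Values
absent from one class contribute with frequency 0 — no smoothing, the
formula taken literally. Association between categorical parameters is
Cramér's V (bias-uncorrected, Pearson chi-square without continuity
correction); V is the standard categorical "correlation" on [0, 1]
compatible with a 0.5–0.9 cutoff grid. Selection is a greedy pass in
descending x (ties by schema order): keep the parameter, drop every
not-yet-processed parameter with V ≥ the cutoff, and finally drop kept
parameters with x below the x-cutoff. The output partitions the input
schema — an invariant asserted on randomized inputs in the tests.
`wrapper_grid()` evaluates cutoff combinations by cross-validated
accuracy and reports train-versus-test accuracy against parameter count
as an over-fitting diagnostic.

## Rule induction

`learn()` is sequential covering: shuffle the positive examples under the
run seed; each still-uncovered positive seeds one `grow_rule()` search;
accepted rules mark their covered positives; stop when all positives are
covered or no seed yields an acceptable rule (at most one iteration per
positive, so termination is guaranteed).

`grow_rule()` specialises to the propositional case of first-order rule
search: because every background predicate here is a single-valued
attribute of the example, the bottom clause reduces to the seed's own
attribute–value pairs, and candidate literals are exactly those pairs.
The search is a beam (width 5 by default) over conjunctions, scored by
`positives − negatives` covered, bounded at 6 literals; a candidate is
acceptable when it covers ≥ `minpos` positives and ≤ `noise` negatives.
Defaults `minpos = 6`, `noise = 0`: zero noise forbids any training false
positive, which makes every rule's training precision exactly 100% — the
package's central invariant, asserted after every `learn()` and
recomputed by `scripts/acceptance.R`.

Numerical/search details worth knowing:

* Every candidate generated is evaluated for acceptability *before* beam
  truncation, and branches are pruned only when their positive coverage
  has already fallen below `minpos` (specialisation can only shrink
  coverage, so such branches are dead). On instances with ≤ 4 candidate
  parameters this makes the search provably exhaustive; the tests exploit
  this by checking `grow_rule()` against brute-force enumeration over all
  seed-true conjunctions on a randomized suite of small datasets.
* Valid states are still extended: with `noise > 0`, specialising an
  already-acceptable rule can raise its score (it may shed more negatives
  than positives).
* Ties are broken deterministically: higher score, then fewer literals,
  then schema order of the literal sequence.
* A rule whose covered positives are a subset of an earlier rule's is
  discarded as redundant, keeping rule sets minimal.
* Beam width 5 and the 6-literal bound are defaults, not dogma; both are
  `run_config()` fields.

## Evaluation

`metrics()` implements the standard confusion-matrix statistics
(accuracy, sensitivity, specificity, precision, NPV, MCC); any statistic
with a zero denominator is `NA`, never silently 0. Percentages render at
two decimals, half away from zero. `cross_validate()` uses *stratified*
fold assignment rather than a plain random split: stratification
preserves the engineered 1:1 class balance in every fold, so no fold can
lose a class by chance. Per-fold rule sets
are learned with fold-derived seeds; the best-accuracy fold's rule set is
retained as the final model. `assess_rules()` ranks rules by precision
then coverage, tabulates precision as a function of the number of rules
covering a record, and counts parameter usage. `chi_square_compare()`
uses the Pearson statistic without Yates correction by default
(configurable); `af_reliability()` bins user-supplied allele frequencies
at 0.1 intervals and correlates bin midpoint with percent predicted
deleterious, excluding empty bins with a notice.

## The synthetic-data generator

`generate_dataset()` emulates a labelled annotation table whose positive
class is generated by known *planted rules*: negatives are rejection-
sampled from a near-uniform background (mild skew toward each
parameter's first value; a hard cap of 10⁴ attempts per record
guarantees termination) until they satisfy no planted rule; positives
are background draws overwritten with one planted rule's literals,
assigned round-robin; optional label noise flips labels after
construction and is recorded in the ground truth. The defaults — 200
positives, 200 negatives, 15 parameters, two planted rules of two and
three literals, no label noise — are the package's standing study
conditions, used unchanged by the test suite and the acceptance script.

`generate_protein_context()` emulates the upstream annotation pipeline:
piecewise-constant disorder/accessibility/secondary-structure tracks
over designated segments (with small within-segment jitter), conserved
positions and domain intervals, plus variants positioned to hit
requested feature combinations.

What the generator does **not** emulate: the parameter marginals,
linkage and disease composition of any real cohort; annotation noise and
disagreement between structure predictors; proteins with missing tracks.
Passing tests therefore demonstrate correctness of the machinery —
planted-rule recovery, the noise-zero precision guarantee, calibration
of every category — not clinical performance on real variants, which
depends entirely on the quality of the upstream annotations supplied.

## Problem sizes and determinism

The test suite runs at desk scale by design: planted datasets of 400
records and 15 parameters for learning and cross-validation (5 seeds),
brute-force oracle suites on ≤ 12-record, ≤ 4-parameter instances, and
single-protein contexts of 60–150 residues. Every stochastic operation
requires an explicit seed (`run_config(seed = )` is mandatory) and all
generators are pure functions of their seed.

## Known limitations

* Prediction is rule-coverage only; there is no score calibration or
  abstention, and the neutral default means sparse rule sets under-call
  deleterious variants.
* The categorical annotation discards within-bin information; boundary
  conventions (disorder 0.4/0.7 to the middle bin, left-closed
  accessibility bins) are choices, not facts of nature.
* The greedy correlation filter depends on the x-ordering; a different
  association measure or significance criterion could keep a different
  parameter subset.
* With `noise = 0` the learner cannot absorb label errors: a single
  mislabelled negative inside a true pattern vetoes the rule. Raising
  `noise` is the intended remedy on noisy cohorts.
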