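---
title: "Methods: atom-pair association rules for GHS acute aquatic toxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: atom-pair association rules for GHS acute aquatic toxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxbasket)
```

## The model

`toxbasket` classifies chemicals into the four GHS-derived acute aquatic
toxicity categories by mining association rules between topological
atom-pair substructures and category labels, treating each chemical as a
market-basket transaction. The method is deliberately semi-quantitative:
with hazard collections of a few dozen compounds, a categorical answer with
an attached conditional probability is defensible where an LC50 regression
is not.

The pipeline is: parse structures into heavy-atom graphs; enumerate
presence/absence atom-pair features; append one GHS category item per
chemical; mine frequent itemsets (Apriori); keep single-category-consequent
rules at the confidence threshold; collapse statistically redundant rules
to minimal toxicophores; classify new structures by best matching rule with
a Tanimoto nearest-neighbour surrogate fallback.

### Atom descriptors and the pi-electron rule

An atom pair is `(descriptor, descriptor, topological distance)` with
descriptor `(element, heavy-neighbour count, pi-electron count)`, distances
being shortest-path bond counts on the heavy-atom graph. Hydrogens are
excluded everywhere and never counted as neighbours. Pi electrons are
counted as

> (incident double bonds) + 2 × (incident triple bonds) + 1 if the atom is
> aromatic, capped at 2,

so an aromatic ring carbon carries 1 pi electron, a carbonyl or nitro
oxygen carries 1, and a nitrile carbon carries 2. This rule was chosen
because it reproduces the conventional descriptor readings for the
motifs that matter in this chemistry (aromatic carbons, carbonyl and nitro
oxygens) with no element-specific tables.

Three normalisations make fingerprints robust to how a structure is drawn:

* **Aromaticity re-perception.** Lowercase-aromatic SMILES is honoured
  directly; kekulized 5- and 6-rings with strictly alternating single and
  double bonds (with the usual N/O/S lone-pair position in 5-rings) are
  converted to aromatic so `C1=CC=CC=C1` and `c1ccccc1` fingerprint
  identically. The perception is conservative: fused or exotic aromatic
  systems written kekulized may stay kekulized, which is acceptable because
  identity of features matters more than chemical completeness here —
  but inputs should prefer aromatic SMILES.
* **Nitro canonicalisation.** `-N(=O)=O` is rewritten to the
  charge-separated form so nitroaromatics — the dominant chemistry in
  acute-toxicity munitions datasets — fingerprint identically however the
  group was drawn. One nitro oxygen carries the pi electron, the other does
  not; the assignment is deterministic (double bond to the lower-indexed
  oxygen).
* **Salt stripping.** Only the largest heavy-atom fragment is kept, ties
  going to the fragment appearing first.

Features are presence/absence, not counts: market-basket transactions are
sets. The feature universe is whatever the input dataset exhibits; no
external fingerprint dictionary is used, and the canonical identity of a
feature is its rendered string
(`"C [2 neighbor(s),1 pi electrons] <-3-> C [2 neighbor(s),1 pi electrons]"`),
not an implementation-specific integer hash.

### GHS discretisation

CAT1 ≤ 1 < CAT2 ≤ 10 < CAT3 ≤ 100 < CAT4, in mg/L (96-h fathead minnow
LC50), with *inclusive upper bounds*. The value exactly 1.0 mg/L is
assigned to CAT1: the official GHS convention uses ≤ 1, and when in doubt
the more hazardous assignment is the conservative one. No unit conversion
is attempted.

### Mining

Apriori is implemented from scratch with level-wise candidate generation
and downward-closure pruning. All supports are exact integer counts over
the transaction total, so

* `confidence = support(lhs ∪ rhs) / support(lhs)` and
  `lift = confidence / support(rhs)` hold to machine precision,
* threshold tests (`support ≥ min_support`, `confidence ≥ min_confidence`)
  are decided on integer arithmetic, immune to floating-point edge cases,
* the miner can be compared *exactly* against exhaustive power-set
  enumeration, which the test suite does on randomised baskets.

Rules are restricted to a single category consequent and category-free
antecedents. Rule identity and all orderings use the rendered feature
strings, making output byte-stable across runs.

**Toxicophore minimisation**: a rule is redundant when the rule set
contains a same-consequent sub-rule (antecedent subset) with identical
support, confidence and lift; `minimize_rule()` returns the smallest such
sub-rule, ties broken lexicographically. Because "identical statistics" is
decided on integer counts, minimisation is exact, transitive and
idempotent.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_confidence` | 0.75 | probability | the conventional alert threshold for this application: a rule is only useful if the category is likely given the substructures |
| `min_support` | 0.05 | fraction of chemicals | at the ~60-chemical scale this means "at least 3 chemicals", low enough to admit rare but high-confidence alerts |
| `max_len` | 5 | antecedent items | published alert rules rarely exceed 4 substructures; bounds the lattice |
| `max_distance` | 15 | bonds | printed alert features rarely reach beyond distance 6; 15 is a generous cap that keeps feature counts bounded for small molecules |
| `min_feature_count` | 1 | chemicals | optional pre-filter; 1 keeps every observed feature |

### Problem sizes used in the analyses

Atom-pair features from a congeneric series are heavily correlated — dozens
of features co-occur in exactly the same chemicals — so the frequent-itemset
lattice grows combinatorially in `max_len`. The bundled analyses (tests,
the acceptance script, the examples) therefore mine with `max_len = 2`:
with planted motifs, one or two atom pairs already identify a toxicophore,
and every additional antecedent item past that is, by construction,
redundant and removed again by minimisation. The package default stays at
5 for real, less redundant datasets; users mining correlated chemistry at
`max_len ≥ 4` should expect runtimes to grow steeply, since equal-support
feature clusters of size *m* alone contribute `choose(m, max_len)`
itemsets.

## Prediction

Among rules whose full antecedent is contained in the query fingerprint the
winner is selected by: highest confidence, then highest lift, then the more
hazardous category (lower category number), then smallest antecedent, then
lexicographic antecedent — a total order, so prediction is deterministic.
The hazard-first tie-break is a deliberate conservative bias: when the
evidence cannot separate two categories, report the worse one.

Queries matching no rule use the surrogate: the **rule-predicted** (not
ground-truth) category of the Tanimoto-nearest training chemical, skipping
training chemicals that have no rule prediction themselves — the surrogate
consumes model output, not labels, so its errors compound the model's
errors honestly rather than leaking ground truth. Ties in distance break
by larger feature intersection, then lexicographic id. Queries with empty
fingerprints (single heavy atoms) are `unclassifiable`: no similarity is
defined.

A consequence worth stating: a rule set with no CAT1/CAT4 rules — typical
when those categories are sparse — can never rule-predict CAT1 or CAT4,
and the evaluation machinery keeps such chemicals visible in the
`unclassified` spill column rather than dropping them.

## Cross-validation

`cross_validate()` uses stratified folds (shuffle within category, deal
round-robin with a carried counter), so fold sizes differ by at most one
and categories spread as evenly as their counts allow — with ~60 skewed
chemicals, unstratified folds would regularly lose a whole category from
training. The fold rate counts, by default, only rule-classified test
chemicals ("the chemicals the model is capable of classifying");
`count_all = TRUE` switches to an all-chemicals denominator including
surrogate predictions. The reported mean is the unweighted mean of defined
fold rates; folds whose training sets yield no rules are excluded with a
warning. The denominator policy is recorded in the result so reported
rates are never ambiguous.

## The synthetic-data generator

`generate_dataset()` emulates the structure of a small acute-fish hazard
collection: a few dozen small organic molecules, skewed category mix
(default 10/30/40/20 % for CAT1–4, CAT3-dominant as in real acute datasets),
LC50 values log-uniform inside the assigned category's band (so they
re-discretise exactly), and specific substructures co-occurring with
specific categories at a controlled conditional probability (`fidelity`).

Design choices:

* **Motifs with disjoint elements.** CAT1 trichloromethyl, CAT2 nitro,
  CAT3 methylthio, CAT4 ethoxy, on pure-hydrocarbon scaffolds. At
  fidelity 1.0 each motif's heteroatom pairs are perfectly associated with
  its category, so the expected mining outcome is known by construction.
* **Congeneric blocks.** Scaffolds are assigned in (category, scaffold)
  cells of several replicate analogues, each cell larger than the
  per-category share of a stratified 5-fold split, and consecutive cells
  cycle scaffolds so every scaffold spans at least two categories. This
  mirrors the analogue-series character of real hazard collections and has
  two provable consequences at fidelity 1.0: every held-out chemical keeps
  an identical analogue in training, and no scaffold-only feature can be
  perfectly pure for a category in any training fold. Together these
  guarantee that every confidence-1.0 rule is category-faithful, hence
  fivefold CV recovers the planted signal exactly — for every seed, not on
  average.
* **Largest-remainder category allocation** (exact counts, testable to ±1)
  rather than multinomial sampling.
* **Determinism.** The dataset is a pure function of the config; the same
  seed gives byte-identical CSV output.

What the generator does *not* emulate: real structure–activity
relationships (LC50 is assigned, not caused by the motif), activity
cliffs, measurement noise in LC50, tautomers, charged species beyond
nitro, or scaffold diversity within a category beyond the block structure.
Passing the planted-recovery tests therefore demonstrates that the
*machinery* — fingerprinting, mining, minimisation, prediction, CV — is
correct, not that the method will achieve any particular accuracy on real
data, where association fidelities are far below 1 and categories overlap
structurally.

## Numerical and degenerate-input choices

* Supports and all threshold decisions are integer-exact; derived
  statistics are exposed as doubles.
* `min_support`/`min_confidence` comparisons use a 1e-9 guard only to
  convert the real-valued thresholds to integer counts, never to relax
  them.
* Single-heavy-atom molecules have empty fingerprints; they are valid
  inputs and come out `unclassifiable`.
* Two empty fingerprints have undefined Tanimoto similarity (error);
  undefined pairs are skipped in nearest-neighbour search.
* Duplicate ids, non-positive or non-numeric LC50s, missing fingerprint
  coverage, `k > n` folds, and empty transaction sets are errors naming
  the offending record.
* Tie-breaks (rule order, nearest-neighbour, fragment selection) are all
  total orders; there is no hidden dependence on hash or insertion order.

## Known limitations

* The SMILES parser covers the organic subset, bracket atoms, rings and
  branches; stereochemistry is discarded, and aromatic perception of
  kekulized input is limited to alternating 5/6-rings. SDF input relies on
  ChemmineR for the format and re-applies the same perception.
* Confidence estimates from ~60 chemicals carry wide implicit confidence
  intervals; the package reports exact sample statistics and leaves
  uncertainty quantification to the user.
* Only single-category consequents and presence/absence features are
  supported; no conviction/leverage measures, no closed/maximal itemset
  mining.
* The default `max_len = 5` can be computationally heavy on strongly
  correlated feature sets (see problem sizes above).
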