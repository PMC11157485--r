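---
title: "Explaining blood-brain-barrier penetration predictions: models, surrogates, and synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining blood-brain-barrier penetration predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bbbalert)
```

`bbbalert` turns a labelled SMILES table into (i) a penetration
classifier, (ii) per-molecule explanations of its predictions, and
(iii) a ranked table of substructures ("alerts") associated with
predicted blood-brain-barrier penetration.  This vignette is the
package's account of the science: the models and their assumptions, the
parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic ground truth does and does not
demonstrate.

## 1. Data curation

Public BBB permeability sets are noisy in three specific, well-known
ways, and `curate()` addresses exactly those:

* **Valence repair.** Some records write quaternary (tetravalent)
  nitrogen without its mandatory +1 formal charge, which strict SMILES
  parsers reject.  Any neutral nitrogen whose bond-order sum is exactly
  four gains the charge; nothing else is touched.  We read "tetravalent"
  as a bond-order sum of four rather than literally four connections, so
  a doubly-bonded three-connection nitrogen is repaired too — the same
  chemistry, one more spelling.  Records that remain valence-invalid or
  unreadable after repair are dropped and counted, never silently.
  OpenBabel (our parser) is deliberately lenient about valence, so the
  package carries its own allowed-valence table (charge-adjusted, with
  hypervalent S/P handled) to decide validity.
* **Protonation-state unification.** Carboxylic acids appear as the
  neutral acid, the anion, or an alkali/halide salt.  The canonical
  structure key is the OpenBabel canonical SMILES of the largest organic
  component after stripping single-atom counter-ions and neutralizing
  carboxylate oxygens — the neutral form, as it should be for most
  structures at physiological pH.  Only these three published rules are
  implemented; tautomer or stereochemistry normalization is out of
  scope.
* **Duplicates and label conflicts.** Records are grouped by canonical
  key.  Consistent groups keep their first occurrence (file order — a
  deterministic choice; nothing in the data privileges any member);
  groups whose members disagree on the label are removed entirely, since
  an automated pipeline cannot adjudicate, e.g., actively transported
  compounds annotated both ways.

The report satisfies `n_output = n_input − unparseable − duplicates −
inconsistent` by construction, and curation is idempotent.  Curation runs
*before* the train/validation split so one structure can never straddle
the split.

## 2. Featurization

Fingerprints are folded binary extended-connectivity (circular)
fingerprints: every atom's environment at radius 0, 1, 2 bond hops is
hashed from (atomic number, heavy degree, implicit H count, formal
charge, aromaticity, ring membership) plus the recursively hashed
neighbour identifiers, and folded modulo 1024.  Radius 2 (the ECFP4
convention) and 1024 bits are the defaults; counts are clipped to
presence/absence because the explainer treats features as categorical.

Two details matter downstream:

* **Environment registry.** Every set bit records the environments
  (center atom, radius, atom set) that produced it.  Environments with
  identical bond sets are merged; a folded bit can still carry several
  distinct environments (fold collision), and attribution credits each
  of them with the full bit weight — the bit-to-substructure map is
  one-to-many by design.
* **Fragment canonicalization.** An environment's fragment is the
  submolecule induced by the atoms within its radius; dangling valence
  becomes implicit hydrogen.  Fully aliphatic fragments are re-canonicalized
  through OpenBabel so identical chemistry merges across molecules;
  fragments containing aromatic atoms can be partial ring systems that
  no longer kekulize, so they keep the package's own deterministic
  (Weisfeiler-Lehman-canonical) SMILES form instead.

The split is a uniform random permutation (80/20 by default), not
stratified — imbalance is handled afterwards by minority oversampling of
the *training* rows only.  `cumulative_explained_variance()` audits the
effective dimensionality of the folded matrix by centered PCA; the
centering choice is ours (raw binary PCA mostly measures bit density).

## 3. Models

The reference backends are tree ensembles via `ranger`: random forest
and extremely-randomized trees, searched over max depth 1–20 and 50–500
trees by randomized draws (default 20) scored with 5-fold
cross-validated ROC-AUC, then refit on all training data.  Probabilities
come from the ensembles' probability machinery; hard labels use the
conventional 0.5 threshold, while the stricter 0.8 threshold is reserved
for choosing which molecules to explain.  ROC-AUC is computed from the
Mann-Whitney rank statistic with average ranks on ties; precision,
recall, F1, accuracy and the Matthews correlation coefficient come
directly from the confusion counts (TN, FP, FN, TP), with 0/0 ratios
defined as 0.  MCC is the preferred single number here because the data
are ~3:1 imbalanced.

A deep residual network backend (`train_residual_network()`) is provided
behind the same `predict_proba()` contract: width-256 pre-activation
residual units (2, 3 or 4 of them), ReLU activations, softmax head,
minibatch SGD with momentum, a `1/(1 + decay·epoch)` learning-rate
schedule and inverted dropout, implemented in plain matrix arithmetic.
Its hyperparameter grid (1728 cells) is sampled randomly rather than
enumerated — full grid search is not desk-scale — and the tree ensembles
remain the reference path: they are faster, more stable at this sample
size, and empirically the stronger penetration classifiers.

`nested_cv()` confines the hyperparameter search (and optional
oversampling) to each outer-training fold, giving the less biased
estimate; outer validation folds are never resampled.

## 4. The local surrogate explainer

The explainer is written from scratch and reproduces the tabular,
all-categorical-features contract: for an instance `x`,

1. draw `n_samples` perturbed rows, each feature independently Bernoulli
   with its *training* frequency (sample 1 is `x` itself);
2. encode agreement `z′ = 1{z = x}` and weight samples by
   `exp(−D²/σ²)` where `D` is the Euclidean distance of `z′` from the
   all-ones vector (√mismatch-count);
3. fit a weighted ridge regression of the model's label-1 probability on
   all `d` features, keep the `K` largest-|coefficient| features, refit
   on that subset; report the refit coefficients, intercept, and
   weighted R² as local fit quality.

Defaults and why: `n_samples = 5000` and ridge penalty 1 are the
documented defaults of the explainer family this reproduces; `σ =
0.75·√d` likewise (stability across σ ∈ {0.5, 0.75, 1}·√d is asserted
by a property test, mirroring the observation that kernel width barely
moves the result); `K = 100` is a conservative cap — empirically fewer
than a dozen features matter per molecule; only the label-1 probability
is regressed (one explained label).  The ridge penalty is switchable to
0, in which the fit is exact weighted least squares — the recovery tests
exploit this: on any fully enumerated design with a linear black box the
surrogate must reproduce the generating coefficients to 1e-8.  The
classic surrogate objective's explicit complexity penalty has no direct
home here; it is realized implicitly by the K-feature selection.

Weights are signed contributions to the penetration probability.  The
sign-sum rule (`classify_by_weight_sums()`) calls a molecule
"penetrating" when positive weight mass exceeds negative mass; an exact
tie falls to "nonpenetrating" (the conservative reading of an
uninformative explanation).

## 5. Attribution

Explanations of correctly-and-confidently predicted penetrants
(probability ≥ 0.8) are filtered at weight ≥ 0.1 — inclusive, so a
weight of exactly 0.1 is kept, and the threshold is configurable.
Filtering happens per explanation *before* aggregation (filter, then
count).  Each retained bit resolves to its environment fragment(s) in
that molecule; each fragment gets +1 occurrence and the full bit weight
(we deliberately do not split a colliding bit's weight among its
fragments — the alternative is defensible but the one-to-many full
credit matches the dictionary semantics of the bit→fragment map, and is
flagged here as a choice).  A retained bit with no environment in its
molecule — possible because the surrogate also weights *absent* features
whose absence is informative — is recorded as an "unmapped bit"
diagnostic rather than credited.  Fragments merge across molecules by
canonical SMILES and are ranked by total weight, ties broken by count
then lexicographic SMILES.  Because explanation output is run-dependent
by nature, the table is always produced per (model, seed).

## 6. Synthetic ground truth

`generate_library()` assembles molecules from ring scaffolds and side
chains, plants an **alert** substructure in a seeded fraction, labels
each molecule 1 exactly when an alert matches (verified by substructure
search, not by construction flags), flips labels with probability ε, and
subsamples to the target size and class balance.  Defaults emulate the
public benchmark's character: 2000 molecules, 76% positives, ε = 0.05.

The generator's structure was designed around three facts about circular
fingerprints that any explainer consumer should know; they are the
reason the defaults look the way they do:

* **Alert geometry.** The planted alert is azetidine (`C1CNC1`) attached
  through an ethyl spacer.  A six-membered ring can never be covered by
  a radius-2 environment, and — less obviously — tree-unfolded
  environment identifiers cannot distinguish 5- from 6-membered ring
  amines at any shared center at radius 2, so for those alerts the
  model's signal lands on bits whose fragments never contain the ring.
  Azetidine's doubly-N-adjacent methylene is the smallest amine-ring
  feature with a *unique* radius-2 identifier, and that environment's
  induced fragment is exactly the full ring: when the pipeline works,
  the attribution table surfaces the alert verbatim.  The spacer keeps
  the alert's environments identical across molecules so they aggregate
  instead of diluting into per-molecule variants.
* **Decoys.** Alert-free molecules receive a counterfactual piperidine
  through the same spacer, and the substituent pool includes acyclic
  nitrogen groups.  Generic nitrogen environments therefore appear in
  both classes and carry no signal; only the alert ring's own geometry
  separates them.  Without decoys the classifier can spread its reliance
  over a dozen redundant nitrogen bits, each individually below the 0.1
  explanation filter — a real phenomenon worth knowing about when
  reading explanations of real models.
* **Label noise and imbalance.** ε = 0.05 keeps the task non-trivial;
  the assembly pool is sized so that both classes can reach the target
  positive fraction after noise.

What passing tests on this library show: the pipeline's plumbing is
correct end to end — curation counts, fingerprint/registry consistency,
train/validation hygiene, surrogate exactness in the unpenalized limit,
and recovery of a planted, concentrated signal through the full
filter-and-aggregate chain.  What they do not show: performance on real
chemistry, where signals are weaker, redundant and confounded, where
substructures overlap, and where the 0.1 filter's yield varies run to
run.  The generator's molecules are also far simpler than drug space (no
stereochemistry, limited functional-group diversity, no
physicochemistry).

## 7. Numerical and procedural choices

* All randomness flows from one global seed through stable per-stage
  derived seeds (a hash of stage name + seed), so any pipeline run is
  bit-for-bit reproducible; per-molecule explanation seeds derive from
  the molecule id.
* The surrogate solves its ridge systems by Cholesky-backed `solve()`
  on the (d+1)² normal equations; a singular system (degenerate
  perturbation sample) is reported with advice to raise `n_samples`
  rather than silently regularized.
* The explained-variance curve is clamped to end at exactly 1 to absorb
  last-ulp drift; its threshold search is a strict first-crossing.
* Ties: ROC-AUC uses average ranks; `top_fragments()` breaks weight ties
  by higher count then lexicographic SMILES; the sign-sum tie falls to
  "nonpenetrating"; duplicate groups keep the first record in file
  order.
* Study problem sizes used by the packaged checks: surrogate exactness
  enumerates all designs up to d = 10; the metric audit uses 200 random
  confusion matrices; separability uses a 500-molecule noise-free
  library; the recovery study runs ten seeded end-to-end pipelines on
  2000-molecule libraries with 4 hyperparameter draws, 8 explained
  molecules and 2000 perturbation samples per explanation — large enough
  for stable behaviour, small enough to run on a laptop in minutes.

## 8. Known limitations

* OpenBabel and RDKit canonicalize differently; canonical keys are
  internally consistent but not interchangeable with other toolkits'.
* Aromatic partial fragments keep a package-canonical (not
  toolkit-canonical) SMILES form and may not re-parse as standalone
  molecules; they are keys and display strings, not structures.
* The Weisfeiler-Lehman canonicalization used for fragment keys is exact
  for all fragments arising at radius ≤ 2 in practice but is, in full
  generality, canonical only up to WL-indistinguishable graphs.
* The residual-network backend is a faithful desk-scale implementation,
  not a performance-tuned deep-learning stack; it exists so the
  explainer can be exercised against a second model family.
* Explanation weights measure the model's local sensitivity, not causal
  chemistry; correlated bits share weight, and a substructure can be
  informative through its absence (surfaced as unmapped-bit
  diagnostics).
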