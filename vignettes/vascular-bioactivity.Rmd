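---
title: "Scoring vascular disruption from HTS potency data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring vascular disruption from HTS potency data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvdc)
```

## The problem

High-throughput screening (HTS) campaigns in toxicology report, for each
chemical-assay pair, a single potency: an AC50 (half-maximal activity
concentration) for biochemical assays or an LEC (lowest effective
concentration) for cell-based readouts, both in micromolar. Pairs with no
detectable activity carry a default of 1 M, stored here as the literal
sentinel `1e6` uM. `pvdc` turns such matrices into a prioritization of
chemicals by their potential to disrupt embryonic blood vessel development
(putative vascular disruptor compounds, pVDCs), and relates that in vitro
prioritization to species-specific developmental outcomes recorded in
prenatal guideline studies on rats and rabbits.

## The vascular bioactivity score

The score operates on a panel of *target features* — named, directional
readouts of genes critical to vasculogenesis/angiogenesis. The default
panel, in order of descending influence, is VEGFR2 down-regulation, TIE2
enzymatic inhibition, CCL2 down-regulation, PAI-1 perturbation (up or
down), CXCL10 up-regulation, and uPAR perturbation; the first two cover
endothelial receptor tyrosine kinase signalling, the middle pair chemokine
signalling, and PAI-1/uPAR the plasminogen-activating system (PAS) that
remodels extracellular matrix during placentation.

Each potency \(c\) (uM) is mapped to a unit score

\[ u(c) = \mathrm{clip}\!\left( \frac{\log_{10}(c_\mathrm{inactive}/c)}
   {\log_{10}(c_\mathrm{inactive}/c_\mathrm{floor})},\ 0,\ 1 \right), \]

with \(c_\mathrm{inactive} = 10^6\) uM (the sentinel, scoring exactly 0)
and \(c_\mathrm{floor} = 10^{-3}\) uM (1 nM; anything at least that potent
saturates at 1). A target feature's score is the maximum (default) or mean
of its assays' unit scores — `max` so that adding inactive assays to a
feature never changes a chemical's score, and so that for an "updown"
feature the more potent direction wins. The vascular bioactivity score is
the weighted sum

\[ \mathrm{VBS} = \sum_t w_t \, s_t, \qquad w = (6, 5, 4, 3, 2, 1) \]

over the ordered panel. The functional form of \(u\) and the integer
weight ladder are this package's own concrete choices for "a weighted sum
of log-transformed potencies with targets in descending influence"; both
are configurable through `vbs_config()`, and no claim is made that the
default reproduces any particular published per-chemical score scale.
Chemicals with VBS at or above the mean over the scored library are
classified pVDC — inclusive, so a chemical sitting exactly at the mean
cutoff is called positive. ToxPi-style profiles display each chemical as a
radial chart whose slice widths are proportional to the weights and whose
slice radii are the target scores normalized by the per-target maximum
across the library.

### Why target-level aggregation

A weighted sum could run over all 23 panel assays or over the 6 target
features. The default aggregates to target level first: it makes the score
invariant to how many redundant assays a platform happens to run for one
readout, which is the property the "adding inactive assays changes
nothing" invariant encodes. Assay-level summation remains available via
`aggregation = "mean"` plus per-assay features in
`build_feature_matrix()`.

## Pathway perturbation scores

Assays map to gene symbols and genes to pathways (GMT gene sets with a
source tag such as GO/KEGG/IPA). A chemical perturbs a pathway only when
it is active against at least five *distinct genes* mapping into the
pathway — gene-level deduplication, since the same gene is often assayed on
several platforms — and the score is then the minimum potency over all its
hits on pathway-mapped assays. AC50- and LEC-measured hits count equally,
both toward the five-gene activity requirement and in the minimum; the
potency semantics of the two measures differ, but both are "lowest
concentration with observed effect" evidence and the source tables mix
them freely. Below the threshold the score is undefined (`NA`), and when
pathway scores enter a feature matrix, undefined means 0 — no evidence of
perturbation — rather than an imputed value.

## Endpoint records and species contrasts

Prenatal endpoint records are (chemical, species, category, LEL) tuples
with a strict controlled vocabulary of 11 aggregated categories seeded
from curated rat/rabbit study tables (`endpoint_vocabulary()`), extensible
by argument. Strictness is deliberate: "skeletal axial" without the colon
is a data error, not a new category. A chemical is developmental-toxicity
positive in a species if it has any record there; by default
"maternal pregnancy loss" counts (pregnancy-related fetal wastage may be
maternally mediated but is still indicative of embryotoxicity), and
`include_maternal = FALSE` restricts to direct embryo/fetal categories.
Species-only positive sets intersect to nothing by construction, and the
negatives for each contrast are the remainder of the universe of chemicals
tested in both species.

## Stepwise LDA signatures

The two-class discriminant is the Fisher direction
\(w = S^{-1}(\mu_1 - \mu_0)\) with pooled within-class covariance \(S\)
ridged by \(10^{-6}\) on the diagonal, and the boundary at the midpoint of
the projected class means (equal priors). Features enter by forward
selection: at each step the candidate maximizing mean held-out balanced
accuracy (BA, the sensitivity/specificity average) over stratified k-folds
is added, ties resolved by lowest column index, stopping when the
improvement is at most `epsilon` (default `1e-6`) or `max_features` is
reached. Fold assignment is a deterministic function of the seed, so
repeated runs with one seed are bit-identical (`stability_check()`
verifies this); across seeds, dispersion of the test BA measures partition
sensitivity. Reported statistics re-evaluate the final feature set on the
same folds: mean training and held-out BA, Mann-Whitney AUC on the pooled
held-out scores, and "best" sensitivity/specificity at the operating point
maximizing Youden's J on those scores (smallest such threshold on ties).

Two caveats are worth stating plainly. Selection and evaluation share the
fold partition (single-level, not nested cross-validation), so the
reported test BA is optimistic — on pure-noise data with dozens of
candidate features it typically lands in the 0.55-0.75 range rather than
at 0.5. The same optimism means that with the tiny default `epsilon` the
selector keeps appending features whose held-out improvement is chance;
the leading selections carry the signal, the trailing ones often do not.
Raising `epsilon` to ~0.01-0.02 prunes most of the trailing noise at the
cost of occasionally stopping one informative feature early.

## The synthetic study generator

`generator_config()` fixes a study shape chosen to mirror a phase-I-like
screen: 309 chemicals by 120 assays, of which 23 assays span the six
vascular target features (4/4/4/4/4/3); 40% of chemicals are planted
actives; hit potencies are log10-uniform on [0.1, 50] uM, matching the
span of the curated reference AC50 table; and every other cell is a false
hit with probability 0.02. Each active belongs to one of two mechanism
groups — PAS-linked or chemokine-linked — always hits both features of its
group, plus 1-4 of the remaining four features (so at least 3 of 6), and
hits each assay of an active feature with probability 0.8 (at least one
guaranteed), reflecting that a chemical perturbing a readout usually
registers on most of that readout's assays. Endpoint generation links
mechanism to species: PAS actives draw rabbit fetal/maternal-loss records
with probability 0.85, chemokine actives draw rat skeletal records with
probability 0.8, and each record's species is flipped with probability
0.05.

What the generator does *not* emulate: assay noise on the potency values
themselves, correlated assay families beyond the planted features,
chemicals active in both mechanism groups, dose-response curve quality,
and maternal pharmacokinetics. Passing recovery tests therefore shows the
pipeline's logic is sound under its own assumptions — planted actives are
ranked above background, and the species contrast points back at the
mechanism assays — not that real screening data would yield signatures of
similar strength.

Problem sizes in the test suite and the acceptance script follow the
generator defaults (10 independent seeds of the 309 x 120 study for the
recovery properties; smaller matrices for per-operation oracles), which
keeps a full run in the tens of seconds on a single core.

## Numerical and degenerate-input conventions

* Potencies must be strictly positive; exactly `1e6` uM is inactive, and a
  value of 999,999 uM is (barely) a hit. Cutoff comparisons are inclusive.
* Identifiers are matched case-insensitively after whitespace collapsing,
  preserving the original spelling in output — pesticide naming is too
  inconsistent for exact matching.
* Mean potency of an empty hit set is `NA`, never 0.
* Matrices round-trip through text with 17 significant digits, so
  write-then-read is bit-exact.
* VBS ranking breaks ties alphabetically by chemical id; stepwise ties go
  to the lowest feature index — both purely for determinism.
* An LDA fit whose pooled covariance stays singular after the ridge
  rejects that feature subset; `stepwise_select()` skips such candidates.
* Keyword and synonym matching is literal (regex metacharacters escaped),
  word-bounded where the term starts/ends with a word character, with
  hyphen/whitespace runs normalized on both sides ("Flk-1" matches
  "Flk 1", but not "Flk1" — distinct tokenizations are distinct synonyms
  and should be listed separately).

## Known limitations

* The VBS scale depends on the weight ladder and floor; only order-based
  statements (ranking, above-mean classification) are comparable across
  configurations.
* Single-level CV optimism, discussed above; treat reported test BA as an
  upper estimate and the feature list's tail as tentative.
* Literature co-occurrence ranking is a counting utility on user-supplied
  corpora; it performs no retrieval, entity recognition, or curation.
* The endpoint module models categorical presence/absence; LEL doses are
  carried but not modeled (no LOAEL/benchmark-dose machinery).
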