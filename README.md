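# pvdc — vascular bioactivity scoring and toxicity signatures from HTS data

`pvdc` is for computational toxicologists who have chemical-by-assay
potency tables from high-throughput screening (AC50 or LEC values in
micromolar, with inactive pairs encoded as 1 M = `1e6` µM) and want to
prioritize chemicals by their potential to disrupt embryonic blood vessel
development — putative vascular disruptor compounds (pVDCs) — and to relate
that in vitro ranking to prenatal developmental outcomes in rats and
rabbits.

## What it computes

**Vascular bioactivity score (VBS).** Each potency *c* becomes a unit
score

    u(c) = clip( log10(c_inactive / c) / log10(c_inactive / c_floor), 0, 1 )

with `c_inactive = 1e6` µM (scores 0) and `c_floor = 1e-3` µM (saturates
at 1). Scores aggregate per target feature (max over its assays) and the
VBS is the weighted sum over the ordered panel — by default VEGFR2 down,
TIE2 inhibition, CCL2 down, PAI-1 up/down, CXCL10 up, uPAR up/down with
weights 6…1 (descending influence). Chemicals at or above the mean VBS
are classified pVDC, and ToxPi-style radial profiles visualize the
ranking (slice width ∝ weight, radius = normalized target score).

**Pathway perturbation scores.** For each (chemical, pathway): defined
only when the chemical is active against ≥ 5 distinct genes whose assays
map into the pathway, and then equal to the minimum potency over those
pathway hits.

**Species-specific endpoint sets.** Prenatal endpoint records
(chemical, species, category, LEL) under a strict controlled vocabulary
are aggregated into rabbit-only / rat-only positive sets and phenotype
prevalence counts.

**Stepwise LDA signatures.** Fisher discriminant (`w = S⁻¹(μ₁ − μ₀)`,
ridged pooled covariance) with forward feature selection maximizing mean
held-out balanced accuracy (BA) over stratified 5-fold CV; reports train/
test BA, best sensitivity/specificity (Youden point), and Mann-Whitney
AUC. Deterministic given the seed.

**Synthetic studies.** `generator_config()` / `generate_hts()` /
`generate_endpoints()` build a phase-I-like screen (309 × 120, 23
vascular assays, 40% planted actives in two mechanism groups linked to
species-specific endpoints) so the whole pipeline is testable end to end.

## Worked example

Hit summary of the packaged reference table (14 chemicals screened
against seven biochemical vascular targets), restricted to the 11
pVDC-classified rows:

```r
library(pvdc)
m  <- read_potency_matrix(pvdc_extdata("vascular_targets_ac50.csv"))
vt <- read.csv(pvdc_extdata("vascular_targets_vbs.csv"))
filter_hits(subset_chemicals(m, vt$chemical[vt$group == "pvdc"]), threshold = 20)
#> <hit_summary> 42 hits, mean potency 15.97714 uM, 30 at or below 20 uM
```

The 11 pVDCs carry 42 AC50 values averaging ~16 µM, 30 of them at or
below 20 µM — i.e. the chemicals flagged by the score are both broadly
and potently active on vascular targets (the three non-pVDC rows yield 4
values averaging ~28 µM, one ≤ 20 µM).

Scoring the antiangiogenic reference compounds against the default
six-target panel, with the curated reference cutoff of 1.48:

```r
rc  <- read_potency_matrix(pvdc_extdata("reference_compounds_activity.csv"))
ann <- read_annotations(pvdc_extdata("reference_compounds_annotations.csv"))
vbs_scores(rc, ann, cutoff = 1.48)
#>      chemical VEGFR2_down TIE2_inhib CCL2_down PAI1_updown CXCL10_up
#> 1     5HPP-33       0.522          0     0.689       0.522         0
#> 2 Thalidomide       0.000          0     0.689       0.489         0
#>   uPAR_updown  vbs is_pvdc rank
#> 1       0.656 8.11    TRUE    1
#> 2       0.622 4.85    TRUE    2
```

Both classify as pVDCs, and the analog designed to be antiangiogenic
(5HPP-33) outranks thalidomide, as its broader and more potent activity
profile dictates.

End-to-end on synthetic data — generate a screen with planted actives,
score it, classify against the mean:

```r
hts <- generate_hts(generator_config(seed = 1))
sc  <- vbs_scores(hts$matrix, hts$annotations)
mean(hts$active %in% sc$chemical[sc$is_pvdc])                      # sensitivity
#> [1] 0.96
mean(!setdiff(sc$chemical, hts$active) %in% sc$chemical[sc$is_pvdc])  # specificity
#> [1] 0.973
```

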