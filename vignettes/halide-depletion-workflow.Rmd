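---
title: "The halide-depletion discovery workflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The halide-depletion discovery workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halomet)
```

## The scientific problem

Halogenases require halide anions as substrates. Removing chloride (and
bromide) from a defined growth medium therefore starves halogenation-dependent
biosynthesis, and any metabolite whose abundance collapses in halide-depleted
cultures is a candidate halogenated natural product — or, when the molecule
itself carries no halogen, a candidate product of *cryptic* halogenation, in
which a transient halogenated intermediate is consumed during biosynthesis.
`halomet` implements the desk side of that experiment: paired-condition
differential statistics on LC–MS feature tables, chlorine detection from MS1
isotope envelopes, exact-mass formula assignment, modified-cosine molecular
networking of MS/MS spectra, and deconvolution of stable-isotope feeding
envelopes. A seeded synthetic-data generator emulates the structure of such an
experiment so every stage is testable without instrument data.

## Differential statistics

Features are aligned across runs by a greedy agglomerative join: all run
features are sorted by intensity descending, and each lands on the nearest
existing consensus row within both tolerances (m/z distance prioritized) whose
column for that run is still free, else opens a new row. The m/z tolerance is
0.01 Th or 20 ppm, whichever is larger at that m/z; the retention-time
tolerance defaults to 0.2 min (a package choice — the joining rt window is not
dictated by the acquisition method). The consensus coordinates are those of
the most intense (seeding) member, which guarantees every member lies within
the tolerances of the consensus.

Missing or sub-noise intensities are replaced by a pseudocount floor of 100
counts before any statistic is computed. The floor bounds otherwise-infinite
fold changes for features undetected in one condition; the "100 counts" value
is instrument-specific and configurable. Fold changes are ratios of
arithmetic condition means, stored as a magnitude ≥ 1 plus a direction enum
(`depleted_without_halide` marks the candidates of interest); a signed export
(negative = depleted without halide) mirrors the common supplementary-table
convention. P values come from a two-tailed two-sample Student's *t*-test on
raw (untransformed) intensities with pooled variance and
df = n₁ + n₂ − 2; a Welch variant sits behind a flag. Whether such tests are
better run on log intensities is a fair question; raw intensities are the
default here because that is the common convention of MZmine-style
comparative-metabolomics workflows, and the report header records the
choice. No multiple-testing
correction is applied by default (raw P values are reported);
Benjamini–Hochberg is available via `p.adjust` on the output. Features with
zero variance in both groups and equal means (typically both conditions fully
at the floor) are degenerate: t = 0, p = 1, direction `unchanged`.

Co-eluting artifact features are grouped by transitive closure over pairwise
m/z differences that match a small delta table (NH₄⁺/H⁺ = 17.02655 Da,
Na⁺/H⁺ = 21.98194 Da, Na⁺/NH₄⁺ = 4.95540 Da, water loss = 18.01056 Da) within
the MS1 tolerance and an rt co-elution window (default 0.05 min). Each group
designates a parent: the member interpretable as [M+H]⁺ (having an
adduct partner above it), else the most intense member.

## Mass and isotope arithmetic

One fixed isotope table (C, H, D, N, O, S, Cl, Na; CODATA/AME reference
values) ships as a plain-text file, and its version string is embedded in
every report. Ionic m/z values include the electron-mass correction (a proton
is 1.007276 Da, not the hydrogen atom mass); this matters in the fourth
decimal, e.g. [M+H]⁺ of C₂₈H₅₅O₈Cl is 555.3658 only with the correction.
Printed m/z values are rounded half-even to four decimals.

Isotope envelopes are computed by convolving per-element isotope
distributions (binary exponentiation over atom counts) and aggregating
isotopologues by integer nominal-mass offset; the centroid m/z of an offset is
the abundance-weighted mean of its isotopologues. This deliberately does not
resolve fine structure (¹³C₂ vs ³⁷Cl within M+2), matching centroided Q-TOF
MS1 data. Abundances below 10⁻⁴ of the base peak are pruned (configurable;
the brute-force oracle tests run unpruned).

Chlorine detection uses the M+2/M+0 ratio: one chlorine contributes 0.320
(³⁷Cl/³⁵Cl = 0.2424/0.7576), with carbon (¹³C pairs) and ¹⁸O adding a smaller,
size-dependent amount. The acceptance windows — 0.20–0.50 for one Cl,
0.50–0.85 for two, gated on a plausible M+1/M+0 ≤ 0.6 — are a package design
choice: the underlying experimental criterion ("intensity of the M+2
isotopologue") is qualitative, so the windows are explicit, configurable, and
validated on simulated envelopes (sensitivity and specificity ≥ 0.95 on
random 300–900 Da formulas). The windows fail gracefully: very large
carbon-only molecules (≈C₅₅+) approach the lower window edge from below, which
bounds specificity rather than sensitivity.

Formula decomposition enumerates all formulas within per-element bounds
(default C 0–60, H 0–120, N 0–5, O 0–15, S 0–3, Cl 0–3, Na 0–1 — sized for
lipid-scale metabolites) whose ionic m/z under a candidate adduct falls within
the ppm tolerance, then filters on ring-plus-double-bond equivalents:
RDBE = C − (monovalent)/2 + N/2 + 1 must be integral (even-electron adduct
ions) and lie in [−0.5, 40]. All monovalent elements (H, D, Cl, Na) count in
the monovalent term; counting Na as monovalent rather than ignoring it keeps
sodium-bearing candidates from being spuriously rejected by the integrality
check. Candidates sort by |ppm error|, ties by fewer heteroatoms. When the
MS1 envelope flags chlorine, the enumeration is constrained to Cl ≥ 1.

## Molecular networking

Before scoring, each MS/MS spectrum is filtered: peaks within ±17 Th of the
precursor are removed (the exclusion zone interpretation — this window
removes the surviving precursor and its isotope/adduct artifacts), and a peak
survives only if it ranks among the 6 most intense within the ±50 Th window
centred on itself (ties broken toward lower m/z; the filter is idempotent).

The modified cosine treats peaks in two spectra as matchable either directly
(|Δm/z| ≤ 0.02 Th) or after shifting by the precursor-mass difference
(neutral-loss match). Intensities are square-root transformed and each
spectrum's weight vector is L2-normalized (configurable to raw intensities);
a greedy one-to-one matching — candidate pairs sorted by weight product
descending, each peak used at most once, a pair counted once even if it
matches both ways — accumulates the score. Greedy assignment is the common
practice in spectral networking; the test suite verifies it against an
exhaustive enumeration over all one-to-one matchings on hundreds of small
random spectra. Fragment-matched and loss-matched pairs are pooled into a
single matched-pair count (one matching, mixed pair types). An edge requires
cosine ≥ 0.60 *and* ≥ 4 matched pairs. No top-K edge pruning or
component-size capping is applied by default; both exist behind flags in
comparable tools but change results in ways that are hard to audit. Each
feature is represented by at most one spectrum: the one with the closest
precursor m/z, ties broken by total ion current.

## Label-incorporation fitting

A feeding experiment with a deuterated precursor yields an MS1 envelope that
is a mixture of the unlabeled metabolite and labeled species retaining
`n_label − n_lost` deuteriums (e.g. one D displaced when chlorination occurs
at a labeled carbon, shifting the labeled envelope from M+2 to M+1). The
observed envelope, normalized to M+0 = 1 (base peak when M+0 is empty), is
fitted on a common nominal-offset grid — default M+0..M+5, widened
automatically to cover every species — as a non-negative mixture of
theoretical envelopes, each normalized to unit total abundance so fractions
are molar shares. The solver is non-negative least squares
(`pracma::lsqnonneg`) followed by sum-to-one renormalization; on noiseless
mixtures it is exact to 10⁻⁶ and the tests verify parameter recovery to
±0.05 under 2% multiplicative noise. Label atoms are modeled at 99% isotopic
purity by default (commercial labels are 98–99 atom-% D); the remainder
behaves as natural hydrogen. Competing retention hypotheses
(n_lost = 0, 1, …) are each fitted as a two-species mixture and ranked by
residual; losing *every* label is indistinguishable from no incorporation and
is therefore not a separate hypothesis, and a best fit with essentially no
labeled fraction (< 0.02) is flagged inconclusive.

## What the synthetic generator emulates — and what it does not

The generator realizes a 3-vs-3 replicate design (the standard small
biological-replicate setting for this kind of screen). Defaults, chosen once
as representative of biological LC–MS replicates and held fixed:

| parameter | default | meaning |
|---|---|---|
| replicate CV | 0.2 | log-normal multiplicative intensity noise |
| detection limit | 500 counts | hard censoring (feature absent from run) |
| noise floor | 100 counts | gap-fill pseudocount applied downstream |
| envelope noise | 2% | multiplicative noise on MS1 isotopologue abundances |
| m/z, rt jitter | 0.002 Th, 0.02 min | per-run feature coordinate noise |
| MS/MS jitter | 0.005 Th, 10% | fragment m/z and intensity noise |

Replicate intensities are drawn log-normal with arithmetic mean equal to the
planted condition mean (base abundance, divided by the planted fold in the
depleted condition), so ratio-of-means estimators are directly comparable to
the planted folds. The demonstration manifest plants one 8-member
chlorinated, halide-dependent glycolipid family (folds 87.5, 421.1 and 607.0
among them — magnitudes typical of strong halide-responsive metabolites —
with formulas such as C₂₈H₅₅O₈Cl and C₄₆H₈₉O₉Cl so demo outputs look like
real lipid chemistry), one halide-independent family, and 200 background
features. Family members share 5 template fragments and 2 sugar-like neutral
losses, which guarantees ≥ 4 matched pairs and a high cosine under jitter;
three members co-emit a secondary adduct at the same retention time to
exercise artifact grouping. MS/MS metadata carries the acquisition
collision-energy convention CE = 10 + 0.02 × m/z.

The generator is deliberately limited: fragment *templates*, not
fragmentation chemistry; no retention-time drift beyond per-run jitter; no
profile-mode chromatograms, co-eluting isomers, or matrix ionization effects;
background features carry no isotope envelopes. Passing tests therefore
demonstrate that the pipeline's statistics, flags and graph construction are
correct under the stated noise model — not that the workflow is robust to
every failure mode of real instrument data (chimeric MS/MS spectra,
in-source decay beyond the delta table, charge states > 2).

## Numerical choices and degenerate inputs

* Tie-breaks are deterministic everywhere (intensity then m/z order in peak
  filtering; |ppm| then heteroatom count in decomposition; stable sort orders
  in joining and reporting), so a pipeline re-run on identical inputs is
  byte-identical.
* Empty spectra, empty networks, singleton components, features absent from
  every depleted run, and all-floor features all pass through with defined
  results rather than errors; genuinely malformed inputs (unknown element or
  adduct, missing CSV columns, duplicate ids, < 2 replicates) fail fast with
  the offending token named.
* Test problem sizes: envelope oracle on ≤ 6-atom formulas (exhaustive
  enumeration is exact there), cosine oracle on 200 pairs of ≤ 8-peak
  spectra, null type-I error on 2000 features, fold-change recovery averaged
  over 10 simulated experiments (a single 3-vs-3 ratio of means at CV 0.2
  carries ~16% sampling error, so the averaged estimate is what isolates
  estimator bias from replicate noise), and the full demonstration manifest
  end to end. These sizes make the checks sharp while keeping the whole
  suite fast.

## Known limitations

Chlorine counting saturates at 2 (bromine, with its near-unity M+2 isotope
ratio, is not modeled); charge states above 2 are out of scope; the artifact
delta table is not a general de-adducting engine; and formula decomposition
is exhaustive within bounds rather than heuristic, so very wide user bounds
cost time exponentially. The fold-change estimator is a plain ratio of means:
with 3 replicates at CV 0.2 individual estimates scatter ~16%, which is
inherent to the design, not to the implementation.
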