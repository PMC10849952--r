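# halomet

Comparative metabolomics for **halide-depletion** natural-product discovery.

Halogenases need halide anions as substrates. Grow a microbe in parallel
halide-replete and halide-depleted media, and any LC–MS feature whose
abundance collapses without halide is a candidate halogenated natural
product — or, if the molecule itself carries no halogen, a candidate product
of *cryptic* halogenation (a transiently halogenated biosynthetic
intermediate). `halomet` is the data-analysis side of that experiment, for
natural-product and metabolomics researchers who have centroided per-run
feature lists and MS/MS peak lists and want a reproducible, auditable
discovery read-out.

## What it computes

* **Differential feature statistics.** Cross-run feature joining (m/z
  tolerance 0.01 Th or 20 ppm), gap filling with a 100-count pseudocount
  floor, fold changes as ratios of condition means
  (FC = max(m̄ᵣ/m̄ᵈ, m̄ᵈ/m̄ᵣ) with a direction flag), and two-tailed
  two-sample Student's *t*-tests (pooled variance, df = n₁+n₂−2) on raw
  intensities — the tabular twin of the classic volcano plot. Co-eluting
  adduct/in-source artifacts ([M+H]⁺/[M+NH₄]⁺/[M+Na]⁺/−H₂O deltas) are
  grouped to a parent ion.
* **Chlorine detection from MS1 envelopes.** Isotope patterns are simulated
  by convolving per-element isotope distributions, aggregated by nominal
  mass offset; one chlorine gives M+2/M+0 ≈ 0.32, and observed envelopes
  are flagged via configurable acceptance windows.
* **Exact-mass formula assignment.** Bounded exhaustive decomposition with
  electron-corrected adduct masses and an RDBE
  (C − monovalent/2 + N/2 + 1) plausibility filter. Reproduces printed
  "calcd." values: [M+H]⁺ of C₂₈H₅₅O₈Cl = 555.3658.
* **Molecular networking.** Modified-cosine similarity over √intensity
  peak vectors, matching fragments directly or as neutral losses after
  precursor-mass shifting, with the standard spectrum filters (±17 Th
  precursor exclusion, top-6-in-±50-Th rank filter); edges require
  cosine ≥ 0.60 and ≥ 4 matched pairs. GraphML export.
* **Stable-isotope label fitting.** Observed feeding envelopes fitted as
  non-negative mixtures of theoretical labeled/unlabeled envelopes
  (NNLS + simplex renormalization); label-retention hypotheses (how many
  deuteriums survive incorporation) ranked by residual.
* **A seeded synthetic experiment generator** planting known fold changes,
  chlorinated formulas, compound families with shared fragments/neutral
  losses, co-eluting artifacts and detection-limit censoring — so the whole
  pipeline is testable without instrument data.

## Worked example

```r
library(halomet)

ex  <- simulate_experiment(demo_manifest(seed = 1))   # 3 vs 3 replicates
rep <- run_pipeline(ex$runs, ex$spectra, ex$envelopes)
rep
#> <discovery report>
#>   input_run_features     1292
#>   joined_features        217
#>   gap_filled_cells       10
#>   tested_features        217
#>   artifact_groups        215
#>   chlorinated_features   8
#>   formula_assigned       18
#>   network_edges          38
#>   network_components     2
#>   ranked_candidates      99
#> top candidates (depleted without halide):
#>  feature_id    mz    rt fold_change   p_value chlorinated ...
#>       F0081 458.5 16.83      4710.6 0.1315416       FALSE
#>       F0114 553.3 12.91       542.9 0.0025416        TRUE
#>       F0211 866.7 18.95       502.4 0.0014820        TRUE
#>       F0183 782.6 16.31       445.2 0.0003814        TRUE
#>       F0201 838.7 18.19       442.1 0.0001067        TRUE

head(rep$components[, c("rank", "n_members", "n_depleted",
                        "n_chlorinated", "max_depletion_fold")], 2)
#>   rank n_members n_depleted n_chlorinated max_depletion_fold
#> 1    1         8          8             8         542.913951
#> 2    2         5          1             0           1.277361
```

Reading this: the generator planted an 8-member chlorinated glycolipid
family with large depletion folds. The pipeline recovers it as the
top-ranked connected component — 8 members, all depleted without halide,
all chlorine-flagged — while the planted halide-independent family (rank 2)
shows no depletion and no chlorine. The candidate list is sorted by
fold-change magnitude among depleted-direction features; note the top row, a
high-fold but non-significant singleton (p = 0.13) from a rare feature-split
at the join tolerance — exactly the kind of artifact the P value, chlorine
flag and network context are there to filter. Estimated folds (542.9, 502.4,
445.2, …) scatter around the planted values (607.0, 500, 421.1, …) with the
~16% sampling error inherent to a 3-replicate ratio of means.

A thin CLI wraps the same functions
(`system.file("cli", "halomet", package = "halomet")`) with subcommands
`simulate`, `join`, `stats`, `clscan`, `formulas`, `network`, `labelfit`,
`report`, `run-all`.

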