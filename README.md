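# cytoglia

Flow-cytometry profiling of microglial activation after experimental
traumatic brain injury (controlled cortical impact, CCI) in the rat — from
raw event tables to gated microglia, absolute counts, differential marker
statistics, correlation rewiring, classifier-based discrimination and tSNE
maps.

## Who this is for

Neuroimmunology and cytometry groups comparing injured vs sham brain
hemispheres with a conventional multicolor panel: microglia identified as
CD45⁺CD11b/c⁺P2y12⁺ single live cells (P2y12 separates resident microglia
from infiltrating monocytes/macrophages), activation state read from
pro-inflammatory (M1: CD32, CD86) and anti-inflammatory (M2: CD200R, RT1B,
CD163) surface markers, and Cyto-Cal-style counting beads for absolute
quantification. Because raw instrument files for such studies are rarely
public, the package includes a synthetic-cohort generator with a per-event
ground-truth manifest, so the entire pipeline is testable and every claim is
checked against known truth.

## The statistical core

* **Gating**: a rooted tree of geometric gates (rectangle, polygon,
  threshold, FSC-H/FSC-A ratio band) with strict-`>` positivity, even-odd
  polygon membership, valley-seeking viability thresholds, and per-node
  population tables. Child populations are provably nested in their parents.
* **Quantification**: `cells/mg = events × (beads_added / bead_events) /
  tissue_mass`, and fold change of CCI-ipsilateral against the mean of the
  other conditions.
* **Per-marker screen**: Mann–Whitney U (midranks; exact enumeration for
  small untied samples, tie/continuity-corrected normal approximation
  otherwise) on pooled microglia events, Benjamini–Hochberg step-up FDR at
  0.05 per comparison family, directions from median MFIs; QQ curves with
  median-shift and signed-area summaries.
* **Differential correlation**: Pearson correlations per marker pair,
  Cohen's q = |atanh ρ₁ − atanh ρ₂|, one-sided two-sample Fisher-z test
  z = (atanh ρ₁ − atanh ρ₂)/√(1/(n₁−3) + 1/(n₂−3)), BH FDR 0.01, and the
  fraction of pairs significantly *higher* after injury.
* **Discrimination**: stratified 10-fold CV × 10 runs for ridge logistic
  regression, random forest and RBF-SVM; AUC by the rank (Mann–Whitney)
  formula; standardized-coefficient/permutation feature contributions;
  per-cell logistic propensity scores.
* **Embedding**: seeded tSNE on markers only (never scatter), with binned
  density and mean-intensity maps.

## Worked example

```r
library(cytoglia)

cfg <- default_config(seed = 7)
cfg$input$design$n_events  <- 5000   # cell events per sample
cfg$input$design$beads_added <- 2000
cfg$classify <- list(classifiers = "logistic", k = 10, runs = 5,
                     n_per_class = 1000, hemispheres = "ipsilateral")
cfg$embedding$enabled <- FALSE

report <- run_pipeline(cfg)
print(report)
#> <cg_report> seed 7 config 37597c4292a00d11df083849a0caacbe
#>   microglia fold change (CCI ipsi vs others): 16.30
#>   markers FDR-flagged: 22 of 30
#>   significantly higher correlation fractions: M1/ipsil 60%, M1/contr 0%, M2/ipsil 67%, M2/contr 7%
#>   best classifier: logistic M2/ipsilateral AUC 0.785 +- 0.0015
```

The injured ipsilateral hemisphere carries ~16× more microglia per mg than
the average of the other three conditions, most parameters shift
significantly, roughly 60% of marker correlations are significantly higher
than sham on the injured side (vs ~0–7% contralaterally), and a logistic
classifier separates injured from sham microglia with AUC ≈ 0.79 on this
5,000-event run (≈ 0.80–0.86 at the full 10,000-event design).

Per-marker detail for the M2 panel, ipsilateral comparison:

```r
scr <- report$screen
m2 <- scr[scr$panel == "M2" & scr$hemisphere == "ipsilateral",
          c("parameter", "p_adjusted", "fdr_significant", "direction")]
print(as.data.frame(m2), digits = 3)
#>   parameter p_adjusted fdr_significant direction
#> 1     FSC_A  1.49e-226            TRUE        up
#> 2     SSC_A  1.64e-130            TRUE        up
#> 3      CD45   5.60e-40            TRUE        up
#> 4    CD11bc   3.10e-20            TRUE        up
#> 5     P2y12   3.70e-42            TRUE      down
#> 6    CD200R   1.33e-02            TRUE        up
#> 7      RT1B   1.38e-15            TRUE      down
#> 8     CD163   2.07e-26            TRUE        up
```

Cells grow bigger and more granular; CD45 and CD11b/c rise while P2y12 falls
(activation); CD163 rises while RT1B falls. CD200R carries no injected
effect — its borderline flag here is the pseudoreplication of event-pooled
testing picking up between-animal variation, which is exactly why the screen
also has an animal-level mode (`marker_screen(cohort, unit = "animal")`) and
why null calibration is assessed on exchangeable-event cohorts; see the
methods vignette (`vignettes/microglia-cytometry.Rmd`).

Each stage is equally usable on its own (`simulate_cohort()`,
`read_events()` for FCS/CSV, `apply_compensation()`,
`transform_intensities()`, `gate_cohort()`, `marker_screen()`,
`differential_correlation_screen()`, `crossval_discriminate()`,
`tsne_embed()`), and results have `autoplot()`/`tidy()`/`glance()` methods.

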