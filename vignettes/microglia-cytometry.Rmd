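---
title: "Profiling microglial activation by flow cytometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling microglial activation by flow cytometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoglia)
library(dplyr)
```

## The analysis problem

After a focal traumatic brain injury (controlled cortical impact, CCI),
resident microglia activate within hours: they grow larger and more granular,
expand in number, and remodel their surface-marker profile. Multicolor flow
cytometry can quantify this on tens of thousands of cells per hemisphere, but
the raw event stream mixes debris, cell aggregates, dead cells, infiltrating
myeloid cells and counting beads with the microglia of interest. `cytoglia`
implements the complete computational path from the event stream to the
biology:

1. **Hierarchical gating** isolates single live CD45^+^CD11b/c^+^P2y12^+^
   cells. P2y12 is the load-bearing marker: it is expressed by CNS-resident
   microglia but not by infiltrating monocytes/macrophages, which share CD45
   and CD11b/c.
2. **Bead-based absolute quantification** converts gated event counts into
   cells per mg of tissue via beads spiked at known quantity.
3. **Per-marker screening** compares injured against sham event
   distributions (Mann–Whitney U, Benjamini–Hochberg FDR 0.05) for scatter
   parameters and activation markers (M1 panel: CD32, CD86; M2 panel:
   CD200R, RT1B, CD163), with QQ curves summarising distribution shifts.
4. **Differential correlation** asks whether marker pairs co-vary more
   tightly after injury (Fisher-z test on Pearson correlations, Cohen's q
   effect sizes, FDR 0.01).
5. **Discrimination** trains cross-validated classifiers (ridge logistic,
   random forest, RBF-SVM) to separate injured from sham microglia,
   reporting AUC, feature contributions and per-cell propensity scores.
6. **tSNE embeddings** visualise the phenotype space with density and
   marker-intensity maps.

Because raw instrument files from such experiments are rarely public, the
package ships a **synthetic-cohort generator** with a per-event ground-truth
manifest. Every downstream claim the package makes is tested against that
ground truth.

## The generative model

### Populations

Each sample is a mixture of six populations: debris, doublets, dead cells,
microglia, infiltrating myeloid cells, and counting beads. Events are drawn
from a multivariate normal on the *generation scale* — linear for the
scatter channels (FSC-A, FSC-H, SSC-A), arcsinh-transformed (cofactor 150)
for all fluorescence channels — and mapped back to raw intensities with
`sinh(x) * 150`. This matches common practice of modelling fluorescence as
log-normal-like with a well-behaved zero, and it makes the copula algebra
below exact.

Default geometry (see `default_populations()`): identification markers are
tight (spread 0.30 on the arcsinh scale) and separate populations by several
standard deviations — e.g. P2y12 at 2.2 on microglia versus 0.15 on
infiltrating cells — as on a well-compensated instrument with bright
antibody clones. Activation markers are deliberately broad (spread 0.75);
they carry the injury effects and make discrimination non-trivial. Debris
sits at low FSC; beads carry a dedicated bright flag channel. Doublets are
not drawn from a distribution: they are literal pairwise sums of two viable
singlet events, so FSC-A doubles while FSC-H (a pulse height) takes the
maximum — exactly the geometry the FSC-H/FSC-A singlet gate exploits.
Baseline cell-population fractions are debris 0.30, doublets 0.10, dead
0.12, microglia 0.04, infiltrate 0.44.

### Injury effects

An `effect_model()` carries, per condition:

* a **microglia fraction multiplier** (default 16 for CCI-ipsilateral,
  matching the order of magnitude of microgliosis plus infiltration at
  24 h); the other populations shrink proportionally;
* additive **location shifts** on the generation scale, applied to the
  microglia population only. The defaults encode the reported directions:
  FSC and SSC up; CD45 and CD11b/c up; P2y12 down; CD32 and CD163 up; CD86
  and RT1B down; CD200R unchanged. The contralateral hemisphere of injured
  animals receives the same directions at roughly a quarter of the
  magnitude (no fraction change), reflecting a mild global response;
* a **marker correlation matrix** injected through a Gaussian copula.
  Sham microglia have a weak uniform correlation of 0.10; injured
  ipsilateral microglia have a 0.45 block over a subset of markers (60% of
  M1 pairs, 67% of M2 pairs), and the contralateral M2 panel has a single
  boosted CD11b/c–CD163 pair.

Shift magnitudes were calibrated once so that a ridge-logistic classifier on
pooled microglia events attains an ipsilateral-injury-versus-sham AUC of
about 0.80 (M1) to 0.86 (M2) — the regime reported for this assay — and then
frozen. With only three animals per group the realized AUC varies by roughly
±0.05 across master seeds; that spread is biological-replication noise, not
estimation error, and we consider it a feature of the simulation.

### Animal intercepts and what "null" means

Animals receive random location intercepts (`animal_sigma`, default 0.05 on
the arcsinh scale, lognormal-multiplicative on scatter), shared across that
animal's hemispheres and panels. This makes the three animals per group
distinguishable and gives the optional animal-level analyses something to
estimate.

It also has a consequence worth stating plainly. The default marker screen
pools *events* across animals within a condition — cells are the statistical
unit, faithfully reproducing how such data are usually analysed. Pooled over
10,000+ events, a Mann–Whitney test resolves location differences far
smaller than the between-animal intercepts, so even with all injury effects
set to zero, two groups of three jittered animals differ detectably: the
event-pooling design is anticonservative under biological replicate
variation. This is pseudoreplication, and no amount of FDR control repairs
it. We therefore define the *null calibration* experiments on
exchangeable-event cohorts (`animal_sigma = 0`, `null_effects()`): they
verify that the testing machinery holds its nominal type-I rate when its
assumptions hold. The package also provides `marker_screen(unit =
"animal")`, which tests per-animal MFIs (n = 3 per group) — honest about
replication and correspondingly weak. Both views are reported in our own
analyses; users should read the event-level p-values as descriptive
strength-of-shift measures, not as animal-level inference.

## Statistical components

* **MFI** defaults to the median (robust to the heavy tails that remain
  after transformation); the mean is available. All outputs record which
  statistic and which intensity scale produced them.
* **Mann–Whitney U** uses midranks; the p-value is exact (full enumeration)
  when the smaller sample has ≤ 8 observations and no ties, otherwise a
  normal approximation with tie and continuity corrections. Degenerate
  all-constant input returns p = 1 with a warning. p-values are floored at
  1e-300 rather than printed as 0.
* **Benjamini–Hochberg** is the classic step-up; rejection is `adjusted p ≤
  q`, applied within each (panel, hemisphere) comparison family for the
  marker screen and across all pairs for the correlation screen.
* **Differential correlation**: the effect size is Cohen's
  q = |atanh ρ₁ − atanh ρ₂|. The test is the standard two-sample Fisher-z
  normal test, z = (atanh ρ₁ − atanh ρ₂) / √(1/(n₁−3) + 1/(n₂−3)),
  one-sided ("injury higher") at FDR 0.01 — the minimal reading of
  "significantly higher correlations". n is the pooled event count per
  condition; `balance_animals = TRUE` downsamples so no animal dominates.
* **Classifiers**: stratified 10-fold CV, re-split for each of 10 runs;
  features standardized inside training folds only; AUC per run is the mean
  over folds, and the headline ± is the SD over the 10 run means. Ridge
  logistic (λ = 0.01) gives deterministic coefficients, used both for
  feature contributions and for per-cell propensity scores (predicted
  probability of the injury class). Random forest: 200 trees, permutation
  importance. RBF-SVM: C = 1, γ = 1/d on standardized features, raw
  decision values as scores. Event-level folds leak animal identity by
  design (cells as units); this matches the assay's conventions and is
  called out wherever AUCs are reported.
* **tSNE**: perplexity 30, 1,000 iterations, no PCA pre-reduction (marker
  spaces are low-dimensional), markers only — scatter channels are excluded
  so the map reflects immunophenotype. Fixed seeds give identical
  embeddings.

## Numerical and design choices

* **Gating conventions.** Positivity thresholds are strict (`>`), boundary
  points of rectangles and polygons are inside (even-odd rule), and the
  singlet band keeps FSC-H/FSC-A in [0.75, 1.10] with non-positive FSC-A
  excluded. The viability threshold is found at the kernel-density valley
  between the two largest dye modes; a candidate valley must dip below half
  the lower mode (otherwise unimodal KDE wiggles masquerade as valleys) and
  failing that the configured fallback is used, with a warning. Marker
  positivity thresholds default to fixed values (1.2 on the arcsinh scale)
  placed between the generator's negative (≈ 0.15–0.3) and positive
  (≥ 2.2) populations, the way an analyst places gates from FMO controls;
  every threshold is a config field.
* **Compensation.** The spillover matrix convention is `S[i, j]` = fraction
  of dye *j* observed in detector *i*; compensation solves the linear
  system, keeps negative values (clipping would bias MFI), and refuses
  near-singular matrices with a condition-number diagnostic.
* **Quantification.** `cells_per_mg = events × (beads_added / bead_events) /
  tissue_mass_mg`, exact arithmetic; zero acquired beads is an error, not a
  zero. Default bead spike (5,000), tissue mass (20 mg) and per-sample event
  count (10,000) are conventions — real instruments publish none of these —
  chosen so counts have plausible magnitudes; fold changes are invariant to
  them.
* **Embedding sanity bounds.** A forced 2-means split of even an ideal
  single Gaussian blob has mean silhouette ≈ 0.32 (and ≈ 0.37 for a uniform
  square), while genuine two-island structure scores ≈ 0.85; our
  "no spurious islands" check therefore requires < 0.45 rather than a
  smaller bound no blob-shaped embedding could meet.

## What the tests do and do not show

The test suite exercises the package at full study scale: a 24-sample
cohort (2 groups × 2 hemispheres × 2 panels × 3 animals) at 10,000 cell
events plus 5,000 beads per sample, where gating recovers every population
with pooled F1 ≥ 0.95 and the bead arithmetic returns the injected 16-fold
microglia expansion within [14, 18] over seeds. Statistical primitives are
checked exactly against brute-force oracles (pair counting and full
enumeration for Mann–Whitney, the step-up definition for BH, the U/(n₁n₀)
identity for AUC, closed forms for Fisher z and Cohen's q). Direction
recovery, null calibration (200 zero-effect replicates), correlation-boost
recovery (±1 pair), the discrimination regime and embedding separability run
at reduced but adequately powered sizes chosen for a laptop-class single
core: 20 × 24-sample cohorts at 3,000 events for direction recovery, 200
12-sample cohorts at 500 events for the null, 10,000-event two-sample
designs for correlation recovery.

Passing these tests shows the pipeline recovers what the generator put in.
It does not show that real microglia data satisfy the generator's
assumptions: real intensity distributions are skewed and zero-inflated
beyond what an arcsinh-normal captures, spillover is never perfectly known,
population boundaries are not 4σ clean, batch and staining variation exceed
a 0.05 intercept, and real effect sizes are not block-constant. The
generator's defaults are a *calibrated caricature*: faithful in directions,
orders of magnitude and correlation topology, and deliberately clean enough
that failures indict the code rather than the simulation.

## Known limitations

* Only the arcsinh transform is provided (no logicle/biexponential), and
  FCS support is list-mode float (3.0/3.1 read, 3.1 write) — integer
  instrument files should be converted upstream.
* The pipeline applies a supplied spillover matrix but does not estimate
  one from capture beads.
* Gating is geometric, not model-based; there is no automated
  clustering-based gate discovery.
* Event-level inference is anticonservative under biological replication
  (see above); animal-level modes exist but n = 3 limits them.
* Published headline numbers from real instruments (exact AUCs, exact
  significant-correlation percentages) depend on unpublished raw files; on
  synthetic cohorts the corresponding quantities are recovered in range,
  not to the digit.
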