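---
title: "Path modeling of chilling-responsive gene blocks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path modeling of chilling-responsive gene blocks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(chillsem)
```

## What the package models

Chilling stress in subtropical crops such as litchi triggers a signaling
cascade: hormone signal-transduction genes respond first, cold-response
transcription factor families (ICE1, CBF, bZIP) relay the signal, and
antioxidant-system genes are activated downstream. `chillsem` treats each
of these gene groups as a *block* whose member transcripts reflect one
latent pathway-activity variable, and asks how strongly the blocks are
connected — directly (hormone → antioxidant) and through the transcription
factor mediators (hormone → TF → antioxidant).

The pipeline has four analysis stages plus a generator:

1. **Screen** — per-timepoint negative-binomial Wald contrasts against the
   control (day 0), FDR ≤ 0.01 and |fold-change| ≥ 2, intersected across
   timepoints into a chilling-responsive gene (CRG) set.
2. **Partition** — CRGs are assigned to hormone / TF / antioxidant blocks
   from an annotation table; expression is row Z-scored.
3. **Path model** — partial least squares structural equation modeling
   (PLS-SEM) over the blocks, with bootstrap inference.
4. **Concordance** — qRT-PCR relative quantification (2^−ΔΔCt) regressed
   against RNA-seq fold-changes.

Because the original sequencing libraries are not bundled, a synthetic-data
generator with *known* differential-expression structure and *known* latent
path structure stands in for them; every downstream stage is validated by
parameter recovery against that generative truth.

## The PLS-SEM estimator

Each latent η_j is measured reflectively (Mode A) by its indicator genes
x_{jk} = λ_{jk} η_j + ε. Estimation follows the classical two-step
alternation (Lohmöller's iteration):

* **Outer step** — the latent score is the standardized weighted sum of its
  indicators, ŷ_j = Σ_k w_{jk} x_{jk}.
* **Inner step (path weighting scheme)** — latent j's inner proxy weights
  each *predecessor* by its multiple-OLS coefficient (regressing ŷ_j on all
  predecessor scores jointly) and each *successor* by its score
  correlation; the proxy is the standardized weighted sum over neighbors.
  The centroid (sign of the correlation) and factorial (the correlation)
  schemes are also implemented; on well-conditioned data the three agree
  closely.
* **Outer update (Mode A)** — each outer weight becomes the correlation of
  its indicator with the block's inner proxy.

Iteration stops when the largest absolute change of the unit-norm outer
weight vectors drops below `tol` (default 1e-7, `max_iter` 300;
non-convergence is flagged and partial results are returned). Afterwards,
scores are re-standardized, outer loadings are indicator–score
correlations, path coefficients are per-endogenous-latent OLS on
predecessor scores (standardized coefficients), and R² comes from those
same regressions.

Two exact reductions pin the implementation down and are enforced in the
test suite at 1e-10: with single-indicator latents, a lone path equals the
Pearson correlation of the two columns, and multiple parents yield the
standardized multiple-OLS coefficients.

### Numerical and identifiability choices

* **Initialization** — all outer weights start at 1. The choice must be
  pinned for determinism; this is the common default.
* **Standardization denominator** — scores use the population (1/n) sd.
  Loadings and path coefficients are invariant to this; pinning it makes
  the score matrices bit-stable.
* **Sign orientation** — a latent score's sign is undetermined, so each
  latent is flipped to make its loading sum positive (ties keep the
  current sign). This is deterministic and independent of indicator order.
* **Low-n regime** — PLS-PM needs only the indicator correlation matrix,
  so fitting 29 indicators on 12 samples is *allowed* but triggers a
  prominent warning: with n far below the indicator count the underlying
  correlations are poorly determined and results should be read as
  exploratory.

### Reliability metrics and effects

Average variance extracted (AVE) is the mean squared loading of a latent's
indicators; `validate_model()` flags latents below the conventional 0.5
bar (inclusive at the boundary). Composite reliability is
(Σλ)² / ((Σλ)² + Σ(1 − λ²)). Direct/indirect/total effects are computed
exactly on the DAG via the terminating power series of the path
coefficient matrix, and are tested against brute-force path enumeration.

### Bootstrap with individual sign changes

`bootstrap_pls()` resamples sample rows with replacement (default
B = 5000; the bundled pipeline fixture uses B = 500 to keep a full run
under a minute) and refits each resample. Because each refit may flip a
latent, estimates are sign-aligned before aggregation. Under the
*individual* policy each outer weight and loading whose sign differs from
the original estimate is flipped on its own; each construct is then
re-oriented by the majority vote of those alignment flips, and path
coefficients are recomputed under the construct orientations (equivalent
to refitting with flipped scores). A whole-construct policy and a
no-alignment policy are available for comparison. Standard errors are the
sd of aligned estimates, t = original / SE with a normal reference for
p-values (the convention of classical PLS software), and percentile CIs
are reported alongside. Resamples that fail to fit or converge are
dropped and counted. The individual-changes convention in legacy PLS
software is not fully documented; the residual ambiguity is resolved here
by the majority-vote construct orientation, which reproduces the
degenerate cases exactly (perfect dependence gives SE 0) and tracks the
analytic correlation SE (1 − r²)/√(n − 1) within a few percent at n = 200.

## The differential-expression screen

The screen is a deliberately transparent NB Wald test rather than a
wrapper around a DE package — the CRG definition depends only on the
thresholds, and the package owns its computation end to end:

* **Normalization** — median-of-ratios size factors over genes with a
  positive geometric mean (i.e. no zero count).
* **Dispersion** — per-gene pooled two-group method of moments,
  α = max(floor, (s² − x̄)/x̄²) with floor 1e-8 (α = 0 is Poisson;
  variance = μ + αμ²), using the pooled within-group variance
  ((n₁−1)s₁² + (n₂−1)s₂²)/(n₁+n₂−2). With 3 replicates per group the raw
  per-gene estimate is extremely noisy and its low tail inflates Wald
  statistics, so the value used for testing is the **maximum of the
  per-gene estimate and the across-gene median** — the conservative
  "maximum" information-sharing rule of early NB DE testing. On null
  synthetic data this keeps the raw p ≤ 0.05 fraction near 0.05; without
  sharing it exceeds 0.12.
* **Test** — log2fc = log2((x̄_t + c)/(x̄_c + c)) with pseudocount c = 0.5;
  delta-method SE from the NB variance; two-sided normal p; BH FDR within
  each contrast separately (matching per-comparison DEG counting).
* **Screen** — fdr ≤ 0.01 and |log2fc| ≥ 1, both inclusive; all-zero genes
  are dropped with a logged count.

## What the generator emulates — and what it does not

`sim_config()` defaults are the package's reference study conditions:
4 timepoints (0d/4d/8d/12d) × 3 replicates = 12 samples; 2000 background
genes with NB baseline mean 100 and dispersion 0.05; 10% DE genes at
log2FC 2 applied at every non-control timepoint; a mediation topology of
one hormone latent (10 indicators), three TF mediators (3 indicators
each) and one antioxidant latent (10 indicators); outer loadings 0.85
with unit-variance indicators. No published effect-size or noise
parameters exist for this design, so these are stated choices of what a
transcriptomics practitioner would call a realistic strong-effect
chilling experiment, fixed once.

Latents are generated in topological order with residual variances solved
from the implied covariance so that **every latent has unit variance**;
configured paths are therefore directly interpretable as the standardized
coefficients PLS-SEM reports. A consequence worth noting: coefficients
cannot be set arbitrarily — a latent whose correlated parents would
explain more than unit variance is rejected at configuration time. For
the default topology this caps uniformly strong coefficients on the
four-parent antioxidant latent; the default profile is 0.5 on the
hormone → TF edges, 0.3 on the TF → antioxidant edges and 0.2 on the
direct edge (explained variance 0.625).

For end-to-end coherence, `simulate_dataset()` embeds the indicator genes
in the count matrix and forces them into the DE set, so they survive the
CRG screen and reach the path-modeling stage. The continuous indicator
matrix is generated on a log-expression scale and is what the PLS stage
consumes (after row Z-scoring, which is immaterial to the fit because
indicator columns are standardized internally anyway); counts are a
parallel output for the DE stage.

The generator does **not** simulate reads, alignment, length/GC biases,
outlier samples, correlated background genes, or library-size variation
beyond what NB sampling induces. Passing recovery tests therefore shows
the estimators are correct under their own model, not that real chilling
data satisfy that model.

## Known limitations

* **Attenuation** — composite scores correlate imperfectly with their
  latents at finite loadings, so PLS path estimates are mildly biased
  toward zero (≈5% of the coefficient at loadings 0.9 with 3-indicator
  blocks). At n = 500 this bias is comparable to the sampling SE, which
  pushes 95% bootstrap CI coverage of generating values down to roughly
  85%. The package reports the classical (uncorrected) estimator by
  design.
* **Wald screen at n = 3** — the screen is a sanity-calibrated
  approximation, not a calibrated test; it is conservative by
  construction of the shared dispersion.
* **qPCR module** — no primer-efficiency (Pfaffl) correction; technical
  replicates are averaged on the Ct scale.

## Problem sizes used by the shipped checks

The test suite fits models at n = 40–500 samples, runs Monte-Carlo
calibration checks at n = 1e5, parameter recovery over 20 seeds at
n = 500 with B = 1000 bootstrap resamples, DE calibration on 2000-gene
matrices, and the full pipeline twice (byte-identity) on a 2000-gene,
12-sample fixture with B = 500. The acceptance script fits the reference
topology at n = 300 and reports the minimum per-latent AVE.

## Interface note

The package is a library in the style of DE/omics analysis packages: the
exported functions (`run_pipeline()`, `render_outputs()`, and the
per-stage functions they compose) plus configuration files are the
interface; there is no shell executable.
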