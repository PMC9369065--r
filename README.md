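# chillsem

Screening chilling-responsive genes from small multi-timepoint RNA-seq
designs and quantifying direct and mediated relationships among gene
blocks with partial least squares structural equation modeling (PLS-SEM).

## The problem

Cold-sensitive crops such as litchi respond to chilling through a
cascade: hormone signal-transduction genes shift first, cold-response
transcription factor families (ICE1, CBF, bZIP) relay the signal, and
antioxidant-system genes are induced downstream. Given a genes × samples
expression matrix over chilling timepoints, the questions are:

1. Which genes respond to chilling at *every* timepoint? A gene is a
   **chilling-responsive gene (CRG)** when it passes FDR ≤ 0.01 and
   |fold-change| ≥ 2 in each timepoint-vs-control contrast.
2. Treating the hormone, TF and antioxidant gene blocks as reflective
   latent variables η (each member transcript x = λη + ε), how strong are
   the structural paths among blocks? For hormone latent H, mediators
   T₁..T₃ and antioxidant latent A, the effect decomposition is

   total(H→A) = c + Σᵢ aᵢbᵢ

   with c the direct path, aᵢ the first-order H→Tᵢ paths and bᵢ the
   second-order Tᵢ→A paths.

The PLS estimator is the classical Lohmöller alternation with the **path
weighting scheme** (Mode A outer estimation; predecessors weighted by
multiple-OLS coefficients, successors by score correlations), with
bootstrap inference using **individual sign changes**, average variance
extracted (AVE ≥ 0.5 as the convergent-validity bar) and composite
reliability. The differential-expression screen is a transparent
negative-binomial Wald test (median-of-ratios size factors,
method-of-moments dispersion with conservative cross-gene sharing,
BH FDR). A synthetic-data generator with known NB effects and known
latent path structure makes every stage testable without external data;
a qRT-PCR module (2^−ΔΔCt, concordance regression) mirrors the usual
wet-lab confirmation step.

## Worked example

Simulate the reference design (one hormone block with 10 indicator
genes, three TF mediators with 3 each, one antioxidant block with 10;
outer loadings 0.85) at n = 300 samples and fit the path model:

```r
library(chillsem)

cfg        <- sim_config(n_samples = 300, seed = 42)
scores     <- simulate_latents(cfg)
indicators <- simulate_indicators(scores, cfg)
fit        <- fit_pls(indicators, model_from_config(cfg))
fit
#> PLSFit: 5 latents, n = 300, scheme = path, converged in 4 iteration(s)
#>   from   to  estimate
#> 1  ABA ICE1 0.5025158
#> 2  ABA  CBF 0.3987710
#> 3  ABA bZIP 0.4334957
#> 4 ICE1   AO 0.2972902
#> 5  CBF   AO 0.2693537
#> 6 bZIP   AO 0.2908360
#> 7  ABA   AO 0.2310668
```

The estimates sit near the generating coefficients (0.5 on the
first-order edges, 0.3 on the second-order edges, 0.2 direct). Outer
measurement quality and the mediation decomposition:

```r
round(pls_ave(fit), 3)
#>   ABA  ICE1   CBF  bZIP    AO
#> 0.754 0.831 0.792 0.823 0.730
subset(pls_effects(fit), from == "ABA" & to == "AO")
#>    from to    direct  indirect     total
#> 17  ABA AO 0.2310668 0.3828796 0.6139464
```

Every AVE clears 0.5 (generating loadings 0.85 imply a population AVE of
0.7225), and about 62% of the hormone block's total effect on the
antioxidant block flows through the TF mediators. Bootstrap inference:

```r
bootstrap_pls(indicators, model_from_config(cfg), B = 500, seed = 1)
#> BootstrapSummary: B = 500 (500 effective, 0 failed), sign policy = individual
#>    from   to  original         se         t            p  ci_lower  ci_upper
#> 59  ABA ICE1 0.5025158 0.03999130 12.565631 3.262636e-36 0.4301722 0.5802574
#> ...
#> 65  ABA   AO 0.2310668 0.05433180  4.252884 2.110350e-05 0.1269902 0.3312025
```

The full five-stage pipeline (simulate → DE screen → block partition →
PLS-SEM → qPCR concordance) runs from one seeded config and is
byte-deterministic:

```r
run_pipeline(list(seed = 1, out_dir = "runs/demo"))
render_outputs("runs/demo")   # heatmaps + summary tables
```

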