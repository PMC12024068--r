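# comdimr

Multiblock data fusion for untargeted metabolomics and lipidomics.

## What this package is for

Untargeted MS studies on one cohort typically yield several sample ×
feature intensity tables ("blocks") — e.g. metabolomics and lipidomics,
each in positive and negative ionization mode — plus a sample metadata
table (genotype, age, treatment, ...). `comdimr` implements the full
chemometric chain that turns those tables into fused, interpretable
sample-level structure:

1. **Preprocessing, per block** — prevalence filtering; per-sample median
   normalization; imputation of censored (zero/missing) intensities by
   seeded uniform draws in `(0, m_j/5]`, with `m_j` the column's smallest
   non-zero value; base-10 log; autoscaling. A state machine enforces the
   stage order.
2. **External Parameter Orthogonalization (EPO)** — removes a
   detrimental-variation subspace (the top-*k* right singular vectors of
   an interference matrix, by default the grand-centered level means of a
   named nuisance factor) by projecting each block onto its orthogonal
   complement: `X ← X(I − VVᵀ)`.
3. **ComDim / CCSWA fusion** — after Frobenius-norm block scaling,
   extracts common components by iterating
   `W = Σ_b λ_b X_b X_bᵀ → q = dominant eigenvector of W → λ_b = qᵀX_bX_bᵀq`
   to convergence, deflating and repeating. The salience `λ_b ≥ 0` is
   block *b*'s weight on each common component; explained-variation
   fractions and convergence diagnostics are recorded. With one block
   this reduces exactly to PCA (tested against an SVD oracle).
4. **Univariate screening** — per-feature two-sided Wilcoxon rank-sum
   (exact when the smaller group ≤ 8 and no ties; tie/continuity
   corrected normal approximation otherwise) or Welch *t* with
   Satterthwaite df for relative-abundance tables, both with
   Benjamini–Hochberg FDR; top-*k* row-normalized heatmap matrices.
5. **Reporting** — ComDim score plots with per-class Hotelling T²
   confidence ellipses, `(x−μ)ᵀS⁻¹(x−μ) ≤ 2(n−1)/(n−2)·F₂,ₙ₋₂(0.98)`,
   using the small-sample F scaling.
6. **Synthetic data** — `simulate_multiblock()` generates multiblock
   cohorts with a shared latent group effect, a nuisance latent,
   log-normal intensities and limit-of-detection censoring, plus ground
   truth for recovery metrics (`truth_eval()`).

See `vignettes/multiblock-fusion.Rmd` for the models, the default
parameters and why, and what the synthetic world does and does not
establish.

## Worked example

```r
library(comdimr)

sim   <- simulate_multiblock(sim_config(seed = 2024))   # 4 blocks, 23 mice
paths <- write_simulation(sim, "readme_sim")

res <- run_pipeline(
  list(blocks = paths$blocks, metadata = paths$metadata, seed = 2024,
       test_factor = "genotype", nuisance_factor = "age", epo_k = 1),
  "readme_out")

res$comdim
#> <comdim_result> 2 common component(s), 4 block(s), 23 samples
#>                     CC1    CC2
#> metabolomics_pos 0.3187 0.0800
#> metabolomics_neg 0.2958 0.0370
#> lipidomics_pos   0.2149 0.0297
#> lipidomics_neg   0.1049 0.0855
#> explained        0.2336 0.0580

truth_eval(res$comdim, sim$truth)
#> score_cor = 0.991, salience_tau = 1.00

res$ellipses$AKR
#> <ellipse_spec 'AKR'> n = 11, 98% level, center (0.0804, -0.0057),
#>   semi-axes (0.274, 0.0674)
```

Reading the numbers: the component-1 saliences (0.319, 0.296, 0.215,
0.105) recover the simulated per-block signal strengths
(1.0, 0.7, 0.4, 0.1) in order (Kendall τ = 1), component-1 scores
correlate 0.99 with the true latent group score, and the two genotype
classes get 98% Hotelling ellipses on the score plane. `readme_out/`
contains `scores.csv`, `saliences.csv`, per-block loadings, univariate
TSVs, heatmap matrices, `ellipses.json` and a `run_log.json` recording
every effective parameter; rerunning with the same seed reproduces every
CSV bit-for-bit.

A command-line driver wraps the same operations:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","comdimr.R",package="comdimr"))')" \
  simulate --seed 1 --out simdir
Rscript ... run --config simdir/config.json --out outdir
```

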