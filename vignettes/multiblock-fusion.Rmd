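---
title: "Multiblock ComDim fusion for untargeted metabolomics: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiblock ComDim fusion for untargeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comdimr)
```

# The problem

Untargeted MS experiments on a single cohort routinely produce several
feature tables — here, metabolomics and lipidomics, each in positive and
negative ionization mode. Each block has its own feature space, intensity
scale and noise level, yet all blocks observe the same animals, so the
biological structure of interest (e.g. genotype separation) should be
*common* across blocks while block-specific artifacts are not. `comdimr`
implements a complete preprocessing-plus-fusion chain for this setting:

```
raw -> filter -> median_normalize -> impute -> [univariate screen]
    -> log10 -> EPO -> autoscale -> frobenius_scale -> ComDim
    -> score plots with Hotelling T2 ellipses
```

The order is enforced by a state flag on every block: each operation
declares the states it accepts and the state it produces, transitions may
skip stages but never move backwards. Out-of-order calls are hard errors,
not warnings, because silently re-normalizing an already-normalized table
is the classic way such pipelines go wrong.

# Preprocessing model and parameters

**Prevalence filter** (`filter_features`, default `min_prevalence = 0.5`).
A feature is kept if at least half the samples observe it (non-missing
and non-zero). The threshold is a convention, not an estimate; it exists
chiefly because the imputation rule below needs a non-zero minimum per
column, which near-empty columns cannot provide. It is configurable and
logged.

**Per-sample median normalization** (`median_normalize`). Every entry is
divided by the median intensity of its sample, cancelling loading and
injection differences. Zeros in MS tables are censoring artifacts, not
measurements, so the median is taken over the *positive non-missing*
entries by default; otherwise a sample's missingness rate would drive its
normalizer. The alternative (`median_over = "all"`) is exposed for users
who disagree. After this step the positive-entry median of every sample
is exactly 1.

**Censored-value imputation** (`impute_censored`). Missing or exactly-zero
entries in column $j$ are replaced by $u \cdot m_j / 5$, where $m_j$ is the
column's smallest non-zero value and $u \sim \mathrm{Uniform}(0, 1]$ — a
standard below-limit-of-detection stand-in: small, positive, random. The
interval is half-open at 0 so the subsequent log10 is always defined. The
step is stochastic, so the seed is a *mandatory* argument, recorded in the
run log; the caller's global RNG stream is saved and restored, so
imputation is reproducible without side effects.

**log10 and autoscaling.** Base-10 log stabilizes multiplicative MS
variance. Autoscaling centers each feature and scales to unit variance
with the $n-1$ (sample) standard deviation — a convention choice;
constant columns are centered to zero and flagged rather than producing
NaN.

# External Parameter Orthogonalization

EPO removes a *detrimental-variation subspace*: given an interference
matrix $D$ whose rows span the unwanted variation, the model keeps the
first $k$ right singular vectors $V$ of column-centered $D$ and projects
every block as $X \leftarrow X(I - VV^\top)$. The projection is idempotent,
a Frobenius contraction, and leaves the corrected data exactly orthogonal
to $V$ — all three are asserted in the tests at $10^{-10}$.

The open design question is what $D$ is. When the nuisance is a known
sample grouping (age, batch, cage), the natural construction — the
default here (`build_interference_matrix`) — is the matrix of
per-level feature means, centered on their grand mean: its singular
vectors are exactly the directions along which the nuisance levels
differ. A user-supplied $D$ is accepted too (`fit_epo` on any matrix).
The package deliberately does **not** pick a nuisance factor for you:
orthogonalizing against the wrong biology silently deletes signal, so the
factor is mandatory configuration whenever $k > 0$.

A consequence worth stating plainly: a grand-centered level-mean matrix
on an $L$-level factor has rank at most $L - 1$, so a two-level factor
supports only $k = 1$. The pipeline's default `epo_k = 4` (a common
choice when the interference matrix is richer, e.g. many batches or a
continuous drift series) therefore fails fast with the achievable rank in
the error message rather than quietly truncating; the simulator's
generated configs set `epo_k` to `n_levels - 1`. Automatic selection of
$k$ is a non-goal: scree information belongs in logs, not in silent
decisions.

# ComDim / CCSWA

After autoscaling, every block is divided by its Frobenius norm so each
carries total variance 1 into the fusion (`frobenius_scale`). ComDim then
extracts common components one at a time. For component $c$, with block
association matrices $W_b = X_b X_b^\top$ and saliences initialized at
$\lambda_b = 1$:

$$W = \sum_b \lambda_b W_b, \qquad q = \text{dominant unit eigenvector of } W,
\qquad \lambda_b \leftarrow q^\top W_b q,$$

iterated until the largest salience change is below `tol` (default
$10^{-10}$, `max_iter = 200`); then every block is deflated by $q$ and
the next component starts. The salience $\lambda_b = \|X_b^\top q\|^2
\ge 0$ is the variance of block $b$ along the common direction — the
per-block weight of that component. The CCSWA objective
$\sum_b \lambda_b^2$ is non-decreasing across iterations (asserted per
iteration in the tests); non-convergence is recorded in the result and
warned about, not fatal.

Numerical choices, all recorded in the run log:

* **Eigen-solver**: dense symmetric `eigen()`. Sample counts here are
  tens; exactness and determinism beat iterative speed.
* **Score scaling**: score columns carry $\sqrt{\mu}$ ($\mu$ the fused
  eigenvalue), so distances in score plots reflect explained variation;
  unit-norm scores are available via `score_scaling = "unit"`.
* **Sign convention**: each score column is flipped so its
  largest-magnitude entry is positive — eigenvectors are sign-ambiguous
  and reproducible output requires a rule.
* **Explained variation**: $\sum_b \lambda_b$ for the component, divided
  by the initial total $\sum_b \|X_b\|_F^2$. Fractions are not forced to
  be non-increasing across components (with unequal saliences the fused
  criterion need not order them), but each lies in $[0,1]$ and the sum is
  bounded by 1.
* **Components**: default 2, matching the 2-D score plots this analysis
  feeds.

With a single block the procedure reduces exactly to PCA of that block
(the salience multiplies $W$ without changing its eigenvectors), which
provides the strongest available correctness oracle and is tested to
$|r| > 1 - 10^{-8}$ against an SVD.

# Univariate screening

Each block is screened feature-by-feature *before* the log step — the
Wilcoxon rank-sum test is invariant under monotone transforms, so the
choice of scale changes nothing (asserted in tests), and the pre-log
matrix is the first complete one in the chain. Exact p-values are used
when the smaller group has at most 8 samples and the feature has no ties;
otherwise the normal approximation with tie and continuity corrections.
The exact path is validated against brute-force enumeration of all
$\binom{n_1+n_2}{n_1}$ group assignments. Benjamini-Hochberg q-values are
computed with the explicit step-up construction and cross-checked against
an independent implementation. A Welch-t path with Satterthwaite degrees
of freedom (`welch_screen`) serves relative-abundance (taxa) tables,
with degenerate zero-variance features flagged explicitly.

The "top-k" heatmap matrix selects features with raw $p < \alpha$
(default 0.05), keeps the $k = 50$ smallest, and row-normalizes each
feature to zero mean / unit variance across samples. Raw p — not q — is
the gate by design, mirroring how such "top 50 modulated features"
figures are conventionally captioned; q-values are reported alongside and
a `use_q` switch inverts the choice. Row order is average-linkage
hierarchical clustering on Euclidean distance, a deterministic common
default.

# Hotelling T² ellipses

Per class, the $1-\alpha$ confidence region of the 2-D scores is
$(x-\mu)^\top S^{-1} (x-\mu) \le \frac{2(n-1)}{n-2} F_{2,n-2}(1-\alpha)$,
drawn at 98% by default. The F-based small-sample scaling is used rather
than the $\chi^2_2$ asymptotic because class sizes in this kind of animal
study are 3-8, where $\chi^2$ under-covers badly. Classes need $n \ge 3$
(fewer samples cannot define a covariance); smaller classes are plotted
without an ellipse, with a warning. Collinear scores give a singular
covariance and a hard error. Coverage is Monte-Carlo calibrated in the
tests: at $n = 10^4$ bivariate normal points, the empirical fraction
inside the 98% ellipse is within 0.005 of nominal, and the 0.5 / 0.9 /
0.98 regions nest monotonically.

# The synthetic world

`simulate_multiblock` generates what the analysis assumes, so that every
stage is testable without any external download. Per sample, a shared
latent score $t_i = \Delta g_i + N(0,1)$ ($g_i = \pm\tfrac12$ the group
coding, $\Delta$ = `effect_size`) and a nuisance latent tied to an
alternating second factor. Per block $b$, log10 intensities are

$$L_b = \mathbf{1}\mu_b^\top + s_b\, t\, p_b^\top + \nu_b\, u\, r_b^\top + E_b,$$

with sparse shared loadings $p_b$ (30% of features by default), a
nuisance direction $r_b$ orthogonalized against $p_b$, per-feature
log-normal baselines, and i.i.d. Gaussian noise. Intensities are
$10^{L_b}$; the lowest `censor_quantile` (default 10%) of each feature's
values is then set to exactly zero. Censoring is *value-dependent*, not
random: it emulates limit-of-detection missingness, which is what the
one-fifth-minimum imputation rule is designed for.

Defaults state a world once and keep it: unbalanced group sizes
(3, 4, 8, 8) crossed over genotype x treatment, so that the small-$n$
code paths (exact Wilcoxon, the $n \ge 3$ ellipse rule) are exercised by
construction; shared-signal strengths (1.0, 0.7, 0.4, 0.1) across the
four blocks; noise SD 0.3 and nuisance strength 0.5 in log10 units, an
effect size of 2 — values chosen as "clear but not trivial" signal for a
stool metabolomics design, and not revisited.

What the generator does **not** emulate: chromatographic or adduct
structure, correlated feature families, retention-time drift,
heteroscedastic instrument noise, or 16S count data. A green recovery
test therefore establishes that the algorithms do what they claim on
data satisfying their own assumptions — not that any particular
biological conclusion is right. Conversely `truth_eval` reports exactly
the quantities a recovery claim needs: |correlation| of fitted scores
with $t$, Kendall agreement of saliences with $s_b$, and
sensitivity/FDP of the univariate screen against the planted feature
set.

One honest consequence of this latent design: all affected features in a
block share the *same* realization of $t$, so univariate power is capped
by the group overlap of $t$ itself no matter how strong a feature's
loading is. With the default effect size 2 and group sizes 3-8, BH
discoveries at $q < 0.05$ are rare — as they would be in a real study of
that size — while the multivariate fusion, which pools features,
recovers the latent structure with $|r| > 0.95$. That contrast is a
feature of the stated world, not a bug.

# Determinism

Everything downstream of a seed is bit-reproducible: imputation and
simulation use private, restored RNG streams; eigendecompositions are
dense and deterministic; score signs follow the fixed convention; CSV
writers format at 15 significant digits. Running `simulate` and the full
pipeline twice with one seed produces bit-identical CSV artifacts, which
is asserted as an acceptance test. The run log records every effective
parameter (including defaults), package and R versions, and all warnings
raised during the run — but deliberately no timestamp, so logs from
identical runs are themselves identical.

# Known limitations

* ComDim here is the exploratory CCSWA variant only; predictive
  (ComDim-PLS) and ICA variants are out of scope.
* The EPO interference construction covers factor-driven nuisance;
  continuous drift would need a user-supplied $D$.
* The Wilcoxon exact path enumerates nothing at runtime (it uses the
  exact null distribution), but the tie-handling path is approximate, as
  is standard.
* Heatmap rendering is intentionally minimal; the CSV matrix is the
  reproducible artifact.
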