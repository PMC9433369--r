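---
title: "Separating specific factors from errors: the estimators behind compfa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating specific factors from errors: the estimators behind compfa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compfa)
```

## The model

Classical factor analysis writes a centered p-variate observation as
x = Λf + Ψu: m common factors plus one *unique* factor per variable. The
comprehensive model splits that unique part further,

x = Λf + Θs + e,

into a *specific* factor per variable (diagonal coefficient matrix Θ) and a
measurement *error* e. Under the standard orthogonality assumptions the
covariance structure is

C = ΛΛ′ + Θ² + C_EE,

where Θ² holds the specific variances and C_EE is the error covariance. The
scientific question the package addresses: which estimation procedures can
tell Θ² apart from the error variances diag(C_EE), and which can only recover
their sum?

Three estimators are implemented, all consuming a covariance (or correlation)
matrix, never raw data — their solutions depend on the data only through C:

* **LVFA** (latent-variable FA): fits C ≈ ΛΛ′ + Ψ² by least squares
  (`fit_lvfa_ls()`) or maximum likelihood (`fit_lvfa_ml()`). The unique
  variance Ψ² estimates θ² + error variance; the two are not separated.
* **MDFA** (matrix-decomposition FA, `fit_mdfa()`): minimizes
  n⁻¹‖X − FΛ′ − SΘ‖² over scores and parameters jointly, with [F, S]
  orthonormal. Its solution satisfies F′E = O and diag(S′E) = 0 but not the
  full S′E = O, and its Θ² estimate is contaminated by the error variances.
* **CDFA** (completely decomposed FA, `fit_cdfa()`): adds the constraint
  S′(X − SΘ) = O, making common factors, specific factors and errors mutually
  orthogonal. Its Θ² comes from minimum-rank factor analysis and tracks the
  generating specific variances even when errors are correlated across
  variables.

## Fitting pipeline and tunable parameters

All fitters take a `compfa_cov` (matrix plus nominal n; symmetrized and
PSD-checked at tolerance 1e-10 relative to the trace) and return a
`compfa_fit` with broom-style `tidy()`/`glance()` methods.

`compfa_options()` exposes the numerical knobs:

* `tol = 1e-8` — relative loss-change convergence criterion (unitless);
* `max_iter = 5000` — iteration cap per start;
* `n_starts = 1` — extra starts perturb the initial unique variances inside
  [0.2, 0.8]·diag(C) under `seed`; one start is sufficient on the simulation
  design, multi-start guards against local minima on hard inputs;
* `variance_floor = 1e-6` — lower bound for Ψ² in the likelihood fitter
  (variance units); the least-squares fitter is deliberately unconstrained in
  sign so Heywood cases surface as `proper = FALSE` rather than being masked.

Numerical choices worth knowing about:

* Eigendecompositions use decreasing eigenvalue order with a deterministic
  sign rule (largest-magnitude component nonnegative), so eigen- and
  SVD-based steps are bit-reproducible.
* The least-squares latent fitter is the classical principal-factor
  alternation; its fixed points satisfy ψ² = diag(C − ΛΛ′).
* The likelihood fitter is EM on the covariance followed by an L-BFGS-B
  polish with the analytic gradient and a tight projected-gradient tolerance;
  EM alone approaches the optimum along a slow linear tail, and the polish is
  what makes the stationarity identity diag(ΛΛ′ + Ψ²) = diag(C) hold to
  ~1e-6.
* MDFA alternates an orthogonal-Procrustes score update (thin SVD of X*A)
  with the closed-form parameter update Λ = X*′F/n, Θ = diag(S′X*)/n, on a
  surrogate root X* = √n·[C½; 0]. Any root of nC gives the same loss and
  parameters; a test verifies this against a Cholesky-based root. The run
  ends with a parameter step, so F′E = O and diag(S′E) = 0 hold exactly in
  the returned solution.
* Ties among eigenvalues or singular values are harmless for the losses
  (which depend only on invariant subspaces) and are resolved by the sign
  rule above.

## The minimum-rank step

CDFA's specific variances solve: minimize the sum of the p−m smallest
eigenvalues of C − diag(θ²) subject to θ² ≥ 0 and C − diag(θ²) positive
semidefinite. The minimizer lies on the PSD boundary, where the reduced
matrix loses rank. A projected-subgradient scheme that steps along the
trailing-eigenvector subgradient and bisects back to feasibility stalls
there: every tangent direction has negative curvature for the active zero
eigenvalue, so feasible step lengths collapse. `fit_mrfa()` therefore solves
the program by an interior-point scheme — a log-determinant barrier on the
reduced matrix plus a log barrier on θ², driven down a geometric schedule
(10⁻¹ to 10⁻¹⁰ times the mean diagonal), with Barzilai–Borwein gradient steps
and backtracking inside each stage. On exact low-rank-plus-diagonal inputs it
reaches the optimum to ~1e-9; on small problems it matches a refining grid
search to better than 1e-4.

Score matrices realizing a CDFA solution can be reconstructed explicitly
(`reconstruct_scores()`) by factorizing the joint Gram matrix of [X, S],
which is PSD precisely because C − Θ² is. That Gram matrix has rank up to
p + rank(C − Θ²) ≈ 2p − 1 after the minimum-rank step, so the reconstruction
uses max(m + p, 2p) score rows by default — the minimal m + p rows of the
fitting root are generally not enough to host a fully orthogonal score
system.

## What the generator emulates

`draw_truth()`, `build_error_cov()`, `scale_errors()` and the two `gen_cov_*`
functions reproduce a 12-cell Monte-Carlo design over p = 12 variables,
m = 3 factors, n = 200 observations:

* loadings uniform on [−1, 1] (rank-m enforced by redraw), specific variances
  uniform on [0.1, 0.8];
* three error-correlation levels — none (diagonal Φ with variances uniform on
  [0.1, 0.8]), low and high (off-diagonal correlations ±N(0.2ρ, (0.05ρ)²)
  with ρ = 1 or 2, independent random signs);
* two error magnitudes — α chosen so tr(α²Φ)/tr(ΛΛ′) is 0.1 or 0.2. The
  ratio is applied to the effective error covariance α²Φ; applying it to the
  unscaled scaffold would leave α undefined, since only α²Φ enters the data;
* a nonrandom version (C = ΛΛ′ + Θ² + realized error scatter, exactly) and a
  random version (factor scores drawn as well, so C fluctuates around the
  structure).

One honesty note on the high-correlation level. A 12×12 matrix with unit
diagonal and incoherently signed off-diagonals of magnitude ≈ 0.4 is never
positive semidefinite — its expected smallest eigenvalue is about −1.2, and
no PSD correlation matrix of this size can carry incoherent correlations that
strong. Since errors must be sampled from N(0, Φ), the generator replaces an
indefinite draw with its nearest correlation matrix (`Matrix::nearPD`). This
preserves the incoherent sign pattern but necessarily attenuates the realized
correlations to mean |r| ≈ 0.28 at the high level (≈ 0.20 at the low level).
Alternatives were examined and rejected: wholesale rejection sampling never
accepts at the high level; attaching the random signs to variables instead of
pairs makes draws feasible but produces near-rank-one error correlation that
the factor estimators simply absorb, flattening the correlation-level effect
the design is meant to probe. The consequence is that recovery errors under
correlated errors — in particular the contrast between the latent-variable
and decomposition estimators at the high level — are somewhat smaller here
than under the nominal (unrealizable) design. Qualitative orderings are
unaffected.

What passing the simulation tests does *not* show about real data: the
generator draws normal scores and errors, exact uniform truths, and a single
(p, m, n) regime; heavy tails, ordinal items, model-rank misspecification and
small-n behavior are all outside its reach.

## The recovery metrics

Estimated loadings are aligned to the truth by orthogonal Procrustes
(reflections allowed) before comparison — the least-squares-optimal transform
is used even though the comparison metric is L1, which is the standard
practice; alignment and metric disagree only rarely and a property test
tracks this. Recovery is summarized by mean absolute differences: loadings
(L1/(pm)), and diagonal variances against either the generating specific
variances or their sum with the realized error variances (L1/p). The Δ
statistic is the latent-variable specific-variance MAD minus the
matrix-decomposition one; Δ > 0 means the decomposition estimate is closer.

`run_grid()` executes the full design with per-cell seeds derived by hashing
(grid seed, replication, cell), so dropping a method or cell never shifts
another stream, and results are reduction-order independent.
`run_strong_condition_suite()` verifies the exact-fit corollaries: when the
realized error scatter is diagonal, every estimator attains loss zero and
returns diagonal variances equal to θ² + error variances.

Problem sizes used by the packaged checks: the bundled Monte-Carlo runs use
50 replications per cell (600 covariance matrices, all four estimators),
which resolves the grand means to a Monte-Carlo standard error of roughly
0.002–0.004 — small relative to the effects of interest; unit tests use
p between 3 and 12 with replication counts of 5–20.

## Interpretation: the variance decomposition

For any fitted solution, `variance_decomposition()` splits each observed
variance as v_j = ‖λ_j‖² + θ_j² + ev_j (communality, specific variance, error
variance); for the decomposition estimators the three parts reproduce
diag(C) exactly, for the latent-variable fits communality plus unique
variance does, and the error column is reported as missing rather than zero.
On a correlation matrix each row sums to 1, so entries read directly as
variance proportions. Varimax rotation (`varimax_rotate()`, Kaiser
normalization on by default, with a switch) is available for interpreting
loadings; communalities and all diagonal variances are rotation-invariant.

## Known limitations

* Oblique rotations, standard errors, likelihood-ratio tests and raw-data
  ingestion are out of scope.
* The minimum-rank solver is a local method; the barrier path makes it
  reliable on the design sizes here (p ≤ 24), where it matches grid-search
  oracles, but global optimality is not certified.
* The factor count m is taken as given, never estimated.
* With nominal sample size n entering only as a scale factor, none of the
  estimators here quantify sampling variability.
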