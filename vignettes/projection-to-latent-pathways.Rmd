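---
title: "Projection to latent pathways: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection to latent pathways: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plpath)
```

## The problem

A metabolic network with stoichiometric matrix $N$ ($m$ internal metabolites
by $q$ reactions) constrains every steady-state flux distribution $r$ to
$N r = 0$ with $r_k \ge 0$ on irreversible reactions. The solution set is a
polyhedral cone whose generating, support-minimal vectors are the elementary
flux modes (EFM): any observed flux distribution is a non-negative
combination

$$ r = \sum_{i=1}^{n_{em}} \lambda_i \, em_i, $$

where $em_i$ is a fixed vector of reaction weights (the mode's structure,
genetically determined) and $\lambda_i \ge 0$ is the mode's weighting factor
(its activity, environmentally modulated). Even small networks carry hundreds
of EFM, most of them inactive under any given culture condition.

`plpath` addresses the discrimination problem: given a matrix $X$
($n_p$ observations of $n_x$ environmental variables — the envirome: pH,
osmolarity, nutrient and metabolite concentrations) and a matrix $R$ ($n_p$
observations of measured exchange fluxes), find the small subset of candidate
EFM whose weighting factors are simultaneously (i) large enough to explain
the flux variance and (ii) well predicted from the envirome. This is a
covariance-maximisation problem between $X$ and $R$ constrained to the flux
cone structure,

$$ \max \ \mathrm{cov}(X, R) \quad \text{s.t.} \quad R = \Lambda\,EM^{\mathsf T}, \qquad \Lambda = X C^{\mathsf T}, $$

solved greedily by projection to latent pathways (PLP), a constrained variant
of partial least squares (PLS) in which the response loadings are not free
directions but candidate EFM.

## The NIPALS-PLS core

`fit_pls()` implements the classic NIPALS sequence per latent variable:
$u = Yq$, $w = X^{\mathsf T}u / \lVert X^{\mathsf T}u \rVert$, $t = Xw$,
$q = Y^{\mathsf T}t / \lVert Y^{\mathsf T}t \rVert$, iterated until
$\lVert t - t_{old} \rVert < \varepsilon$ (default $10^{-8}$), then
$p = X^{\mathsf T}t / t^{\mathsf T}t$ rescaled to unit length (with $t$ and
$w$ multiplied by $\lVert p \rVert$), inner coefficient
$b = u^{\mathsf T}t / t^{\mathsf T}t$, and deflation
$X \leftarrow X - t p^{\mathsf T}$, $Y \leftarrow Y - b\, t q^{\mathsf T}$.
For a single-column $Y$ the response loading is identically 1 and no
iteration occurs.

Three implementation decisions matter here:

* **Y-deflation uses $q^{\mathsf T}$.** The rank-one response update is
  $b\,t\,q^{\mathsf T}$; this is the only dimensionally consistent deflation
  and the one that makes the overall decomposition
  $Y = U Q^{\mathsf T} + E_Y$ hold.
* **Exact regression coefficients.** Because each component's weights apply
  to the *deflated* predictor block, the naive product
  $RC = Q\,B\,W^{\mathsf T}$ does not reproduce the NIPALS fitted values from
  the original $X$. The package stores
  $RC = Q\,B\,[W(P^{\mathsf T}W)^{-1}]^{\mathsf T}$, where
  $P^{\mathsf T}W$ is unit upper triangular; with this correction,
  full-component PLS on full-rank data coincides with ordinary least squares
  to machine precision (a property the test suite asserts at $10^{-6}$).
* **Preprocessing.** Predictors are autoscaled (mean 0, unit variance) by
  default — standard chemometrics practice, and the scale on which
  "% explained variance of $X$" is meaningful; responses are centered but
  never scaled, because the response loadings of PLP are EFM expressed in
  flux units and rescaling columns of $R$ would silently rescale the modes.
  Explained-variance percentages are therefore reported on the centered flux
  scale. A `raw` policy is available for both choices.

The convergence criterion is absolute, as is conventional; the iteration cap
defaults to 100000 because near-degenerate singular-value pairs of
$X^{\mathsf T}Y$ — routine in late components of noisy blocks — slow the
power iteration to thousands of sweeps (each sweep costs microseconds at
these block sizes). Hitting the cap is an error, never a warning: an
unconverged component would silently poison downstream mode selection. A rank
guard stops extraction when a score norm collapses below $10^{-12}$ of the
first component's, and requesting more components than the predictor rank is
refused up front.

## The PLP selection loop

`select_efms()` iterates over a candidate mode library:

1. For every remaining candidate $em_k$ (restricted to the measured fluxes
   and scaled to unit Euclidean norm by default), compute the weighting
   factor $\lambda_k = R\,em_k$ on the current flux residual.
2. Fit an inner *univariate* PLS of $X$ onto $\lambda_k$ with `Fac` latent
   variables (default 4) and obtain $\hat\lambda_k$.
3. Score the candidate by the explained variance of the residual block by
   the rank-one reconstruction $\hat R_k = \hat\lambda_k\,em_k^{\mathsf T}$,
   $$ var_k = 100\left(1 - \frac{\sum (R - \hat R_k)^2}{\sum R^2}\right), $$
   together with $r^2 = \mathrm{cor}(\lambda_k, \hat\lambda_k)^2$ and the
   two-sided p-value of that correlation
   ($t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom).
4. Take the candidate with the highest $var_k$ (ties broken by lower mode
   id). Accept it only if $r^2 > 0.75$, $p < 0.05$, and the marginal gain in
   explained flux variance is at least `min_variance_gain` (default $10^{-6}$
   of the total sum of squares, operationalizing "the explained variance does
   not increase any further"). Otherwise stop.
5. Deflate $R \leftarrow R - \hat R_k$, remove the mode, repeat until the
   gate fails or `max_efms` is reached.

The loop picks the best candidate *first* and then applies the correlation
gate, so the accepted mode always dominates every remaining candidate's
$var_k$ at its iteration — a property the tests re-verify by exhaustive
re-scoring.

Choices the method description leaves open, and what this package does:

* **Candidate normalization.** Modes are scaled to unit norm over the
  measured fluxes before projection, so $var_k$ comparisons are invariant to
  each mode's arbitrary scaling. `efm_normalization = "raw"` disables this.
* **No predictor deflation between modes.** Each inner univariate PLS
  restarts from the full envirome block; `deflate_x = TRUE` offers the
  alternative (deflating $X$ by each accepted inner model's X-decomposition).
* **$Var(\lambda)$** is reported as the inner model's explained variance of
  the weighting factor, on the centered scale.
* **Non-negativity of $\lambda$ is not enforced.** The projection
  $R\,em_k$ can go negative even though convex mode weights cannot; the
  fraction of negative entries per selected mode is reported as a diagnostic
  (`neg_lambda_frac`) rather than constrained away.
* **The p-value gate is weak by construction.** With `Fac` latent variables
  drawn from $n_x$ predictors, the inner PLS overfits a pure-noise weighting
  factor toward the ordinary-least-squares level ($\approx n_x/n_p$, not
  $Fac/n_p$), and the naive correlation test is then anti-conservative: in
  simulation at $n_p = 67$, $n_x = 26$ virtually every null candidate has
  $p < 0.05$, while fewer than 0.5% reach $r^2 > 0.75$. It is the $r^2$
  threshold that controls false selection; the p-value is kept for
  continuity with the method's published form and reported per mode.

## Bootstrap over random partitions

`run_bootstrap()` repeats the whole analysis over random half/half
calibration/validation splits (default $z = 200$), recording per run the
selected modes, the inner regression-coefficient vectors (on the autoscaled
envirome scale, so coefficients are comparable across variables), and the
calibration/validation explained flux variance of both PLP and a
full-component PLS fitted to the same calibration half. Splits are stratified
by experiment when labels are provided — bioreactor campaigns have strong
block structure and an unstratified split can starve a model of an entire
experiment; a plain uniform split is used otherwise. Per-run child seeds are
derived from the master seed by a counter scheme, so extending the run count
never changes earlier runs.

`selection_frequency()` reports selection counts divided by the total number
of runs. `coefficient_confidence()` summarises each mode's coefficient draws
by their mean $\bar B$ and standard deviation $S$ (denominator $z-1$ over the
runs where the mode was selected) and the interval
$\bar B \pm S\, t_{0.975,\,z - Fac}$. Note the interval's width is set by the
run-to-run *standard deviation*, not the standard error of the mean: it
describes where the coefficient from a random repartition falls (a
spread/prediction statement, calibrated at ~95% against replicate draws in
the tests), and it covers the mean of the draws essentially always. The
degrees of freedom use the global run count by default; `dof_policy =
"per_efm"` substitutes the mode's own selection count for modes selected in
only part of the runs.

## Elementary flux mode enumeration

`enumerate_efms()` computes the modes of small networks by the classical
tableau (double description) algorithm in exact integer arithmetic
(stoichiometries are scaled to integers via continued-fraction denominators;
rows are reduced by their gcd after every combination, with an overflow
guard). Reversible reactions are handled by splitting each into a forward and
a backward irreversible column. This choice is deliberate: in an
all-irreversible tableau the support of a combined row is exactly the union
of its parents' supports, which makes the classical adjacency pre-test (skip
a combination when another row's support fits inside the union) sound. A
mixed tableau that keeps signed "reversible" rows violates that premise —
combinations can cancel reaction coordinates, the combined support shrinks
below the union, and the pre-test then prunes true modes; this failure mode
was observed directly against an exhaustive oracle during development. After
the tableau completes, two-cycle artifacts of the split (forward+backward of
the same reaction) and anything containing them are dropped, modes are mapped
back to net fluxes, and a fully reversible mode — found once per orientation —
is deduplicated under a canonical orientation (first nonzero coefficient
positive), so each mode is counted once.

Soundness is enforced twice: every surviving mode must pass an exact
rank-based elementarity test (the nullspace of the internal stoichiometry
restricted to the mode's support must be one-dimensional), and the test suite
compares the full output against an independent exhaustive enumeration over
all support subsets on dozens of random networks. Output is canonical —
modes scaled so the smallest nonzero absolute coefficient is 1, columns
sorted by support pattern then coefficients — so ids are stable across runs.
Enumeration is intended for tens of reactions; a configurable cap on
intermediate rows raises an explicit resource error instead of truncating.

`is_elementary()` exposes the rank test directly and, for decomposable
vectors, constructs a certificate: a sign-feasible steady-state vector with
strictly smaller support, found by cancelling a support component along a
second nullspace direction.

## The synthetic-data generator

Real envirome/fluxome campaigns of the kind this method targets are not
redistributable, so `generate_dataset()` builds datasets with known ground
truth at the same scale: 134 observations from 7 experiment blocks, 26
envirome variables, 24 measured fluxes, a 200-mode candidate library with 3
truly active modes, and 5% flux noise — these defaults are the package's
study conditions and all tests run against them.

The generative model reads the PLP decomposition forwards:

* Within each experiment, a few latent trajectories (random low-order Fourier
  series in batch time) are mixed by a loading matrix shared across
  experiments into the envirome $X$, plus 2% relative noise. This mimics
  smooth bioreactor profiles with block-to-block variation.
* Each active mode's weighting factor is
  $\lambda_i = \mathrm{softplus}(a + X_{std}\,c_i)$ with $a = 1$ and slope
  0.8. The softplus keeps weighting factors non-negative, as convex mode
  weights must be — a deliberate mild nonlinearity relative to a purely
  linear $\Lambda = XC^{\mathsf T}$, documented as such; in the near-linear
  regime used by the defaults the inner linear models still reach
  $r^2 > 0.9$ comfortably.
* Fluxes are $R = \Lambda\,EM_{active}^{\mathsf T}$ plus i.i.d. Gaussian
  noise with standard deviation `noise_sd_R` times the global signal RMS, so
  the unexplained variance share is exactly
  $s^2/(1+s^2)$ — the invariant the tests check.

The candidate library (`generate_efm_library()`) consists of sparse signed
mode footprints over the measured fluxes (each mode consumes some compounds
and produces others, support sizes 3–6), with the active modes' supports
mutually disjoint. Disjoint supports make the active modes orthogonal, which
is what guarantees that a greedy rank-one search scores a true mode above any
linear mixture; heavily overlapping active modes with correlated weighting
factors can in general defeat any greedy selector, and this generator does
not emulate that regime. Other aspects of real data the generator does not
reproduce: measurement error structure beyond i.i.d. Gaussian, missing
values (rejected at the IO layer by design), mechanistic kinetics, and modes
in full intracellular (rather than reduced exchange-flux) form. Passing the
recovery tests therefore demonstrates correctness of the machinery under the
stated conditions, not performance guarantees on arbitrary campaigns.

## Reproducibility and problem sizes

Every stochastic step is a pure function of its seed: dataset generation,
bootstrap partitions (counter-derived child seeds), and the CLI's `--seed`
flag. Output directories carry a `manifest.json` with the command, effective
configuration, input digests, package version and seed; determinism is
asserted on the data outputs by digest (the manifest itself contains a
timestamp and is excluded from that comparison).

The test suite and the acceptance script use the generator's default scale
throughout: 25 random networks of up to 8 reactions for the enumeration
oracle, 20 generator seeds for recovery and null-control, one dataset with
200 random half-splits for the PLP-versus-PLS comparison, and 200 simulated
runs of 400 coefficients for interval calibration. These sizes were chosen as
the smallest at which the Monte-Carlo slack quoted in the assertions is
comfortably above the simulation noise.

## Known limitations

* Enumeration is exact but combinatorial; it is meant for networks of tens of
  reactions, not genome scale (where mode counts reach millions).
* The greedy loop inherits greedy selection's usual caveat: it optimises one
  mode at a time and makes no claim of finding the best *subset*.
* The correlation p-value is not a calibrated error rate under the inner
  model's overfitting (see above); interpret Table-style reports through the
  $r^2$ column.
* Coefficient intervals describe resampling spread, not standard errors of
  means, and coefficients are reported on the autoscaled envirome scale.
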