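---
title: "Projection-based kinetics separation for TRXL data: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection-based kinetics separation for TRXL data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepcr)
```

## The signal model

A time-resolved X-ray liquidography (TRXL) dataset is a matrix of
difference scattering intensities $\Delta S(q, t)$ — post-excitation minus
pre-excitation scattering — on a momentum-transfer grid $q$ (Å$^{-1}$)
across pump–probe delays $t$ (ps). The package models each column as

$$\Delta S(q, t) = \frac{1}{R}\sum_k f_k(t)\,\mathrm{SADS}_k(q)
  + \Delta T(t)\left(\frac{\partial S}{\partial T}\right)_{\!\rho}
  + \Delta\rho(t)\left(\frac{\partial S}{\partial \rho}\right)_{\!T},$$

with $R$ the solvent:solute number ratio, $f_k(t)$ species molar fractions,
$\mathrm{SADS}_k(q)$ the species-associated difference curve (solute plus
its solvation cage, per unit concentration, scaled per solvent molecule by
$1/R$), and the two solvent differentials describing the bulk response to
heating and expansion. Negative delays are pre-excitation references and
carry noise only.

Two standing conventions, chosen deliberately:

* **All inner products act on $\Delta S$, never on $q\,\Delta S$.**
  Multiplying by $q$ is a display device for the weak high-$q$ signal; using
  it in the analysis would silently change every projection, SVD component
  and fit. Plots may rescale; the vectors do not.
* **Units are fixed**: $q$ in Å$^{-1}$, $t$ and all time constants in ps.

## Projection onto the complement of the trivial space

Given known curves $\{trv_1,\dots,trv_m\}$ (solvent differentials,
already-characterized species, or a measured column such as the curve at one
anchor delay), each delay column $v$ is split as

$$v = \sum_i w_{\mathrm{LS},i}\,trv_i + v_\perp,
  \qquad v_\perp \cdot trv_i = 0 \;\forall i,$$

where the weights are the least-squares solution of $v \approx \sum_i x_i\,
trv_i$. The residual $v_\perp$ is unique (it depends only on the span of the
trivial set); the weights are not when the set is rank-deficient, so the
implementation returns the **minimum-norm** solution from an SVD of the
basis matrix with a relative singular-value cutoff (`rank_tol`, default
$10^{-10}$). This keeps reported weights deterministic for collinear or
duplicated components while leaving the residual untouched.

The consequence that drives the whole workflow: writing each true species
curve as $\mathrm{SADS}_k = \sum_i d_{k,i}\,trv_i + \mathrm{SADS}_{k,\perp}$,
the projected data are exactly
$\frac{1}{R}\sum_k f_k(t)\,\mathrm{SADS}_{k,\perp}(q)$ — the solvent
time-dependence $\Delta T(t), \Delta\rho(t)$ is *gone*, while every $f_k(t)$
survives unchanged. The price is that species shapes are distorted by
$-\sum_i d_{k,i}\,trv_i$; that distortion is linear, known up to the
$d$ coefficients, and undone during structural comparison (below).

Solves are per delay and unweighted by default, matching the plain
dot-product geometry of the decomposition; a `sigma_weighted` mode (whitened
least squares) exists for strongly heteroscedastic data but changes the
geometry and is therefore opt-in. No positivity or smoothness constraints
are placed on the weights — they are free linear coefficients.

An independent cross-check, `orthonormal_projection_oracle()`, computes the
same residual by modified Gram–Schmidt orthonormalization (two passes,
dropping vectors below the rank tolerance) with sequential subtraction; the
test suite requires agreement with the least-squares route to $10^{-10}$ on
random instances including rank-deficient sets.

## Kinetic analysis

**SVD and rank.** The projected matrix is decomposed as
$\mathrm{LSV}\cdot\mathrm{diag}(sv)\cdot\mathrm{RSV}^\top$. Each left
singular vector is sign-fixed so its largest-magnitude element is positive
(the matching right vector is flipped along), removing the arbitrary sign
from plots and tests. Signal-bearing components are selected by requiring,
cumulatively from the first component, lag-1 autocorrelation
$\sum_i v_i v_{i+1} / \sum_i v_i^2$ above 0.6 for *both* singular vectors
and a singular-value ratio above $10^{-3}$. The autocorrelation statistic is
the common TRXL practice (smooth vectors score near 1, white noise near 0);
the two thresholds are defaults with overrides, since no canonical values
exist — the rank can always be forced with `override`.

**Global exponential fitting.** The first $k$ right singular vectors are
fitted simultaneously with $\sum_j A_{ij}\, h(t;\tau_j)$ where $h$ is the
exact convolution of a causal exponential with a normalized Gaussian IRF of
FWHM $w$:

$$h(t) = \tfrac12 \exp\!\left(\frac{\sigma^2}{2\tau^2} -
  \frac{t-t_0}{\tau}\right)
  \operatorname{erfc}\!\left(\frac{\sigma}{\tau\sqrt2} -
  \frac{t-t_0}{\sigma\sqrt2}\right),\qquad
  \sigma = \frac{w}{\sqrt{8\ln 2}}.$$

Numerically this form overflows when $\tau \ll \sigma$; the implementation
evaluates it as $\tfrac12\,\mathrm{erfcx}(z)\,e^{-(t-t_0)^2/2\sigma^2}$ for
$z \ge 0$ (with an asymptotic-series branch of $\mathrm{erfcx}$ beyond the
range where the library routine is stable) and the direct form otherwise,
making it overflow-safe for any $\tau/\sigma$.

Time constants are shared across RSVs; amplitudes are per-RSV linear
parameters, profiled out analytically at every objective evaluation
(variable projection). The nonlinear search thus runs only over
$\log\tau$, bounded to $[0.1\,\Delta t_{\min},\, 10\,t_{\max}]$, from five
deterministic log-spaced starting ladders (Nelder–Mead then BFGS polish;
Brent for a single constant). Best final residual wins; exact ties go to the
lexicographically smallest sorted $\tau$ vector. With fixed starts the fit
is bit-reproducible. Per-RSV constant offsets and singular-value weighting
exist but default off; $t_0$ and the IRF width are user-supplied constants
by default since they are usually known from the experiment.

**Concentration profiles.** Sequential chains
$A_1 \to A_2 \to \dots \to$ ground use the Bateman closed form with each
eigen-decay convolved exactly through $h(t;\tau)$; general first-order rate
matrices go through eigendecomposition with per-mode convolution. Rates
coinciding within $10^{-9}$ relative (degenerate Bateman denominators),
complex eigenvalues, or a singular eigenvector matrix trigger a fallback:
dense `deSolve::lsoda` integration followed by numerical Gaussian
convolution on a fine grid. Fractions are clipped to $[0,1]$ only when the
violation is below $10^{-9}$ — larger excursions indicate a modeling error
and are surfaced, not hidden.

**Species extraction (kinetics-constrained analysis).** With profiles fixed,
$\Delta S_\perp \approx \frac{1}{R}\,\mathrm{SADS}\,C^\top$ is solved for
the species curves by least squares. When a truncation rank is supplied the
data are first replaced by their rank-$k$ reconstruction, so each recovered
curve is exactly a linear combination of the retained left singular vectors.
If the concentration matrix is ill-conditioned (condition number above
$10^{8}$ — species with indistinguishable kinetics) the solve refuses and
reports the condition number rather than returning an arbitrary mixture.

## Structural comparison on distorted curves

A projected species curve relates to the truth by
$\mathrm{SADS}_{k,\perp} = \mathrm{SADS}_k - \sum_i d_{k,i}\,trv_i$.
Against a candidate curve (e.g. from the Debye model below) the correction
weights $\alpha_{i,k}$ minimizing
$\lVert \mathrm{SADS}_{k,\perp} + \sum_i \alpha_{i,k}\,trv_i -
\mathrm{candidate}\rVert$ are a *linear* solve — never free nonlinear
parameters — so comparing against a candidate costs one Gram-system solve
and adds no fitting complexity. $\chi^2$ is the (optionally
uncertainty-weighted) residual sum of squares over $n_q - m$ degrees of
freedom ($m$ counts only the $\alpha$ parameters: structural parameters
enter through the candidate curve, not this solve). For the correct
candidate, $\alpha$ reproduces the generator's $d$ coefficients and
$\chi^2 \approx 0$; wrong structures cannot be rescued by any $\alpha$,
which is what makes discrimination work. `rank_candidates()` orders
candidates by this $\chi^2$, ties broken by label order.

Candidate curves come from a deliberately minimal Debye model:
$S(q) = \sum_{ij} f_i f_j \,\mathrm{sinc}(q\,r_{ij})$ with q-independent
scattering factors $f \approx Z$. Full Cromer–Mann form factors, DFT
geometries and MD-derived cage terms are out of scope — the discrimination
machinery, not quantitative modeling of any particular compound, is the
deliverable. Cage contributions are user-supplied curves or the
parameterized damped sinusoid
$A\,e^{-q^2 w^2}\sin(q r_0)/(q r_0)$ of `cage_curve()`.

## Solvent hydrodynamics

After the solute term $\frac1R \sum_k f_k(t)\mathrm{SADS}_k(q)$ is
subtracted, the remainder is decomposed per delay onto the two solvent
differentials — plain linear least squares, no coupling across delays. The
condition number (singular-value ratio) of the basis matrix is attached to
the result; above `cond_warn` (default 6.2, the ratio at cosine similarity
0.95 between normalized curves) the two-term solve is flagged as
ill-conditioned. That is precisely the water regime, where the two
differentials are nearly collinear; `temperature_only` mode then describes
the response with the heating term alone, recovering the combined amplitude
stably. Trace units follow the basis curves' scaling; the package carries
unit metadata but performs no thermodynamic conversion (deposited energy,
acoustic dynamics and the like are out of scope).

## The synthetic forward model

`simulate_dataset()` assembles the full signal model with stored ground
truth: concentration matrix, true and perpendicular species curves, the $d$
coefficients, solvent basis, $\Delta T(t)$, $\Delta\rho(t)$, the noiseless
matrix and the noise realization. Design choices:

* **Solvent basis geometry is constructed, not sampled.** Two smooth
  Gaussian-sum shapes are orthonormalized and recombined at an exact target
  cosine: 0.98 for the water-like (nearly collinear) case, 0.15 for the
  distinct case. The geometry thresholds hold by construction on any grid.
* **Solvent time profiles**: $\Delta T$ is an IRF-broadened step (prompt
  heating) plus a slower exponential rise (vibrational relaxation, default
  50 ps); $\Delta\rho$ is a delayed rise (expansion lags heating, default
  2 ns). Shapes are qualitative stand-ins; no experimental profile is
  reproduced.
* **Noise** is additive i.i.d. Gaussian, seeded (the RNG state is restored
  afterwards), with scale given either absolutely or relative to the
  root-mean-square of the noiseless matrix; an optional $1/q$ amplitude
  profile makes the noise uniform in the $q\,\Delta S$ display domain.
  Negative-delay columns contain noise only, by causality of every signal
  term.
* Two canned scenarios set the study conditions used throughout the tests:
  `sim_config_gtc_like()` — three sequential species at 1.7 ps / 1.0 ns /
  114 ns with a 0.48 ps IRF, 60 log-spaced delays from 0.1 ps to 1 µs plus
  negative references, $R = 1000$, solvent channels within a factor
  $\sim$2 of the solute-term Frobenius norm; and `sim_config_chi3_like()` —
  two known product pathways plus an optional hidden isomer whose
  default amplitude places its projection residual at roughly ten times the
  noise floor at 5% relative noise. The 5% noise level is the stress level
  used in the acceptance experiments; realistic SNR varies widely between
  beamlines.

What the generator does **not** emulate: detector artifacts (the horizontal
striping of real difference images), correlated noise between delays,
$q$-dependent systematic errors from imperfect scaling, and physically
calibrated solvent differentials. Passing tests therefore demonstrate the
correctness and calibration of the *algorithms* under the stated noise
model, not robustness to every experimental pathology.

## The null-hypothesis residual test

To test whether a dataset contains only known components, the data are
projected against the full trivial set and the Frobenius-norm fraction of
the residual over positive delays is compared against a noise floor — from
the uncertainty matrix when available, otherwise from the projected
negative-delay (noise-only) columns rescaled to the positive-delay count.
`signal_remains` is declared above `factor` times the floor. The factor
(default 3) is this package's operationalization — no quantitative criterion
is standard — and is exposed; calibration tests require at least 18/20 true
negatives on trivial-span data and 20/20 detections of the hidden-species
scenario at its default amplitude.

## Problem sizes and numerical tolerances

The test and acceptance experiments run at 300 $q$-points × 40–63 delays
with 1–5 trivial components — desk-scale versions of real datasets, chosen
so the full suite completes in seconds while every matrix dimension
(rank-deficient trivial sets, more species than significant components,
split sub-datasets) is still exercised. Core identities (reconstruction,
orthogonality, linearity, span invariance) are asserted at $10^{-10}$ to
$10^{-12}$ relative; recovery under 5% noise at the few-percent level
matching the estimator variance. Grid-equality checks use $10^{-9}$
relative; text output uses 15 significant digits so write/read round-trips
are lossless at double precision.

## Known limitations

* Sequential chains and general first-order networks only; no stretched or
  distributed-rate kinetics.
* The outer loop of structural refinement (optimizing atomic coordinates
  against the corrected-curve $\chi^2$) is intentionally not shipped; the
  analytic $\alpha$-solve is designed to sit inside such an optimizer.
* The projection removes exactly what it is told: a trivial curve that is
  itself noisy injects its noise into the residual. Measured anchor-delay
  curves should be averaged before use.
* No automatic discovery of trivial components — choosing what is "known"
  is the analyst's call.
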