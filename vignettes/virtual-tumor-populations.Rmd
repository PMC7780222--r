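---
title: "Virtual tumor populations: models, estimators and numerical choices"
author: "virtopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual tumor populations: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtopop)
```

# Overview

`virtopop` simulates and calibrates *virtual tumor populations*: ensembles of
in-silico patients whose growth dynamics are driven by spatially heterogeneous
coefficient fields, and whose patient-specific parameters are estimated from
noisy molecular-imaging data. The pipeline has four layers:

1. a **growth model** — the Fisher-KPP reaction-diffusion equation with
   spatially varying diffusion, growth rate and carrying capacity;
2. a **stochastic object model** for those coefficients — lumpy random
   fields, a standard construction in image science that guarantees
   non-negative, bounded realizations;
3. an **imaging model** — planar binned-mode emission computed tomography
   (ECT) with a Gaussian point-spread function and Poisson counting noise;
4. **estimators** — maximum likelihood (MLEM for linear lump bases,
   box-constrained quasi-Newton for nonlinear lump models),
   Metropolis-Hastings posterior sampling, and Monte-Carlo marginal
   likelihood for population hyperparameters.

This vignette records the scientific assumptions, the tunable parameters and
their defaults, and the numerical choices, in the same spirit as the methods
sections of other model-based analysis packages.

# Growth model

The tumor cell density $n(\mathbf{x},t)$ (cells/cm$^2$ in the planar setting)
evolves on a rectangular domain $V$ (default the unit square, in cm) as

$$\partial_t n \;=\; \nabla\cdot\big(D(\mathbf{x})\,\nabla n\big)
  \;+\; \rho(\mathbf{x})\, n\Big(1 - \frac{n}{\kappa(\mathbf{x})}\Big),
  \qquad \hat\nu\cdot\nabla n = 0 \text{ on } \partial V,$$

with diffusion $D \ge 0$ (cm$^2$/day), growth rate $\rho \ge 0$ (1/day) and
carrying capacity $\kappa > 0$ (cells/cm$^2$). Zero-flux boundaries mean no
cells enter or leave the domain, so pure diffusion conserves the total burden
$N(t) = \int_V n\,d\mathbf{x}$ — one of the solver's structural test oracles.
The initial condition is a well-localized Gaussian seed,
$n_0(\mathbf{x}) = \frac{N_0}{2\pi\sigma^2}
 \exp\!\big(-\|\mathbf{x}-\mathbf{x}_0\|^2/(2\sigma^2)\big)$,
with defaults $N_0 = 5$ cells, $\mathbf{x}_0 = (0.5, 0.5)$ and
$\sigma^2 = 10^{-4}$ cm$^2$.

A note on units: the growth term only balances dimensionally when $\rho$ has
units of 1/day and $\kappa$ the units of a density; the package adopts that
reading throughout (two-dimensional simulations, cells per cm$^2$).

## Discretization

Space is discretized on a node-centered uniform grid (`space_grid()`,
default $128^2$; spacing $h = 1/(N-1)$, nodes include the domain edges).
The diffusion operator is a finite-volume five-point stencil with
*arithmetic* face averaging of $D$; each node owns a control cell of width
$h$ ($h/2$ at the edges, matching the trapezoid quadrature weights used for
all spatial integrals). Interior face fluxes cancel pairwise, so the
trapezoid-weighted burden is conserved to rounding under $\rho \equiv 0$ —
this is exact by construction, not approximate. The boundary half-cell form
is algebraically the classical ghost-node Neumann treatment.

Time integration is an adaptive embedded Dormand-Prince Runge-Kutta 5(4)
pair implemented in C++ with mixed error control
(`rtol = 1e-6`, `atol = 1e-3` cells/cm$^2$ per step; `max_step = 5` days).
Rare negative undershoots are clipped to zero at output times and counted
(`$n_clipped`), preserving admissibility of the density for the Poisson
imaging means downstream. Non-finite states abort with a diagnostic.

One regime deserves a caution. With the default coefficient priors the
traveling-front width $\sqrt{D/\rho}$ (order $10^{-3}$ cm) is *below* the
grid spacing, so the numerical front speed is partly lattice-controlled.
The solver is consistent (the grid-refinement test holds on smooth,
front-resolved problems), but absolute invasion speeds in the under-resolved
regime should be read as properties of the discretized model. This matters
for the year-one burden magnitude discussed under *Known limitations*.

# Lumpy random fields

Each coefficient field is modeled as a lumpy-type random field

$$\varphi(\mathbf{x}) = \sum_{l=1}^{L} b_l\,
  \exp\!\Big(-\frac{\|\mathbf{x}-\mathbf{x}_l\|^2}{2\sigma_0^2}\Big),
  \qquad L \sim \mathrm{Poisson}(\bar L),\quad
  \mathbf{x}_l \stackrel{iid}{\sim} \mathrm{Unif}(V),\quad b_l = b_0,$$

written $LB(\bar L, b_0, \sigma_0^2)$. The lumps are *unnormalized*
Gaussians (a lump evaluated at its own center equals its amplitude), so
realizations are non-negative and bounded by $L \cdot b_0$ — exactly the
admissibility needed for the growth equation to be well-posed. By Campbell's
theorem the interior mean is $\bar L\, b_0\, 2\pi\sigma_0^2 / |V|$; the test
suite checks this against $10^4$ Monte-Carlo draws.

Two choices the construction leaves open were fixed once:

* Poisson draws above `max_lumps` are truncated (default
  `max(10 * mean_lumps, 200)`); with $\bar L \ll L_{max}$ truncation is a
  measure-zero event in practice.
* Lump centers may fall anywhere in $V$ including near the boundary; no
  reflection or periodic wrapping is applied.

The default *study-design priors* (`default_population_priors()`) are
$D \sim LB(20, 10^{-7}, 0.04)$, $\rho \sim LB(200, 0.25, 0.002)$ and
$\kappa \sim LB(100, 5\times 10^{7}, 0.1)$, in the units above. A tiny floor
(1 cell/cm$^2$) is applied to $\kappa$ so the logistic ratio stays defined
far from every lump.

Parameter vectors. A `lump_layout()` fixes which blocks of a field a flat
vector $\theta$ encodes: `"amplitudes"` (fixed centers and width; the linear
reconstruction basis, $N$ = number of centers), `"shared"` (free centers
with one common amplitude and width, $N = 2L_{max}+2$; the nonlinear MLE
parameterization) and `"free"` ($N = 3L_{max}$). Inactive lumps are encoded
as amplitude zero, and pack/unpack round-trips are exact.

# Imaging model

Binned-mode ECT data are independent Poisson counts per detector bin with
mean $\bar g_m = \int_V h_m(\mathbf{x})\, f(\mathbf{x})\, d\mathbf{x}$,
where $f$ is the particle activity (here proportional to the cell density,
or to the growth-rate field for a proliferation tracer) and

$$h_m(\mathbf{x}) = \frac{A}{2\pi\sigma_{blur}^2}
  \exp\!\Big(-\frac{\|\mathbf{x}-\mathbf{x}_m\|^2}{2\sigma_{blur}^2}\Big)$$

is a normalized Gaussian point-spread function times the gain $A$ (detected
photons per cell over the exposure). Imaging is treated as a snapshot of a
single time point; the exposure-time integral is absorbed into $A$. Bins are
a uniform grid of virtual pixel centers covering the field of view (default
$64\times 64$ on the unit square — planar detectors need not have physical
pixels, and the bin count is a design choice of the virtual system).
$\sigma_{blur} = 0.021$ cm corresponds to $\approx 500\,\mu$m FWHM
(`fwhm_from_sigma()`), the cell-density channel default; the growth-factor
channel uses $0.042$ cm ($\approx 1$ mm).

Quadrature vs closed form. For gridded activities, $\bar g$ is computed by
trapezoid quadrature, which factorizes over the axes (two small matrix
products). For lumpy activities the Gaussian-Gaussian convolution has the
exact closed form

$$\bar g_m = \sum_l A\, b_l\, \frac{\sigma_l^2}{\sigma_l^2+\sigma_{blur}^2}
  \exp\!\Big(-\frac{\|\mathbf{x}_m-\mathbf{x}_l\|^2}
  {2(\sigma_l^2+\sigma_{blur}^2)}\Big),$$

used both for the system matrix and as the independent oracle against which
the quadrature path is verified ($<10^{-6}$ relative on resolved grids).
The second channel's photon yield is tracer-specific and not derivable from
the cell-density channel; the default `gain_rho = 1e4` was chosen once to
give a few thousand expected counts per bin over the tumor for the default
growth-rate prior.

# Estimation

## Poisson likelihood and MLEM

The log-likelihood is $\ell(\theta \mid g) = \sum_m [g_m \ln \bar
g_m(\theta) - \bar g_m(\theta)]$ up to the data constant, with the
$0\ln 0 = 0$ convention and $-\infty$ when a bin with observed counts has
zero model mean. For the linear amplitudes basis, the MLEM multiplicative
update is run for a fixed `iterations` (default 5000) from the back
projection $\theta^{(0)} = H^\top g$, with no early stopping; the full
log-likelihood trace is stored so users can truncate. Iterates stay
non-negative and the trace is non-decreasing (asserted in the tests —
this is the EM monotonicity property, checked numerically, not assumed).
Zero-sensitivity basis columns are excluded; zero model means under
observed counts are floored inside the ratio only, with the likelihood left
honest.

## Nonlinear maximum likelihood

For the `"shared"` layout (free lump centers, common amplitude and width)
the likelihood is maximized by `optim(method = "L-BFGS-B")` with the
analytic gradient of the closed-form forward map and box constraints
(centers in the field of view, amplitude positive, lump variance in
$(0, 0.1]$ by default in the two-channel experiment). The problem is
non-convex; a small multi-start (default 3, the extra starts perturbed by
5% of the parameter scale) mitigates local maxima, and a non-converged
optimizer returns its best iterate with a warning rather than failing.

## Fisher information

For Poisson data $F_{nn'} = \sum_m \partial_n \bar g_m\, \partial_{n'}
\bar g_m / \bar g_m$; derivatives are analytic for the amplitudes and
shared layouts, central finite differences (relative step $10^{-5}$)
otherwise. `vcov()` on a fit inverts $F$ (pseudo-inverse with a warning if
singular — e.g. basis lumps with no data support). The tests verify $F$
against a Monte-Carlo average of numerical Hessians, and verify that the
sampling covariance of a two-parameter MLE at high counts matches
$F^{-1}$ within 50%.

## Metropolis-Hastings posterior sampling

The posterior over lump parameters is $p(\theta\mid g) \propto p_0(\theta)
L(\theta \mid g)$ with an i.i.d. uniform box prior (default $[0, 10^{10}]$
per amplitude). Each proposal perturbs `l_mcmc` randomly chosen lumps
(without replacement) by independent Gaussians; the kernel is symmetric, so
the acceptance probability is the plain posterior ratio. Moves that leave
the support (negative amplitudes, centers outside the domain) are rejected
through the prior's $-\infty$ log-density — no reflection. Chains started
at the maximum-likelihood estimate need little burn-in because that point
is also the posterior mode under the flat prior; when reconstruction
artifacts push a few amplitudes above the prior bound, the start is
projected onto the box (the constrained mode). Rejected steps repeat the
previous state exactly, and for linear layouts the mean counts are updated
incrementally from the perturbed columns, so a step costs
$O(M \cdot l_{mcmc})$.

# Virtual populations and biomarkers

`generate_vpp()` assembles an ensemble: coefficients given as priors are
redrawn per member, fixed coefficients and/or per-member initial conditions
(e.g. posterior samples of the imaged density) are passed through, and each
member is solved forward. Member $j$ re-seeds the generator at
`seed + j`, so any member can be regenerated in isolation and ensembles are
bitwise reproducible. A failed member is flagged and does not abort the
ensemble. Scalar biomarkers (`biomarker_sample()`) default to the burden
$N(t)$ at a requested day; `ensemble_summary()` reports the pointwise mean
and a $\pm 1$ sample standard deviation band (denominator $J-1$). The
integrated log-kill functional $\int \ln(n/n_0)$ is available for
treatment-evaluation workflows on stored paths.

# Population calibration

The marginal likelihood of the field hyperparameters
$\theta_p = (\bar L, b_0, \sigma_0^2)$ given an image database is
approximated per image by Monte Carlo,
$P(g_j \mid \theta_p) \approx \frac{1}{J'}\sum_{j'} P(g_j \mid f_{j'})$,
computed in log space with log-sum-exp. Field draws may be fresh per image
or shared across images (common random numbers); sharing is the default for
*comparisons* across candidate $\theta_p$, where it substantially reduces
Monte-Carlo noise in the argmax. `population_mle()` is a seeded grid search
only — the marginal likelihood is badly scaled and non-convex, so
gradient-based hyperparameter optimization is deliberately out of scope.
A caveat established empirically in the test suite: the $1/J'$ variance
scaling of the log-marginal estimate holds in the light-tailed regime
(smooth, overlapping field draws); with high-information images the
estimate is dominated by rare well-matching draws and converges more
slowly. Recovery of the true lump rate from 32 images at $J' = 256$
succeeds in $\ge 80\%$ of seeded repeats in the packaged study.

# What the synthetic data does and does not emulate

All data in this package are generated by its own forward models: lumpy
coefficient fields, deterministic growth solves, and Poisson counts through
a Gaussian-blur operator. That emulates intra- and inter-patient coefficient
heterogeneity, detector blur and shot noise — the dominant uncertainty
sources the estimators are designed for. It does **not** emulate: model
error (real tumors do not follow Fisher-KPP exactly), three-dimensional
propagation, attenuation or scatter, detector dead-time, list-mode
acquisition, reconstruction-induced noise correlations, or treatment
effects. Passing tests therefore demonstrate the internal consistency and
statistical correctness of the estimators under the assumed models, not
fidelity to any real imaging system or tumor.

# Problem sizes and reproducibility

The packaged tests and the results script use deliberately scaled problem
sizes chosen to exercise every claim at comfortable statistical resolution:
$128^2$ grids for the patient pipeline, $16^2$-$64^2$ virtual detectors,
$10^4$ draws for field-statistics checks, $J = 16$ member populations for
the design-magnitude check, 20 seeded repeats for hyperparameter recovery,
and 8000-step chains for posterior-moment checks. Every random stage takes
an explicit seed, and all sampling flows through R's generator, so runs are
bitwise reproducible.

# Known limitations

* **Year-one burden magnitude.** Under the default study priors the
  package's population-mean $N(365)$ computed by the test suite is of order
  $10^9$ cells, while the priors' stated design intent is order $10^8$. The
  discrepancy is structural, not a bug: the Campbell means of the default
  priors ($\bar\rho \approx 0.63$/day, $\bar\kappa \approx 3\times 10^9$
  cells/cm$^2$, $\bar D \approx 5\times10^{-7}$ cm$^2$/day) give a
  Fisher front speed near $10^{-3}$ cm/day, which saturates an
  appreciable fraction of a 1 cm$^2$ domain within a year. A smaller
  physical domain, a coarser (front-pinning) discretization, or smaller
  $D$ would each bring the magnitude down; the package keeps the stated
  hyperparameters and documents the computed value.
* **Identifiability.** Single-time-point density images cannot identify
  $D$ or $\kappa$ (and only weakly constrain $\rho$); the virtual
  population machinery treats those as randomized, never estimated, from
  such data.
* **Reconstruction artifacts.** The fixed lump basis has a nontrivial null
  space; MLEM estimates show amplitude artifacts that matter little for
  integrated biomarkers but are visible in the field. No regularization is
  applied.
* **High-dimensional sampling.** The random-walk sampler is adequate for
  the few-hundred-parameter amplitude posteriors used here; it is not a
  substitute for dimension-robust samplers in much larger parameterizations.
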