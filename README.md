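# virtopop

Patient-specific **virtual tumor populations** from reaction–diffusion
growth models and noisy molecular-imaging data.

Predicting how an individual tumor will grow requires parameters — local
diffusivity, proliferation rate, carrying capacity — that are never observed
directly; at best they are glimpsed through blurred, photon-starved images.
`virtopop` implements an end-to-end statistical framework for this setting,
aimed at researchers in mathematical oncology and imaging science:

* **Growth model.** The Fisher–KPP reaction–diffusion equation
  `∂n/∂t = ∇·(D∇n) + ρ n (1 − n/κ)` with zero-flux boundaries and spatially
  varying coefficients `β = (D, ρ, κ)`, solved by a conservative
  finite-volume stencil with adaptive Runge–Kutta time stepping (C++ core).
* **Coefficient heterogeneity.** Lumpy random fields
  `LB(L̄, b₀, σ₀²)`: a Poisson(L̄) number of unnormalized Gaussian lumps with
  amplitude `b₀` and width `σ₀²`, placed uniformly — non-negative, bounded
  realizations with interior mean `L̄·b₀·2πσ₀²/|V|` (Campbell's theorem).
* **Imaging model.** Planar binned-mode emission computed tomography:
  expected counts `ḡ_m = ∫ h_m(x) f(x) dx` with a Gaussian point-spread
  sensitivity `h_m` (gain `A`, blur `σ_blur`), and independent Poisson counts
  per bin.
* **Estimation.** Poisson maximum likelihood: the MLEM multiplicative
  iteration for linear lump bases, box-constrained quasi-Newton (analytic
  gradients) for nonlinear lump models, and Fisher-information uncertainty
  (`vcov()`); Metropolis–Hastings sampling of the amplitude posterior;
  Monte-Carlo marginal likelihood for calibrating `(L̄, b₀, σ₀²)` from an
  image database.
* **Prediction.** Virtual populations: ensembles of forward solves with
  estimated and/or randomized coefficients, summarized through scalar
  biomarkers such as the tumor burden `N(t) = ∫ n dx`.

The central fitting function is `fit_lumpy_mle()`, which returns a classed
model object with the standard `coef`, `logLik`, `fitted`, `residuals`,
`predict`, `simulate`, `vcov`, `plot` and `summary` methods.

## Worked example

Simulate a "true" patient from the study priors, image its cell density at
day 100, reconstruct, sample the posterior, and predict forward with a
virtual population:

```r
library(virtopop)

grid  <- space_grid(128)                      # 1 cm x 1 cm, 128 x 128 nodes
truth <- make_ground_truth(seed = 1, grid = grid, times = c(0, 100, 365))
truth$path
#> cell_density_path: 128 x 128 grid, 3 time points (t = 0 .. 365 days)
#>   final burden N(T) = 1.808e+09 cells

sys <- ect_system(nbins = 64, sigma_blur = 0.021, gain = 1e-3)
sys
#> ect_system: 64 x 64 bins on [0, 1] x [0, 1] cm
#>   sigma_blur = 0.021 cm (FWHM 495 um), gain = 0.001 photons/cell
set.seed(1001)
g <- sample_counts(forward_mean(sys, density_at(truth$path, 100), grid))

layout <- lump_layout("amplitudes", centers = lump_center_grid(25),
                      lump_variance = 1e-2 / 256)
fit <- fit_lumpy_mle(g, sys, layout, iterations = 5000)

chain <- run_chain(g, start = pmin(coef(fit), 1e10),
                   config = mh_config(l_mcmc = 3, sd_amplitude = 1e4,
                                      n_samples = 512),
                   prior = box_prior(0, 1e10), system = sys,
                   layout = layout, seed = 2001)
chain
#> lumpy_chain: 512 samples x 625 parameters
#>   acceptance rate: 0.330

n0_hat <- pmax(predict(fit, type = "field", grid = grid), 0)
pr  <- default_population_priors()
vpp <- generate_vpp(n0_hat, D = pr$D, rho = pr$rho, kappa = pr$kappa,
                    grid = grid, times = seq(100, 130, by = 10),
                    J = 16, seed = 3001)
ensemble_summary(vpp)
#>   time      mean       sd     lower     upper
#> 1  100 358485767        0 358485767 358485767
#> 2  110 248397652 20359684 228037968 268757336
#> 3  120 317580320 27427655 290152666 345007975
#> 4  130 379484306 33275797 346208509 412760104
```

Reading the output: the ground-truth tumor grows from 5 seeded cells to
`1.8e9` cells over a year; its day-100 image is reconstructed on a fixed
25 × 25 lump basis; the 512-step amplitude chain accepts 33% of proposals;
and the 16-member virtual population — which shares the reconstructed
initial condition (zero spread at day 100) but randomizes the unmeasured
coefficients — spreads to a ±1 sd band of roughly `3.3e7` cells by day 130.
The transient dip after day 100 is a known artifact of the unregularized
reconstruction: amplitude overshoots above the local carrying capacity relax
logistically before growth resumes.

A thin command-line front end over the same functions is installed at
`inst/cli/virtopop.R`:

```sh
Rscript inst/cli/virtopop.R experiment1 --seed 1 --out-dir runs/exp1
```

See the vignette (`vignettes/virtual-tumor-populations.Rmd`) for the model
assumptions, parameter defaults, numerical choices and known limitations.

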