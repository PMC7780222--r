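#' Study-design population priors for the coefficient fields
#'
#' The lumpy-field hyperparameters used throughout the in-silico
#' experiments, chosen so that the population-mean tumor burden after one
#' year is of order 1e8 cells:
#' `D ~ LB(20, 1e-7, 0.04)` (cm^2/day), `rho ~ LB(200, 0.25, 0.002)`
#' (1/day), `kappa ~ LB(100, 5e7, 0.1)` (cells/cm^2).
#'
#' @param domain sampling box for lump centers.
#' @return Named list of three [lump_prior()] objects.
#' @export
default_population_priors <- function(domain = c(0, 1, 0, 1)) {
  list(D = lump_prior(20, 1e-7, 0.04, domain = domain),
       rho = lump_prior(200, 0.25, 0.002, domain = domain),
       kappa = lump_prior(100, 5e7, 0.1, domain = domain))
}

#' Simulate a ground-truth tumor
#'
#' Draws one realization of each coefficient field from the population
#' priors, seeds the default 5-cell Gaussian initial condition at the domain
#' center, and integrates the growth model over the requested horizon. This
#' is the common "true patient" against which estimation and
#' virtual-population prediction are assessed.
#'
#' @param seed integer seed (fixed seed gives a bitwise-identical truth).
#' @param grid the [space_grid()] (default 128^2 on the unit square).
#' @param times output days; defaults to every 5 days from 0 to 365 (always
#'   including the imaging day if you keep the default `t0 = 100` grid).
#' @param priors coefficient priors as from [default_population_priors()].
#' @return List with `coefficients` (the three [lump_field()] draws),
#'   `path` (a `cell_density_path`), `burden`, `seed`.
#' @export
make_ground_truth <- function(seed = 1L, grid = space_grid(128),
                              times = seq(0, 365, by = 5),
                              priors = default_population_priors()) {
  set.seed(seed)
  fields <- list(D = sample_lump_field(priors$D),
                 rho = sample_lump_field(priors$rho),
                 kappa = sample_lump_field(priors$kappa))
  cs <- coefficient_set(fields$D, fields$rho, fields$kappa, grid)
  n0 <- gaussian_initial_condition(grid)
  path <- solve_rde(cs, n0, times)
  list(coefficients = fields, path = path, burden = tumor_burden(path),
       seed = seed, grid = grid)
}

#' Patient-specific pipeline: image, reconstruct, sample the posterior
#'
#' The first in-silico experiment end to end: simulate a ground-truth tumor,
#' image its cell density at day `t0` with the Gaussian-blur ECT model
#' (Poisson counts), reconstruct the density by MLEM on a fixed 25 x 25 lump
#' basis, run a Metropolis-Hastings chain over the lump amplitudes from the
#' MLE, and (optionally) generate virtual populations from the MLE and from
#' the posterior samples by randomizing the unmeasured coefficients.
#'
#' @param seed integer seed controlling every stage.
#' @param t0 imaging day.
#' @param t_end final prediction day.
#' @param grid simulation [space_grid()].
#' @param sigma_blur,gain,nbins imaging-system settings; defaults 0.021 cm
#'   blur (about 500 um FWHM), 1e-3 photons/cell, 64 x 64 bins.
#' @param basis_n,basis_box,basis_variance reconstruction basis: center-grid
#'   side, sub-domain box, lump variance.
#' @param mlem_iterations MLEM iteration count.
#' @param chain an [mh_config()] for the posterior chain.
#' @param prior_upper upper bound of the i.i.d. uniform amplitude prior.
#' @param J_mle size of the MLE-initialized virtual population (0 skips it).
#' @param J_post number of posterior samples used as virtual-population
#'   initial conditions (0 skips it; capped at the chain length).
#' @param vpp_times output days for the virtual populations.
#' @param priors population priors for the randomized coefficients.
#' @return List bundle: `truth`, `g`, `system`, `fit`, `chain`,
#'   `acceptance_rate`, and (if requested) `vpp_mle`, `vpp_post`.
#' @examples
#' \donttest{
#' b <- run_experiment1(seed = 1, grid = space_grid(48), nbins = 24,
#'                      mlem_iterations = 50,
#'                      chain = mh_config(n_samples = 32), J_mle = 0,
#'                      J_post = 0)
#' b$acceptance_rate
#' }
#' @export
run_experiment1 <- function(seed = 1L, t0 = 100, t_end = 365,
                            grid = space_grid(128),
                            sigma_blur = 0.021, gain = 1e-3, nbins = 64L,
                            basis_n = 25L, basis_box = c(0.35, 0.65),
                            basis_variance = 1e-2 / 256,
                            mlem_iterations = 5000L,
                            chain = mh_config(l_mcmc = 3L, sd_amplitude = 1e4,
                                              n_samples = 512L),
                            prior_upper = 1e10,
                            J_mle = 64L, J_post = 512L,
                            vpp_times = seq(t0, t_end, by = 5),
                            priors = default_population_priors()) {
  truth <- make_ground_truth(seed, grid = grid,
                             times = sort(unique(c(seq(0, t_end, by = 5), t0))),
                             priors = priors)
  n_t0 <- density_at(truth$path, t0)

  system <- ect_system(nbins = nbins, sigma_blur = sigma_blur, gain = gain,
                       fov = grid$domain)
  gbar <- forward_mean(system, n_t0, grid)
  set.seed(seed + 1000L)
  g <- sample_counts(gbar)

  layout <- lump_layout("amplitudes",
                        centers = lump_center_grid(basis_n, basis_box),
                        lump_variance = basis_variance)
  fit <- fit_lumpy_mle(g, system, layout, method = "mlem",
                       iterations = mlem_iterations)

  # start at the MAP: under the box prior this is the MLE projected onto the
  # prior support (MLEM artifacts can push a few amplitudes above the bound)
  start <- pmin(pmax(coef(fit), 0), prior_upper)
  ch <- run_chain(g, start = start, config = chain,
                  prior = box_prior(0, prior_upper),
                  system = system, layout = layout, seed = seed + 2000L)

  out <- list(truth = truth, g = g, system = system, fit = fit, chain = ch,
              acceptance_rate = ch$acceptance_rate, seed = seed)

  if (J_mle > 0L) {
    n0_hat <- pmax(predict(fit, type = "field", grid = grid), 0)
    out$vpp_mle <- generate_vpp(n0_hat, D = priors$D, rho = priors$rho,
                                kappa = priors$kappa, grid = grid,
                                times = vpp_times, J = J_mle,
                                seed = seed + 3000L)
  }
  if (J_post > 0L) {
    J_post <- min(J_post, nrow(ch$samples))
    idx <- round(seq(1, nrow(ch$samples), length.out = J_post))
    n0_list <- lapply(idx, function(i)
      pmax(synthesize(unpack_lumps(ch$samples[i, ], layout), grid), 0))
    out$vpp_post <- generate_vpp(n0_list, D = priors$D, rho = priors$rho,
                                 kappa = priors$kappa, grid = grid,
                                 times = vpp_times, seed = seed + 4000L)
  }
  out
}

#' Patient-specific pipeline with an added growth-factor channel
#'
#' The second in-silico experiment: in addition to the day-`t0` cell-density
#' image, a second (coarser, 1 mm FWHM) ECT channel images the growth factor
#' rho directly. The density is reconstructed by MLEM as before; rho is
#' estimated by nonlinear maximum likelihood over free lump centers with a
#' common amplitude and width (bounds: centers in the unit square, amplitude
#' positive, lump variance in (0, 0.1]). The virtual population then fixes
#' both the initial condition and the growth factor at their estimates and
#' randomizes only D and kappa.
#'
#' @inheritParams run_experiment1
#' @param sigma_blur_rho blur of the growth-factor channel (cm).
#' @param gain_rho photon yield of the growth-factor tracer (detected
#'   photons per unit rho over the exposure). Tracer yields are
#'   channel-specific; the default 1e4 gives a few thousand expected counts
#'   per bin over the tumor for the study-design rho prior.
#' @param L_max number of free lumps in the rho reconstruction.
#' @param rho_maxit,rho_starts optimizer budget for the nonlinear MLE.
#' @return List bundle: `truth`, the two count vectors `g_n`, `g_rho`, the
#'   two fits `fit_n`, `fit_rho`, and (if requested) `vpp`.
#' @export
run_experiment2 <- function(seed = 1L, t0 = 100, t_end = 365,
                            grid = space_grid(128),
                            sigma_blur = 0.021, sigma_blur_rho = 0.042,
                            gain = 1e-3, gain_rho = 1e4, nbins = 64L,
                            basis_n = 25L, basis_box = c(0.35, 0.65),
                            basis_variance = 1e-2 / 256,
                            mlem_iterations = 5000L,
                            L_max = 60L, rho_maxit = 200L, rho_starts = 3L,
                            J_mle = 64L,
                            vpp_times = seq(t0, t_end, by = 5),
                            priors = default_population_priors()) {
  truth <- make_ground_truth(seed, grid = grid,
                             times = sort(unique(c(seq(0, t_end, by = 5), t0))),
                             priors = priors)
  n_t0 <- density_at(truth$path, t0)
  rho_true <- synthesize(truth$coefficients$rho, grid)

  sys_n <- ect_system(nbins = nbins, sigma_blur = sigma_blur, gain = gain,
                      fov = grid$domain)
  sys_rho <- ect_system(nbins = nbins, sigma_blur = sigma_blur_rho,
                        gain = gain_rho, fov = grid$domain)
  set.seed(seed + 1000L)
  g_n <- sample_counts(forward_mean(sys_n, n_t0, grid))
  g_rho <- sample_counts(forward_mean_lumpy(sys_rho, truth$coefficients$rho))

  layout_n <- lump_layout("amplitudes",
                          centers = lump_center_grid(basis_n, basis_box),
                          lump_variance = basis_variance)
  fit_n <- fit_lumpy_mle(g_n, sys_n, layout_n, method = "mlem",
                         iterations = mlem_iterations)

  layout_rho <- lump_layout("shared", max_lumps = L_max)
  set.seed(seed + 1500L)
  fit_rho <- fit_lumpy_mle(g_rho, sys_rho, layout_rho, method = "nonlinear",
                           lower = c(rep(0, 2L * L_max), 1e-12, 1e-6),
                           upper = c(rep(1, 2L * L_max), Inf, 0.1),
                           n_starts = rho_starts, maxit = rho_maxit)

  out <- list(truth = truth, g_n = g_n, g_rho = g_rho,
              system_n = sys_n, system_rho = sys_rho,
              fit_n = fit_n, fit_rho = fit_rho, seed = seed)

  if (J_mle > 0L) {
    n0_hat <- pmax(predict(fit_n, type = "field", grid = grid), 0)
    rho_hat <- pmax(predict(fit_rho, type = "field", grid = grid), 0)
    out$vpp <- generate_vpp(n0_hat, D = priors$D, rho = rho_hat,
                            kappa = priors$kappa, grid = grid,
                            times = vpp_times, J = J_mle,
                            seed = seed + 3000L)
  }
  out
}
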