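# Shared fixtures: everything is generated in code at test time.

# brute-force lumpy-field evaluation: plain double loop over lumps and points,
# independent of the vectorized synthesize() path
naive_synthesize <- function(field, points) {
  out <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    acc <- 0
    for (l in seq_len(nrow(field$centers))) {
      d2 <- sum((points[p, ] - field$centers[l, ])^2)
      acc <- acc + field$amplitudes[l] * exp(-d2 / (2 * field$lump_variance))
    }
    out[p] <- acc
  }
  out
}

# closed-form mean counts of a single Gaussian lump under Gaussian blur
# (analytic Gaussian-Gaussian convolution, independent of the package paths)
closed_form_lump_counts <- function(system, center, amplitude, lump_var) {
  v <- lump_var + system$sigma_blur^2
  d2 <- (system$bin_centers[, 1] - center[1])^2 +
        (system$bin_centers[, 2] - center[2])^2
  system$gain * amplitude * lump_var / v * exp(-d2 / (2 * v))
}

# uniform-coefficient helper
const_coeffs <- function(grid, D = 0, rho = 0, kappa = 1e6) {
  coefficient_set(matrix(D, grid$nx, grid$ny),
                  matrix(rho, grid$nx, grid$ny),
                  matrix(kappa, grid$nx, grid$ny), grid)
}

# hand-rolled density path object for quadrature-only tests
fake_path <- function(slices, times, grid) {
  values <- array(unlist(slices), dim = c(grid$nx, grid$ny, length(slices)))
  structure(list(values = values, times = times, grid = grid, n_clipped = 0),
            class = "cell_density_path")
}

# the small imaging system used across estimation tests
toy_system <- function(nbins = 16, sigma_blur = 0.05, gain = 1) {
  ect_system(nbins = nbins, sigma_blur = sigma_blur, gain = gain)
}

# effective-sample-size-aware Monte-Carlo standard error for a chain mean
chain_se <- function(x) {
  n <- length(x)
  r <- suppressWarnings(stats::cor(x[-1], x[-n]))
  if (!is.finite(r)) r <- 0
  r <- min(max(r, 0), 0.99)
  stats::sd(x) / sqrt(n * (1 - r) / (1 + r))
}
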