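#' Binned-mode ECT imaging system
#'
#' Defines the continuous-to-discrete operator of a planar binned-mode
#' emission imaging system. Detector bin `m` at position \eqn{x_m} responds
#' to emission at \eqn{x} through the Gaussian sensitivity function
#' \deqn{h_m(x) = \frac{A}{2\pi\sigma_{blur}^2}
#'       \exp\left(-\frac{\|x - x_m\|^2}{2\sigma_{blur}^2}\right),}
#' i.e. a normalized point-spread function times the gain `A` (detected
#' photons per emitted cell over the exposure; the exposure-time integral is
#' absorbed into `A`, imaging being a single-time snapshot). Expected counts
#' are \eqn{\bar g_m = \int_V h_m(x) f(x)\,dx} for an activity `f`, and
#' observed counts are independent Poisson draws.
#'
#' @param nbins bins per side, `c(mx, my)` or a scalar; bins are a uniform
#'   grid of virtual pixel centers covering `fov`.
#' @param sigma_blur blur standard deviation (cm); e.g. 0.021 cm for a
#'   roughly 500 um FWHM system.
#' @param gain photon yield `A` (detected photons per cell).
#' @param fov field of view `c(x0, x1, y0, y1)` (cm).
#' @return An object of class `ect_system` with `bin_centers` (`M x 2`),
#'   per-axis center vectors `bx`, `by`, and bin count `M`.
#' @examples
#' sys <- ect_system(nbins = 64, sigma_blur = 0.021, gain = 1e-3)
#' @export
ect_system <- function(nbins = 64L, sigma_blur, gain = 1,
                       fov = c(0, 1, 0, 1)) {
  if (length(nbins) == 1L) nbins <- c(nbins, nbins)
  nbins <- as.integer(nbins)
  if (any(nbins < 1L)) stop("need at least one bin per side")
  if (!is.finite(sigma_blur) || sigma_blur <= 0)
    stop("sigma_blur must be a positive scalar")
  if (!is.finite(gain) || gain <= 0) stop("gain must be positive")
  dx <- (fov[2] - fov[1]) / nbins[1]
  dy <- (fov[4] - fov[3]) / nbins[2]
  bx <- fov[1] + (seq_len(nbins[1]) - 0.5) * dx
  by <- fov[3] + (seq_len(nbins[2]) - 0.5) * dy
  bin_centers <- cbind(rep(bx, times = nbins[2]), rep(by, each = nbins[1]))
  structure(list(nbins = nbins, bx = bx, by = by, bin_centers = bin_centers,
                 M = nrow(bin_centers), sigma_blur = sigma_blur,
                 gain = gain, fov = fov),
            class = "ect_system")
}

#' @export
print.ect_system <- function(x, ...) {
  cat(sprintf("ect_system: %d x %d bins on [%g, %g] x [%g, %g] cm\n",
              x$nbins[1], x$nbins[2], x$fov[1], x$fov[2], x$fov[3], x$fov[4]))
  cat(sprintf("  sigma_blur = %g cm (FWHM %.0f um), gain = %g photons/cell\n",
              x$sigma_blur, 1e4 * fwhm_from_sigma(x$sigma_blur), x$gain))
  invisible(x)
}

#' Gaussian FWHM / standard-deviation conversion
#'
#' `FWHM = 2 sqrt(2 ln 2) sigma`. A blur of sigma = 0.021 cm corresponds to
#' 494 um FWHM (500 um to the nearest 100 um); sigma = 0.042 cm to 989 um
#' (about 1 mm).
#'
#' @param sigma,fwhm Gaussian standard deviation / full width at half
#'   maximum, in the same length unit.
#' @return The converted value.
#' @export
fwhm_from_sigma <- function(sigma) 2 * sqrt(2 * log(2)) * sigma

#' @rdname fwhm_from_sigma
#' @export
sigma_from_fwhm <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Expected bin counts for a gridded activity
#'
#' Mean data \eqn{\bar g_m = \int_V h_m(x) f(x)\,dx}, computed by trapezoid
#' quadrature of the Gaussian sensitivity against the gridded activity. The
#' Gaussian kernel factorizes over the axes, so the quadrature reduces to two
#' small matrix products.
#'
#' @param system an [ect_system()].
#' @param f activity matrix (>= 0) on `grid` (e.g. a cell-density slice).
#' @param grid the [space_grid()] `f` lives on.
#' @return Length-`M` vector of expected counts (bin order column-major over
#'   the bin grid).
#' @export
forward_mean <- function(system, f, grid) {
  stopifnot(inherits(system, "ect_system"), inherits(grid, "space_grid"))
  f <- as.matrix(f)
  if (nrow(f) != grid$nx || ncol(f) != grid$ny)
    stop("activity does not match the grid")
  if (any(f < 0)) stop("activity must be non-negative")
  s2 <- system$sigma_blur^2
  pref <- system$gain / (2 * pi * s2)
  Ex <- exp(-outer(grid$x, system$bx, "-")^2 / (2 * s2))   # nx x Mx
  Ey <- exp(-outer(grid$y, system$by, "-")^2 / (2 * s2))   # ny x My
  wf <- f * outer(grid$wx, grid$wy)                        # weighted activity
  gbar <- pref * crossprod(Ex, wf) %*% Ey                  # Mx x My
  as.vector(gbar)
}

#' Expected bin counts for a lumpy activity (closed form)
#'
#' For a lumpy-type activity the bin mean has the Gaussian-Gaussian
#' convolution closed form
#' \deqn{\bar g_m = \sum_l A\, b_l \frac{\sigma_l^2}{\sigma_l^2 +
#'   \sigma_{blur}^2} \exp\left(-\frac{\|x_m - x_l\|^2}
#'   {2(\sigma_l^2 + \sigma_{blur}^2)}\right),}
#' evaluated exactly (no quadrature). This is the nonlinear forward map from
#' lump parameters to mean data; for an amplitudes-only layout it is linear
#' and equals the system matrix times theta.
#'
#' @param system an [ect_system()].
#' @param field a [lump_field()], or a parameter vector `theta` when `layout`
#'   is given.
#' @param layout optional [lump_layout()] used to decode `theta`.
#' @return Length-`M` vector of expected counts.
#' @export
forward_mean_lumpy <- function(system, field, layout = NULL) {
  stopifnot(inherits(system, "ect_system"))
  if (!is.null(layout)) field <- unpack_lumps(field, layout)
  stopifnot(inherits(field, "lump_field"))
  L <- nrow(field$centers)
  if (L == 0L) return(numeric(system$M))
  v <- field$lump_variance + system$sigma_blur^2
  amp <- system$gain * field$amplitudes * field$lump_variance / v
  d2 <- outer(system$bin_centers[, 1], field$centers[, 1], "-")^2 +
        outer(system$bin_centers[, 2], field$centers[, 2], "-")^2
  drop(exp(-d2 / (2 * v)) %*% amp)
}

#' System matrix for a fixed lump basis
#'
#' The `M x N` matrix whose column `l` is the mean data of the unit-amplitude
#' lump centered at the `l`-th basis center, computed with the
#' Gaussian-Gaussian convolution closed form. `H %*% theta` then gives the
#' mean counts of the amplitudes-only lumpy model.
#'
#' @param system an [ect_system()].
#' @param centers `N x 2` matrix of basis lump centers.
#' @param lump_variance common basis lump variance (cm^2).
#' @return `M x N` non-negative matrix.
#' @export
build_system_matrix <- function(system, centers, lump_variance) {
  stopifnot(inherits(system, "ect_system"))
  centers <- as.matrix(centers)
  v <- lump_variance + system$sigma_blur^2
  amp <- system$gain * lump_variance / v
  d2 <- outer(system$bin_centers[, 1], centers[, 1], "-")^2 +
        outer(system$bin_centers[, 2], centers[, 2], "-")^2
  amp * exp(-d2 / (2 * v))
}

#' Poisson count sample
#'
#' Draws independent Poisson counts per bin from the mean data, using R's
#' global random number generator.
#'
#' @param gbar non-negative vector of expected counts.
#' @return Integer count vector of the same length.
#' @export
sample_counts <- function(gbar) {
  if (any(gbar < 0)) stop("mean counts must be non-negative")
  stats::rpois(length(gbar), gbar)
}
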