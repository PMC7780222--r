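#' Coefficient fields for the growth equation
#'
#' Bundles and validates the three spatially varying coefficients of the
#' Fisher-KPP reaction-diffusion model: diffusion `D` (cm^2/day, >= 0),
#' growth rate `rho` (1/day, >= 0) and carrying capacity `kappa` (cells/cm^2,
#' > 0). Each may be given as a [lump_field()] (evaluated on the grid) or as
#' an `nx x ny` matrix.
#'
#' @param D,rho,kappa coefficient fields ([lump_field()] or matrix).
#' @param grid the [space_grid()] the solver will use.
#' @param kappa_floor small positive floor added where `kappa` would
#'   otherwise vanish far from every lump; keeps the logistic term defined.
#'   Default 1 cell/cm^2.
#' @return An object of class `coefficient_set` holding gridded matrices and,
#'   when supplied, the originating lump fields.
#' @export
coefficient_set <- function(D, rho, kappa, grid, kappa_floor = 1) {
  stopifnot(inherits(grid, "space_grid"))
  as_mat <- function(f, name) {
    v <- if (inherits(f, "lump_field")) synthesize(f, grid) else as.matrix(f)
    if (nrow(v) != grid$nx || ncol(v) != grid$ny)
      stop(sprintf("%s does not match the grid", name))
    v
  }
  Dm <- as_mat(D, "D"); rm_ <- as_mat(rho, "rho"); km <- as_mat(kappa, "kappa")
  if (any(Dm < 0)) stop("D must be non-negative everywhere")
  if (any(rm_ < 0)) stop("rho must be non-negative everywhere")
  km <- pmax(km, kappa_floor)
  if (any(km <= 0)) stop("kappa must be positive everywhere")
  structure(list(D = Dm, rho = rm_, kappa = km, grid = grid,
                 fields = list(D = if (inherits(D, "lump_field")) D,
                               rho = if (inherits(rho, "lump_field")) rho,
                               kappa = if (inherits(kappa, "lump_field")) kappa)),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("coefficient_set on", x$grid$nx, "x", x$grid$ny, "grid\n")
  for (nm in c("D", "rho", "kappa"))
    cat(sprintf("  %-5s in [%.3g, %.3g]\n", nm, min(x[[nm]]), max(x[[nm]])))
  invisible(x)
}

#' Gaussian initial tumor seed
#'
#' The initial cell density is an isotropic Gaussian
#' \eqn{n_0(x) = A \exp(-\|x - x_0\|^2 / (2\sigma^2))} with amplitude
#' \eqn{A = N_0 / (2\pi\sigma^2)}, so its integral over the plane equals the
#' seeded cell count \eqn{N_0}. The defaults place 5 cells at the domain
#' center with \eqn{\sigma^2 = 10^{-4}} cm^2.
#'
#' @param grid a [space_grid()].
#' @param center seed location \eqn{x_0} (cm).
#' @param variance Gaussian variance \eqn{\sigma^2} (cm^2, > 0).
#' @param total_cells seeded cell count \eqn{N_0} (>= 0).
#' @return `nx x ny` density matrix (cells/cm^2).
#' @examples
#' g <- space_grid(256)
#' n0 <- gaussian_initial_condition(g)
#' grid_integral(n0, g)  # ~ 5 cells
#' @export
gaussian_initial_condition <- function(grid, center = c(0.5, 0.5),
                                       variance = 1e-4, total_cells = 5) {
  stopifnot(inherits(grid, "space_grid"))
  if (!is.finite(variance) || variance <= 0)
    stop("variance must be a positive scalar")
  if (total_cells < 0) stop("total_cells must be >= 0")
  A <- total_cells / (2 * pi * variance)
  ex <- exp(-(grid$x - center[1])^2 / (2 * variance))
  ey <- exp(-(grid$y - center[2])^2 / (2 * variance))
  A * outer(ex, ey)
}

#' Solve the Fisher-KPP reaction-diffusion equation
#'
#' Method-of-lines solution of
#' \deqn{\partial_t n = \nabla\cdot(D \nabla n) + \rho\, n (1 - n/\kappa)}
#' with zero-flux (Neumann) boundaries on the grid's rectangular domain.
#' Space is discretized with the conservative five-point stencil
#' (face-averaged D), time with an adaptive embedded Dormand-Prince
#' Runge-Kutta 5(4) pair. Negative undershoots from time integration are
#' clipped to zero at output times and counted.
#'
#' @param coeffs a [coefficient_set()].
#' @param n0 initial density matrix (cells/cm^2, >= 0) on the same grid.
#' @param times increasing output times (days) starting at the initial time.
#' @param rtol,atol relative / absolute (cells/cm^2) time-step error
#'   tolerances.
#' @param max_step upper bound on the internal step (days).
#' @return An object of class `cell_density_path`: `values` (an
#'   `nx x ny x nt` array), `times`, `grid`, and `n_clipped`.
#' @examples
#' g <- space_grid(32)
#' cf <- coefficient_set(matrix(0, 32, 32), matrix(0.1, 32, 32),
#'                       matrix(1e6, 32, 32), g)
#' p <- solve_rde(cf, matrix(10, 32, 32), times = c(0, 10))
#' @export
solve_rde <- function(coeffs, n0, times, rtol = 1e-6, atol = 1e-3,
                      max_step = 5) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  grid <- coeffs$grid
  n0 <- as.matrix(n0)
  if (nrow(n0) != grid$nx || ncol(n0) != grid$ny)
    stop("n0 does not match the grid")
  if (any(n0 < 0)) stop("n0 must be non-negative")
  times <- as.numeric(times)
  if (length(times) < 1L || is.unsorted(times, strictly = length(times) > 1L))
    stop("times must be increasing")
  res <- .solve_rde_cpp(as.numeric(coeffs$D), as.numeric(coeffs$rho),
                        as.numeric(coeffs$kappa), as.numeric(n0),
                        grid$nx, grid$ny, grid$hx, grid$hy,
                        times, rtol, atol, max_step)
  values <- array(res$values, dim = c(grid$nx, grid$ny, length(times)))
  structure(list(values = values, times = times, grid = grid,
                 n_clipped = res$n_clipped),
            class = "cell_density_path")
}

#' @export
print.cell_density_path <- function(x, ...) {
  cat(sprintf("cell_density_path: %d x %d grid, %d time points (t = %g .. %g days)\n",
              x$grid$nx, x$grid$ny, length(x$times),
              x$times[1], x$times[length(x$times)]))
  cat(sprintf("  final burden N(T) = %.4g cells\n",
              grid_integral(x$values[, , length(x$times)], x$grid)))
  invisible(x)
}

#' Extract a density slice at a stored time
#'
#' @param path a `cell_density_path`.
#' @param t requested time (days).
#' @param exact require `t` to be one of the stored output times; with
#'   `exact = FALSE` the nearest stored slice is returned.
#' @return `nx x ny` density matrix.
#' @export
density_at <- function(path, t, exact = TRUE) {
  i <- which.min(abs(path$times - t))
  if (exact && abs(path$times[i] - t) > 1e-9)
    stop(sprintf("time %g is not among the stored output times", t))
  path$values[, , i]
}

#' Tumor burden time series
#'
#' The scalar quantity of interest \eqn{N(t) = \int_V n(x, t)\,dx}, computed
#' by trapezoid quadrature for every stored time slice.
#'
#' @param path a `cell_density_path` from [solve_rde()].
#' @return Numeric vector of burdens (cells), one per stored time.
#' @export
tumor_burden <- function(path) {
  stopifnot(inherits(path, "cell_density_path"))
  vapply(seq_along(path$times),
         function(i) grid_integral(path$values[, , i], path$grid),
         numeric(1))
}

#' Integrated log-kill time series
#'
#' A treatment-evaluation quantity of interest: the burden integrand is
#' replaced by \eqn{\ln(n(x,t) / n_0(x))}, integrated over the support where
#' the reference density is positive.
#'
#' @param path a `cell_density_path`.
#' @param n0 reference density matrix (usually the initial condition).
#' @param support logical matrix selecting where to integrate; default
#'   `n0 > 0`. Must select at least one node.
#' @return Numeric vector, one value per stored time (dimensionless).
#' @export
integrated_log_kill <- function(path, n0, support = n0 > 0) {
  stopifnot(inherits(path, "cell_density_path"))
  n0 <- as.matrix(n0)
  if (!any(support)) stop("empty support: n0 must be positive somewhere")
  w <- outer(path$grid$wx, path$grid$wy) * support
  vapply(seq_along(path$times), function(i) {
    ratio <- path$values[, , i] / n0
    integrand <- ifelse(support, log(pmax(ratio, .Machine$double.xmin)), 0)
    sum(w * integrand)
  }, numeric(1))
}
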