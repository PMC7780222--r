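#' Node-centered computational grid on a rectangular domain
#'
#' Builds the uniform node-centered lattice used by the growth solver and the
#' imaging quadrature. With `nx` nodes per side the spacing is
#' `h = side / (nx - 1)` and the nodes include both domain edges; spatial
#' integrals use trapezoid weights, so a constant field integrates to exactly
#' the domain area.
#'
#' @param nx,ny number of nodes in x and y (`ny` defaults to `nx`).
#' @param domain domain box `c(x0, x1, y0, y1)` in cm; default the unit square.
#' @return An object of class `space_grid`: node coordinates `x`, `y`,
#'   spacings `hx`, `hy`, and trapezoid quadrature weights `wx`, `wy`.
#' @examples
#' g <- space_grid(64)
#' grid_integral(matrix(2, 64, 64), g)  # area * 2 = 2
#' @export
space_grid <- function(nx = 128L, ny = nx, domain = c(0, 1, 0, 1)) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L) stop("grid needs at least 2 nodes per side")
  if (length(domain) != 4L || domain[2] <= domain[1] || domain[4] <= domain[3])
    stop("domain must be c(x0, x1, y0, y1) with positive extents")
  x <- seq(domain[1], domain[2], length.out = nx)
  y <- seq(domain[3], domain[4], length.out = ny)
  hx <- (domain[2] - domain[1]) / (nx - 1)
  hy <- (domain[4] - domain[3]) / (ny - 1)
  wx <- rep(hx, nx); wx[c(1L, nx)] <- hx / 2
  wy <- rep(hy, ny); wy[c(1L, ny)] <- hy / 2
  structure(list(nx = nx, ny = ny, domain = domain, x = x, y = y,
                 hx = hx, hy = hy, wx = wx, wy = wy),
            class = "space_grid")
}

#' @export
print.space_grid <- function(x, ...) {
  cat(sprintf("space_grid: %d x %d nodes on [%g, %g] x [%g, %g] cm (h = %g)\n",
              x$nx, x$ny, x$domain[1], x$domain[2], x$domain[3], x$domain[4],
              x$hx))
  invisible(x)
}

#' Integrate a gridded field over the domain
#'
#' Trapezoid quadrature of a field sampled on a [space_grid()].
#'
#' @param values `nx x ny` matrix of field values.
#' @param grid a [space_grid()].
#' @return scalar integral.
#' @export
grid_integral <- function(values, grid) {
  stopifnot(inherits(grid, "space_grid"))
  if (!is.matrix(values) || nrow(values) != grid$nx || ncol(values) != grid$ny)
    stop("values must be an nx x ny matrix matching the grid")
  drop(grid$wx %*% values %*% grid$wy)
}

# all (x, y) node pairs as an (nx*ny) x 2 matrix, column-major like the field
grid_points <- function(grid) {
  cbind(rep(grid$x, times = grid$ny), rep(grid$y, each = grid$nx))
}
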