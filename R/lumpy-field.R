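#' Lumpy random-field realization
#'
#' A lumpy-type field is a finite sum of translated kernels,
#' \deqn{\varphi(x) = \sum_{l} b_l \, \ell(x - x_l; \sigma^2),}
#' here with isotropic *unnormalized* Gaussian lumps
#' \eqn{\ell(x; \sigma^2) = \exp(-\|x\|^2 / (2\sigma^2))}, so a lump evaluated
#' at its own center equals its amplitude. Because amplitudes are non-negative
#' and the lump count finite, every realization is non-negative and bounded —
#' the property that makes these fields admissible reaction-diffusion
#' coefficients.
#'
#' @param centers numeric `L x 2` matrix of lump centers (cm); may have zero
#'   rows for the empty field.
#' @param amplitudes numeric vector of non-negative lump amplitudes (field
#'   units), one per center.
#' @param lump_variance positive scalar lump variance \eqn{\sigma^2} (cm^2).
#' @param max_lumps maximum number of lumps this field's parameterization
#'   allows; defaults to the number of centers.
#' @return An object of class `lump_field`.
#' @seealso [sample_lump_field()], [synthesize()], [pack_lumps()]
#' @examples
#' f <- lump_field(rbind(c(0.4, 0.5), c(0.6, 0.5)), c(1, 2), 0.01)
#' g <- space_grid(32)
#' range(synthesize(f, g))
#' @export
lump_field <- function(centers, amplitudes, lump_variance,
                       max_lumps = nrow(centers)) {
  if (is.null(centers)) centers <- matrix(numeric(0), 0L, 2L)
  centers <- as.matrix(centers)
  if (nrow(centers) > 0L && ncol(centers) != 2L)
    stop("centers must be an L x 2 matrix")
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) != nrow(centers))
    stop("need one amplitude per lump center")
  if (any(amplitudes < 0)) stop("lump amplitudes must be non-negative")
  if (!is.numeric(lump_variance) || length(lump_variance) != 1L ||
      !is.finite(lump_variance) || lump_variance <= 0)
    stop("lump_variance must be a positive scalar")
  max_lumps <- as.integer(max_lumps)
  if (nrow(centers) > max_lumps)
    stop("number of lumps exceeds max_lumps")
  structure(list(centers = centers, amplitudes = amplitudes,
                 lump_variance = lump_variance, max_lumps = max_lumps),
            class = "lump_field")
}

#' @export
print.lump_field <- function(x, ...) {
  cat(sprintf("lump_field: %d lumps (max %d), sigma^2 = %g cm^2\n",
              nrow(x$centers), x$max_lumps, x$lump_variance))
  if (length(x$amplitudes))
    cat(sprintf("  amplitudes in [%g, %g]\n",
                min(x$amplitudes), max(x$amplitudes)))
  invisible(x)
}

#' Lumpy-field prior \eqn{LB(\bar L, b_0, \sigma_0^2)}
#'
#' Hyperparameters of the lumpy-type random field: the lump count is
#' Poisson(\eqn{\bar L}), centers are i.i.d. uniform on the domain box, all
#' amplitudes equal \eqn{b_0}, and all lumps share variance
#' \eqn{\sigma_0^2}. By Campbell's theorem, the mean field value at a point
#' well inside the domain is \eqn{\bar L b_0 2\pi\sigma_0^2 / |V|} in 2D.
#'
#' @param mean_lumps expected lump count \eqn{\bar L} (> 0).
#' @param amplitude common amplitude \eqn{b_0} (>= 0); units depend on the
#'   coefficient the field models (cm^2/day for D, 1/day for rho, cells/cm^2
#'   for kappa).
#' @param lump_variance common lump variance \eqn{\sigma_0^2} (cm^2, > 0).
#' @param domain sampling box `c(x0, x1, y0, y1)` for centers.
#' @param max_lumps truncation bound on the Poisson draw; Poisson realizations
#'   above it are truncated. Default `max(10 * mean_lumps, 200)`.
#' @return An object of class `lump_prior`.
#' @examples
#' pr <- lump_prior(20, 1e-7, 0.04)   # diffusion-coefficient prior
#' f <- sample_lump_field(pr)
#' @export
lump_prior <- function(mean_lumps, amplitude, lump_variance,
                       domain = c(0, 1, 0, 1),
                       max_lumps = max(ceiling(10 * mean_lumps), 200L)) {
  if (!is.finite(mean_lumps) || mean_lumps <= 0)
    stop("mean_lumps must be > 0")
  if (!is.finite(amplitude) || amplitude < 0)
    stop("amplitude must be >= 0")
  if (!is.finite(lump_variance) || lump_variance <= 0)
    stop("lump_variance must be > 0")
  structure(list(mean_lumps = mean_lumps, amplitude = amplitude,
                 lump_variance = lump_variance, domain = domain,
                 max_lumps = as.integer(max_lumps)),
            class = "lump_prior")
}

#' @export
print.lump_prior <- function(x, ...) {
  cat(sprintf("lump_prior: LB(%g, %g, %g) on [%g, %g] x [%g, %g]\n",
              x$mean_lumps, x$amplitude, x$lump_variance,
              x$domain[1], x$domain[2], x$domain[3], x$domain[4]))
  invisible(x)
}

#' Draw a lumpy-field realization from its prior
#'
#' Draws `L ~ Poisson(mean_lumps)` (truncated at `max_lumps`), places `L`
#' centers i.i.d. uniform on the prior's domain, and assigns every lump the
#' common amplitude and variance. Uses R's global random number generator;
#' seed with [set.seed()] for reproducibility.
#'
#' @param prior a [lump_prior()].
#' @return A [lump_field()].
#' @export
sample_lump_field <- function(prior) {
  stopifnot(inherits(prior, "lump_prior"))
  L <- min(stats::rpois(1L, prior$mean_lumps), prior$max_lumps)
  d <- prior$domain
  centers <- cbind(stats::runif(L, d[1], d[2]), stats::runif(L, d[3], d[4]))
  lump_field(centers, rep(prior$amplitude, L), prior$lump_variance,
             max_lumps = prior$max_lumps)
}

#' Evaluate a lumpy field on a grid or at points
#'
#' Synthesizes the continuous field \eqn{\sum_l b_l \exp(-\|x - x_l\|^2 /
#' (2\sigma^2))}. On a [space_grid()] the Gaussian lumps factorize over the
#' two axes, so evaluation is a pair of small matrix products.
#'
#' @param field a [lump_field()].
#' @param where a [space_grid()] (returns an `nx x ny` matrix) or an `n x 2`
#'   matrix of points (returns a length-`n` vector).
#' @return Matrix or vector of non-negative field values.
#' @export
synthesize <- function(field, where) {
  stopifnot(inherits(field, "lump_field"))
  s2 <- field$lump_variance
  L <- nrow(field$centers)
  if (inherits(where, "space_grid")) {
    if (L == 0L) return(matrix(0, where$nx, where$ny))
    # rank-L separable evaluation: field = Ux diag(b) Uy'
    Ux <- exp(-outer(where$x, field$centers[, 1], "-")^2 / (2 * s2))
    Uy <- exp(-outer(where$y, field$centers[, 2], "-")^2 / (2 * s2))
    Ux %*% (field$amplitudes * t(Uy))
  } else {
    pts <- as.matrix(where)
    if (ncol(pts) != 2L) stop("points must be an n x 2 matrix")
    if (L == 0L) return(numeric(nrow(pts)))
    d2 <- outer(pts[, 1], field$centers[, 1], "-")^2 +
          outer(pts[, 2], field$centers[, 2], "-")^2
    drop(exp(-d2 / (2 * s2)) %*% field$amplitudes)
  }
}

#' Parameter layouts for lumpy fields
#'
#' Describes which blocks of a lumpy field are encoded in a flat parameter
#' vector theta, defining the synthesis map from parameter space to field
#' realizations:
#' \describe{
#'   \item{`"amplitudes"`}{theta = lump amplitudes (length `max_lumps`);
#'     centers and variance fixed in the layout. Linear in theta — the basis
#'     used for MLEM reconstruction.}
#'   \item{`"shared"`}{theta = `(x_1..x_L, y_1..y_L, b, sigma^2)` (length
#'     `2 * max_lumps + 2`): free centers with one common amplitude and one
#'     common variance, the nonlinear-MLE parameterization.}
#'   \item{`"free"`}{theta = `(b_1..b_L, x_1..x_L, y_1..y_L)` (length
#'     `3 * max_lumps = (d+1) max_lumps` in d = 2); variance fixed.}
#' }
#' Inactive lumps are encoded as amplitude 0.
#'
#' @param type one of `"amplitudes"`, `"shared"`, `"free"`.
#' @param max_lumps number of lump slots.
#' @param centers fixed `max_lumps x 2` center matrix (required for
#'   `"amplitudes"`).
#' @param lump_variance fixed lump variance (required for `"amplitudes"` and
#'   `"free"`).
#' @return An object of class `lump_layout` with an `n_par` element.
#' @examples
#' ly <- lump_layout("amplitudes", centers = lump_center_grid(25),
#'                   lump_variance = 1e-2 / 256)
#' ly$n_par  # 625
#' @export
lump_layout <- function(type = c("amplitudes", "shared", "free"),
                        max_lumps = if (!is.null(centers)) nrow(centers) else NULL,
                        centers = NULL, lump_variance = NULL) {
  type <- match.arg(type)
  if (type == "amplitudes") {
    if (is.null(centers) || is.null(lump_variance))
      stop("amplitudes layout needs fixed centers and lump_variance")
    centers <- as.matrix(centers)
    max_lumps <- nrow(centers)
    n_par <- max_lumps
  } else if (type == "shared") {
    if (is.null(max_lumps)) stop("shared layout needs max_lumps")
    n_par <- 2L * max_lumps + 2L
  } else {
    if (is.null(max_lumps) || is.null(lump_variance))
      stop("free layout needs max_lumps and a fixed lump_variance")
    n_par <- 3L * max_lumps
  }
  structure(list(type = type, max_lumps = as.integer(max_lumps),
                 centers = centers, lump_variance = lump_variance,
                 n_par = as.integer(n_par)),
            class = "lump_layout")
}

#' Fixed reconstruction-basis center grid
#'
#' Uniformly spaced lump centers on a square sub-domain, the fixed basis used
#' for linear (amplitudes-only) image reconstruction.
#'
#' @param n grid side (n x n centers).
#' @param box sub-domain `c(lo, hi)` replicated on both axes; default
#'   `c(0.35, 0.65)`.
#' @return An `n^2 x 2` matrix of centers.
#' @export
lump_center_grid <- function(n = 25L, box = c(0.35, 0.65)) {
  s <- seq(box[1], box[2], length.out = n)
  cbind(rep(s, times = n), rep(s, each = n))
}

#' Pack a lumpy field into a flat parameter vector
#'
#' @param field a [lump_field()].
#' @param layout a [lump_layout()]; the field must be expressible in it
#'   (matching centers for `"amplitudes"`, common amplitude/variance for
#'   `"shared"`).
#' @return Numeric vector theta of length `layout$n_par`.
#' @seealso [unpack_lumps()] for the inverse; the round trip is exact.
#' @export
pack_lumps <- function(field, layout) {
  stopifnot(inherits(field, "lump_field"), inherits(layout, "lump_layout"))
  L <- nrow(field$centers)
  if (L > layout$max_lumps) stop("field has more lumps than the layout allows")
  if (layout$type == "amplitudes") {
    if (L != layout$max_lumps ||
        !isTRUE(all.equal(unname(field$centers), unname(layout$centers))))
      stop("amplitudes layout requires the field to use the layout's fixed centers")
    field$amplitudes
  } else if (layout$type == "shared") {
    b <- if (L) field$amplitudes[1] else 0
    if (L && any(field$amplitudes != b))
      stop("shared layout requires a common amplitude")
    cx <- c(field$centers[, 1], rep(0, layout$max_lumps - L))
    cy <- c(field$centers[, 2], rep(0, layout$max_lumps - L))
    c(cx, cy, b, field$lump_variance)
  } else {
    b <- c(field$amplitudes, rep(0, layout$max_lumps - L))
    cx <- c(field$centers[, 1], rep(0, layout$max_lumps - L))
    cy <- c(field$centers[, 2], rep(0, layout$max_lumps - L))
    c(b, cx, cy)
  }
}

#' Unpack a flat parameter vector into a lumpy field
#'
#' @param theta numeric vector of length `layout$n_par`.
#' @param layout a [lump_layout()].
#' @return A [lump_field()]. `unpack_lumps(pack_lumps(f, ly), ly)` synthesizes
#'   identically to `f`.
#' @export
unpack_lumps <- function(theta, layout) {
  stopifnot(inherits(layout, "lump_layout"))
  if (length(theta) != layout$n_par)
    stop(sprintf("theta has length %d but layout expects %d",
                 length(theta), layout$n_par))
  Lm <- layout$max_lumps
  if (layout$type == "amplitudes") {
    lump_field(layout$centers, theta, layout$lump_variance, max_lumps = Lm)
  } else if (layout$type == "shared") {
    centers <- cbind(theta[1:Lm], theta[(Lm + 1):(2 * Lm)])
    b <- theta[2 * Lm + 1]
    s2 <- theta[2 * Lm + 2]
    lump_field(centers, rep(b, Lm), s2, max_lumps = Lm)
  } else {
    b <- theta[1:Lm]
    centers <- cbind(theta[Lm + (1:Lm)], theta[2 * Lm + (1:Lm)])
    lump_field(centers, b, layout$lump_variance, max_lumps = Lm)
  }
}
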