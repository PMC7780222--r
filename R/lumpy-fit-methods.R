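#' @export
print.lumpy_fit <- function(x, ...) {
  cat(sprintf("Lumpy emission-model fit (%s), %d parameters, %d bins\n",
              x$method, length(x$coefficients), x$system$M))
  cat(sprintf("  log-likelihood (up to constant): %.4f\n", x$loglik))
  invisible(x)
}

#' Summarize a lumpy emission-model fit
#'
#' @param object a `lumpy_fit` from [fit_lumpy_mle()].
#' @param ... unused.
#' @return A `summary.lumpy_fit` object: counts, log-likelihood, parameter
#'   summaries, Pearson residual spread.
#' @export
summary.lumpy_fit <- function(object, ...) {
  gb <- fitted(object)
  pr <- residuals(object, type = "pearson")
  out <- list(method = object$method, n_par = length(object$coefficients),
              M = object$system$M, total_counts = sum(object$g),
              total_mean = sum(gb), loglik = object$loglik,
              iterations = object$iterations,
              coef_summary = summary(object$coefficients),
              pearson_sd = stats::sd(pr), converged = object$converged)
  class(out) <- "summary.lumpy_fit"
  out
}

#' @export
print.summary.lumpy_fit <- function(x, ...) {
  cat(sprintf("Lumpy emission-model fit (%s)\n", x$method))
  cat(sprintf("  bins: %d   parameters: %d\n", x$M, x$n_par))
  cat(sprintf("  observed counts: %d   fitted mean counts: %.1f\n",
              as.integer(x$total_counts), x$total_mean))
  cat(sprintf("  log-likelihood: %.4f", x$loglik))
  if (!is.na(x$iterations)) cat(sprintf("   (MLEM iterations: %d)", x$iterations))
  cat("\n  coefficients:\n")
  print(x$coef_summary)
  cat(sprintf("  Pearson residual sd: %.3f\n", x$pearson_sd))
  invisible(x)
}

#' @export
coef.lumpy_fit <- function(object, ...) object$coefficients

#' @export
logLik.lumpy_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$system$M, class = "logLik")
}

#' @export
fitted.lumpy_fit <- function(object, ...) {
  forward_mean_lumpy(object$system, object$coefficients, object$layout)
}

#' Residuals of a lumpy emission-model fit
#'
#' Pearson residuals \eqn{(g - \bar g)/\sqrt{\bar g}} or signed deviance
#' residuals of the Poisson model.
#'
#' @param object a `lumpy_fit`.
#' @param type `"pearson"` or `"deviance"`.
#' @param ... unused.
#' @export
residuals.lumpy_fit <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  g <- object$g
  gb <- pmax(fitted(object), .Machine$double.xmin)
  if (type == "pearson") {
    (g - gb) / sqrt(gb)
  } else {
    dev <- 2 * (ifelse(g > 0, g * log(g / gb), 0) - (g - gb))
    sign(g - gb) * sqrt(pmax(dev, 0))
  }
}

#' Predict from a lumpy emission-model fit
#'
#' @param object a `lumpy_fit`.
#' @param type `"response"` for expected bin counts (optionally under a
#'   different `system`), `"field"` for the synthesized activity field.
#' @param grid a [space_grid()] for `type = "field"`; defaults to a 128^2
#'   grid over the system field of view.
#' @param system optional alternative [ect_system()] for `type = "response"`.
#' @param ... unused.
#' @return Expected-count vector or field matrix.
#' @export
predict.lumpy_fit <- function(object, type = c("response", "field"),
                              grid = NULL, system = NULL, ...) {
  type <- match.arg(type)
  if (type == "response") {
    sys <- if (is.null(system)) object$system else system
    forward_mean_lumpy(sys, object$coefficients, object$layout)
  } else {
    if (is.null(grid)) grid <- space_grid(128, domain = object$system$fov)
    synthesize(unpack_lumps(object$coefficients, object$layout), grid)
  }
}

#' Simulate count data from a fitted lumpy model
#'
#' Parametric-bootstrap replicates: independent Poisson draws from the
#' fitted mean counts.
#'
#' @param object a `lumpy_fit`.
#' @param nsim number of replicate count vectors.
#' @param seed optional seed passed to [set.seed()].
#' @param ... unused.
#' @return `M x nsim` integer matrix.
#' @export
simulate.lumpy_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  gb <- fitted(object)
  matrix(stats::rpois(length(gb) * nsim, rep(gb, nsim)),
         ncol = nsim)
}

#' Asymptotic covariance of the maximum likelihood estimate
#'
#' The inverse of the Fisher information evaluated at the estimate. If the
#' information matrix is singular (e.g. basis lumps outside the data
#' support), the Moore-Penrose pseudo-inverse is returned with a warning.
#'
#' @param object a `lumpy_fit`.
#' @param ... unused.
#' @export
vcov.lumpy_fit <- function(object, ...) {
  Fm <- fisher_information(object$coefficients, object$layout, object$system)
  V <- tryCatch(solve(Fm), error = function(e) NULL)
  if (is.null(V)) {
    warning("Fisher information is singular; returning the pseudo-inverse")
    V <- .pinv(Fm)
  }
  V
}

#' Plot a lumpy emission-model fit
#'
#' Image of the synthesized activity field, with the basis lump centers
#' overlaid for fixed-center layouts.
#'
#' @param x a `lumpy_fit`.
#' @param grid a [space_grid()] to synthesize on (default 128^2 over the
#'   field of view).
#' @param show_centers overlay basis centers.
#' @param ... passed to [graphics::image()].
#' @export
plot.lumpy_fit <- function(x, grid = NULL, show_centers = TRUE, ...) {
  if (is.null(grid)) grid <- space_grid(128, domain = x$system$fov)
  f <- predict(x, type = "field", grid = grid)
  graphics::image(grid$x, grid$y, f, xlab = "x (cm)", ylab = "y (cm)",
                  main = "reconstructed activity", useRaster = TRUE, ...)
  if (show_centers && !is.null(x$layout$centers))
    graphics::points(x$layout$centers, pch = ".", col = "black")
  invisible(x)
}
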