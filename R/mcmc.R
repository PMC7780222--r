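#' Metropolis-Hastings chain configuration
#'
#' Settings for the random-walk sampler over lump parameters: each proposal
#' selects `l_mcmc` lump indices uniformly without replacement and perturbs
#' the free blocks (amplitude, center, width) of those lumps by independent
#' Gaussians with the given standard deviations. The proposal is symmetric,
#' so the Metropolis-Hastings ratio needs only the posterior densities.
#'
#' @param l_mcmc number of lumps perturbed per proposal.
#' @param sd_amplitude,sd_center,sd_width Gaussian proposal standard
#'   deviations per block; use 0 (or leave the block frozen by the layout)
#'   to keep a block fixed.
#' @param n_samples chain length.
#' @param burn_in samples discarded from the front (default 0: chains
#'   started at the MLE need little burn-in).
#' @return An object of class `mh_config`.
#' @export
mh_config <- function(l_mcmc = 3L, sd_amplitude = 1e4, sd_center = 0,
                      sd_width = 0, n_samples = 512L, burn_in = 0L) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (l_mcmc < 1L) stop("l_mcmc must be >= 1")
  if (any(c(sd_amplitude, sd_center, sd_width) < 0))
    stop("proposal standard deviations must be >= 0")
  structure(list(l_mcmc = as.integer(l_mcmc), sd_amplitude = sd_amplitude,
                 sd_center = sd_center, sd_width = sd_width,
                 n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in)),
            class = "mh_config")
}

#' Uniform box prior over lump parameters
#'
#' Independent uniform prior per parameter block. The log-density is a
#' constant inside the box and `-Inf` outside; with this prior, log-posterior
#' differences equal log-likelihood differences inside the support.
#'
#' @param lower,upper per-parameter bounds, recycled to the layout length
#'   (e.g. amplitudes i.i.d. uniform on `[0, 1e10]`).
#' @return An object of class `box_prior` with a `logdensity(theta)` field.
#' @export
box_prior <- function(lower = 0, upper = 1e10) {
  force(lower); force(upper)
  structure(list(lower = lower, upper = upper,
                 logdensity = function(theta) {
                   lo <- rep_len(lower, length(theta))
                   hi <- rep_len(upper, length(theta))
                   if (all(theta >= lo & theta <= hi)) 0 else -Inf
                 }),
            class = "box_prior")
}

#' Log-posterior of lump parameters given count data
#'
#' `log p0(theta) + loglik(theta | g)` up to an additive constant; `-Inf`
#' outside the prior support (a valid return, used by the sampler to reject
#' moves that leave the support, e.g. negative amplitudes).
#'
#' @param theta parameter vector.
#' @param g count vector.
#' @param prior a [box_prior()] (or any list with a `logdensity` function).
#' @param system an [ect_system()].
#' @param layout a [lump_layout()].
#' @return Scalar log-posterior.
#' @export
log_posterior <- function(theta, g, prior, system, layout) {
  lp <- prior$logdensity(theta)
  if (!is.finite(lp)) return(-Inf)
  lp + poisson_loglik(g, forward_mean_lumpy(system, theta, layout))
}

#' Symmetric block proposal over lump parameters
#'
#' Chooses `l_mcmc` lump indices uniformly without replacement and adds
#' independent Gaussian perturbations to the corresponding entries of each
#' free block. Blocks whose proposal standard deviation is 0, and blocks the
#' layout freezes (e.g. centers in an amplitudes-only layout), are left
#' untouched. The transition density is symmetric in (theta, theta').
#'
#' @param theta current parameter vector.
#' @param layout a [lump_layout()].
#' @param config an [mh_config()].
#' @return Proposed parameter vector theta'.
#' @export
mh_propose <- function(theta, layout, config) {
  Lm <- layout$max_lumps
  if (config$l_mcmc > Lm) stop("l_mcmc exceeds the number of lumps")
  idx <- sample.int(Lm, config$l_mcmc)
  k <- config$l_mcmc
  if (layout$type == "amplitudes") {
    if (config$sd_amplitude > 0)
      theta[idx] <- theta[idx] + stats::rnorm(k, 0, config$sd_amplitude)
  } else if (layout$type == "shared") {
    if (config$sd_center > 0) {
      theta[idx] <- theta[idx] + stats::rnorm(k, 0, config$sd_center)
      theta[Lm + idx] <- theta[Lm + idx] + stats::rnorm(k, 0, config$sd_center)
    }
    if (config$sd_amplitude > 0)
      theta[2 * Lm + 1] <- theta[2 * Lm + 1] + stats::rnorm(1, 0, config$sd_amplitude)
    if (config$sd_width > 0)
      theta[2 * Lm + 2] <- theta[2 * Lm + 2] + stats::rnorm(1, 0, config$sd_width)
  } else {
    if (config$sd_amplitude > 0)
      theta[idx] <- theta[idx] + stats::rnorm(k, 0, config$sd_amplitude)
    if (config$sd_center > 0) {
      theta[Lm + idx] <- theta[Lm + idx] + stats::rnorm(k, 0, config$sd_center)
      theta[2 * Lm + idx] <- theta[2 * Lm + idx] + stats::rnorm(k, 0, config$sd_center)
    }
  }
  theta
}

#' Metropolis-Hastings posterior sampling over lump parameters
#'
#' Random-walk Metropolis-Hastings targeting the posterior
#' `p(theta | g) proportional to p0(theta) L(theta | g)` with the symmetric
#' block proposal of [mh_propose()]. A proposal theta' is accepted with
#' probability `min(1, exp(logpost(theta') - logpost(theta)))`; on rejection
#' the previous state is repeated. For the linear amplitudes layout the mean
#' counts are updated incrementally from the system-matrix columns of the
#' perturbed lumps, so a step costs O(M l_mcmc).
#'
#' @param g count vector.
#' @param start starting parameter vector, typically the MLE (which for a
#'   flat prior is also the MAP, so little burn-in is needed).
#' @param config an [mh_config()].
#' @param prior a [box_prior()].
#' @param system an [ect_system()].
#' @param layout a [lump_layout()].
#' @param seed optional seed passed to [set.seed()].
#' @return An object of class `lumpy_chain`: `samples`
#'   (`n_samples x n_par`), `log_post` trace, `accepted` logical vector and
#'   `acceptance_rate` (accepted proposals / total samples).
#' @examples
#' sys <- ect_system(8, sigma_blur = 0.1, gain = 1)
#' ly <- lump_layout("amplitudes", centers = cbind(0.5, 0.5),
#'                   lump_variance = 0.02)
#' g <- sample_counts(forward_mean_lumpy(sys, c(theta = 300), ly))
#' ch <- run_chain(g, start = 300, config = mh_config(1, 50, n_samples = 200),
#'                 prior = box_prior(0, 1e6), system = sys, layout = ly,
#'                 seed = 1)
#' ch$acceptance_rate
#' @export
run_chain <- function(g, start, config, prior, system, layout, seed = NULL) {
  stopifnot(inherits(config, "mh_config"))
  if (!is.null(seed)) set.seed(seed)
  theta <- as.numeric(start)
  if (length(theta) != layout$n_par) stop("start does not match the layout")
  lp <- log_posterior(theta, g, prior, system, layout)
  if (!is.finite(lp)) stop("starting point has zero posterior density")

  n <- config$n_samples
  samples <- matrix(NA_real_, n, layout$n_par)
  log_post <- numeric(n)
  accepted <- logical(n)

  # incremental mean-count updates for the linear layout
  linear <- layout$type == "amplitudes"
  if (linear) {
    H <- build_system_matrix(system, layout$centers, layout$lump_variance)
    gbar <- drop(H %*% theta)
    ll <- function(gb) poisson_loglik(g, pmax(gb, 0))
  }

  for (i in seq_len(n)) {
    if (linear) {
      idx <- sample.int(layout$max_lumps, config$l_mcmc)
      delta <- stats::rnorm(config$l_mcmc, 0, config$sd_amplitude)
      theta_p <- theta
      theta_p[idx] <- theta_p[idx] + delta
      lpr <- prior$logdensity(theta_p)
      if (is.finite(lpr)) {
        gbar_p <- gbar + drop(H[, idx, drop = FALSE] %*% delta)
        lp_p <- lpr + ll(gbar_p)
      } else lp_p <- -Inf
    } else {
      theta_p <- mh_propose(theta, layout, config)
      lp_p <- log_posterior(theta_p, g, prior, system, layout)
    }
    if (is.finite(lp_p) && log(stats::runif(1)) < lp_p - lp) {
      theta <- theta_p
      lp <- lp_p
      if (linear) gbar <- gbar_p
      accepted[i] <- TRUE
    }
    samples[i, ] <- theta
    log_post[i] <- lp
  }

  keep <- if (config$burn_in > 0L) -(seq_len(config$burn_in)) else TRUE
  structure(list(samples = samples[keep, , drop = FALSE],
                 log_post = log_post[keep],
                 accepted = accepted,
                 acceptance_rate = mean(accepted),
                 config = config, layout = layout, start = start),
            class = "lumpy_chain")
}

#' @export
print.lumpy_chain <- function(x, ...) {
  cat(sprintf("lumpy_chain: %d samples x %d parameters\n",
              nrow(x$samples), ncol(x$samples)))
  cat(sprintf("  acceptance rate: %.3f\n", x$acceptance_rate))
  invisible(x)
}

#' @export
summary.lumpy_chain <- function(object, ...) {
  m <- colMeans(object$samples)
  s <- apply(object$samples, 2, stats::sd)
  out <- list(n = nrow(object$samples), n_par = ncol(object$samples),
              acceptance_rate = object$acceptance_rate,
              post_mean = m, post_sd = s,
              log_post_range = range(object$log_post))
  class(out) <- "summary.lumpy_chain"
  out
}

#' @export
print.summary.lumpy_chain <- function(x, ...) {
  cat(sprintf("Metropolis-Hastings chain: %d samples, %d parameters\n",
              x$n, x$n_par))
  cat(sprintf("  acceptance rate: %.3f\n", x$acceptance_rate))
  cat(sprintf("  log-posterior range: [%.2f, %.2f]\n",
              x$log_post_range[1], x$log_post_range[2]))
  cat(sprintf("  posterior mean range over parameters: [%.3g, %.3g]\n",
              min(x$post_mean), max(x$post_mean)))
  invisible(x)
}

#' @export
as.matrix.lumpy_chain <- function(x, ...) x$samples

#' Trace plot of a Metropolis-Hastings chain
#'
#' @param x a `lumpy_chain`.
#' @param pars indices of parameters to trace (default the 4 with the
#'   largest posterior mean).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lumpy_chain <- function(x, pars = NULL, ...) {
  if (is.null(pars))
    pars <- order(colMeans(x$samples), decreasing = TRUE)[seq_len(min(4, ncol(x$samples)))]
  graphics::matplot(x$samples[, pars, drop = FALSE], type = "l", lty = 1,
                    xlab = "iteration", ylab = "parameter value",
                    main = sprintf("MH trace (acceptance %.2f)",
                                   x$acceptance_rate), ...)
  invisible(x)
}
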