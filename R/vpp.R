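#' Generate a virtual tumor population
#'
#' Builds an ensemble of virtual patients: for each member, any coefficient
#' given as a [lump_prior()] is drawn fresh, fixed coefficients (gridded
#' matrices or [lump_field()]s) are shared, the growth equation is solved
#' from the given initial condition, and the burden curve is recorded. The
#' initial condition may itself vary per member (e.g. posterior samples of
#' the imaged density) by passing a list of matrices.
#'
#' @param n0 initial density: one `nx x ny` matrix shared by all members, or
#'   a list of `J` matrices (one per member).
#' @param D,rho,kappa coefficients: a [lump_prior()] (randomized per member)
#'   or a fixed [lump_field()] / matrix.
#' @param grid the [space_grid()].
#' @param times output times (days).
#' @param J population size (default `length(n0)` when `n0` is a list).
#' @param seed integer seed; member `j` uses seed `seed + j`, recorded in the
#'   result, so any member can be regenerated in isolation.
#' @param keep_paths store full density paths (memory-heavy) in addition to
#'   burden curves.
#' @param kappa_floor passed to [coefficient_set()].
#' @param rtol,atol,max_step solver settings, see [solve_rde()].
#' @return An object of class `virtual_population`: `burden` (`nt x J`
#'   matrix), `times`, `members` (per-member seeds, provenance, solver
#'   status), `grid`, optional `paths`.
#' @examples
#' g <- space_grid(24)
#' n0 <- gaussian_initial_condition(g, variance = 5e-3)
#' vp <- generate_vpp(n0, D = matrix(1e-6, 24, 24),
#'                    rho = lump_prior(50, 0.2, 0.01),
#'                    kappa = matrix(1e6, 24, 24),
#'                    grid = g, times = c(0, 50), J = 4, seed = 1)
#' @export
generate_vpp <- function(n0, D, rho, kappa, grid, times, J = NULL,
                         seed = 1L, keep_paths = FALSE, kappa_floor = 1,
                         rtol = 1e-6, atol = 1e-3, max_step = 5) {
  stopifnot(inherits(grid, "space_grid"))
  n0_list <- if (is.list(n0) && !is.matrix(n0)) n0 else NULL
  if (is.null(J)) J <- if (!is.null(n0_list)) length(n0_list) else stop("J is required")
  if (!is.null(n0_list) && length(n0_list) != J)
    stop("list n0 must have one matrix per member")
  J <- as.integer(J)
  if (J < 1L) stop("J must be >= 1")

  realize <- function(cf) {
    if (inherits(cf, "lump_prior")) sample_lump_field(cf) else cf
  }
  is_random <- vapply(list(D = D, rho = rho, kappa = kappa),
                      inherits, logical(1), what = "lump_prior")

  nt <- length(times)
  burden <- matrix(NA_real_, nt, J)
  members <- vector("list", J)
  paths <- if (keep_paths) vector("list", J) else NULL

  for (j in seq_len(J)) {
    member_seed <- as.integer(seed) + j
    set.seed(member_seed)
    Dj <- realize(D); rj <- realize(rho); kj <- realize(kappa)
    n0j <- if (!is.null(n0_list)) n0_list[[j]] else n0
    member <- list(seed = member_seed, randomized = names(is_random)[is_random],
                   ok = TRUE, error = NULL)
    path <- tryCatch({
      cs <- coefficient_set(Dj, rj, kj, grid, kappa_floor = kappa_floor)
      solve_rde(cs, n0j, times, rtol = rtol, atol = atol, max_step = max_step)
    }, error = function(e) e)
    if (inherits(path, "error")) {
      member$ok <- FALSE
      member$error <- conditionMessage(path)
      warning(sprintf("member %d failed: %s", j, member$error))
    } else {
      burden[, j] <- tumor_burden(path)
      if (keep_paths) paths[[j]] <- path
    }
    member$coefficients <- list(D = Dj, rho = rj, kappa = kj)
    members[[j]] <- member
  }

  structure(list(burden = burden, times = times, members = members,
                 grid = grid, J = J, seed = seed, paths = paths),
            class = "virtual_population")
}

#' @export
print.virtual_population <- function(x, ...) {
  ok <- vapply(x$members, `[[`, logical(1), "ok")
  cat(sprintf("virtual_population: J = %d members (%d ok), t = %g .. %g days\n",
              x$J, sum(ok), x$times[1], x$times[length(x$times)]))
  fin <- x$burden[nrow(x$burden), ok]
  if (length(fin))
    cat(sprintf("  final burden: mean %.4g, sd %.4g cells\n",
                mean(fin), stats::sd(fin)))
  invisible(x)
}

#' Scalar biomarker sample from a virtual population
#'
#' Evaluates a scalar quantity of interest for each member, producing the
#' virtual biomarker sample `Q` whose empirical distribution quantifies the
#' propagated heterogeneity/uncertainty. The default functional is the tumor
#' burden `N(t)` at a requested day (linearly interpolated between stored
#' times); any function of a member's burden curve can be supplied.
#'
#' @param vpp a `virtual_population`.
#' @param at day at which to read the burden (default: last stored time).
#' @param functional optional `function(burden, times)` overriding the
#'   default read-out.
#' @return An object of class `biomarker_sample`: numeric vector `Q` of
#'   length `J` with a `descriptor` attribute; `NA` for failed members.
#' @export
biomarker_sample <- function(vpp, at = NULL,
                             functional = NULL) {
  stopifnot(inherits(vpp, "virtual_population"))
  if (is.null(functional)) {
    if (is.null(at)) at <- vpp$times[length(vpp$times)]
    desc <- sprintf("tumor burden N(%g)", at)
    functional <- function(burden, times) stats::approx(times, burden, at)$y
  } else desc <- "user functional"
  Q <- vapply(seq_len(vpp$J), function(j) {
    b <- vpp$burden[, j]
    if (anyNA(b)) return(NA_real_)
    functional(b, vpp$times)
  }, numeric(1))
  structure(Q, descriptor = desc, class = c("biomarker_sample", "numeric"))
}

#' @export
print.biomarker_sample <- function(x, ...) {
  cat(sprintf("biomarker_sample: %s, J = %d\n", attr(x, "descriptor"),
              length(x)))
  print(summary(unclass(x)))
  invisible(x)
}

#' Pointwise ensemble mean and standard-deviation band
#'
#' Mean and mean +/- 1 sd (sample sd, denominator J - 1) of the member
#' burden curves at each stored time.
#'
#' @param x a `virtual_population` or an `nt x J` burden matrix.
#' @return Data frame with `time`, `mean`, `sd`, `lower`, `upper`.
#' @export
ensemble_summary <- function(x) {
  if (inherits(x, "virtual_population")) {
    burden <- x$burden; times <- x$times
  } else {
    burden <- as.matrix(x); times <- seq_len(nrow(burden))
  }
  if (ncol(burden) < 2L) stop("need at least 2 members for a sd band")
  m <- rowMeans(burden, na.rm = TRUE)
  s <- apply(burden, 1, stats::sd, na.rm = TRUE)
  data.frame(time = times, mean = m, sd = s, lower = m - s, upper = m + s)
}

#' Plot a virtual population's burden curves
#'
#' Member curves in grey with the ensemble mean and one-standard-deviation
#' band; optionally the true path for comparison.
#'
#' @param x a `virtual_population`.
#' @param truth optional reference burden curve on the same times.
#' @param log y-axis log scale.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.virtual_population <- function(x, truth = NULL, log = "y", ...) {
  b <- pmax(x$burden, .Machine$double.xmin)
  graphics::matplot(x$times, b, type = "l", lty = 1, col = "grey70",
                    log = log, xlab = "t (days)", ylab = "N(t) (cells)", ...)
  es <- ensemble_summary(x)
  graphics::lines(x$times, pmax(es$mean, .Machine$double.xmin), lty = 3, lwd = 2)
  graphics::lines(x$times, pmax(es$lower, .Machine$double.xmin), lty = 2)
  graphics::lines(x$times, pmax(es$upper, .Machine$double.xmin), lty = 2)
  if (!is.null(truth)) graphics::lines(x$times, truth, lwd = 2)
  invisible(x)
}

#' Monte-Carlo marginal log-likelihood of population hyperparameters
#'
#' The log-likelihood of the lumpy-field hyperparameters
#' `theta_p = (mean_lumps, amplitude, lump_variance)` given a database of
#' per-patient count vectors, with the per-image marginal
#' \deqn{P(g_j | \theta_p) = E_{f|\theta_p}[P(g_j | f)] \approx
#'   \frac{1}{J'} \sum_{j'} P(g_j | f_{j'})}
#' approximated by Monte Carlo over field draws and computed in log space
#' with log-sum-exp. Likelihood values are reported up to the additive
#' constant `-sum(lgamma(g + 1))`, which cancels when comparing
#' hyperparameter values on the same data.
#'
#' @param G `M x J` matrix of count vectors (one column per patient image).
#' @param prior a [lump_prior()] holding the hyperparameters to score.
#' @param system the [ect_system()] that produced the images.
#' @param Jprime Monte-Carlo sample size.
#' @param share_draws if `TRUE` (default) one set of `Jprime` field draws is
#'   shared across all images (common random numbers); if `FALSE` each image
#'   gets fresh draws.
#' @param seed optional seed passed to [set.seed()].
#' @param draws optional list of [lump_field()] realizations to use instead
#'   of sampling from `prior` (overrides `Jprime`); useful for enumeration
#'   checks and externally managed common random numbers.
#' @return Scalar log-likelihood; `-Inf` if some image has zero likelihood
#'   under every draw.
#' @export
population_loglik <- function(G, prior, system, Jprime = 256L,
                              share_draws = TRUE, seed = NULL, draws = NULL) {
  stopifnot(inherits(prior, "lump_prior"), inherits(system, "ect_system"))
  G <- as.matrix(G)
  if (nrow(G) != system$M) stop("G must have one row per detector bin")
  if (!is.null(seed)) set.seed(seed)
  J <- ncol(G)

  draw_means <- function(k) {
    if (!is.null(draws))
      return(vapply(draws, function(f) forward_mean_lumpy(system, f),
                    numeric(system$M)))
    vapply(seq_len(k),
           function(i) forward_mean_lumpy(system, sample_lump_field(prior)),
           numeric(system$M))
  }
  logsumexp <- function(v) {
    m <- max(v)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(v - m)))
  }
  img_ll <- function(g, GB) {
    # log-likelihood of image g under each drawn field (columns of GB)
    lls <- vapply(seq_len(ncol(GB)), function(i) poisson_loglik(g, GB[, i]),
                  numeric(1))
    logsumexp(lls) - log(ncol(GB))
  }

  if (share_draws) {
    GB <- draw_means(Jprime)
    total <- sum(vapply(seq_len(J), function(j) img_ll(G[, j], GB), numeric(1)))
  } else {
    total <- sum(vapply(seq_len(J),
                        function(j) img_ll(G[, j], draw_means(Jprime)),
                        numeric(1)))
  }
  total
}

#' Grid-search maximum likelihood for population hyperparameters
#'
#' Evaluates [population_loglik()] on a finite grid of candidate
#' hyperparameter triples, using common random numbers across grid points
#' (the same seed re-seeds the draw stream for every candidate) to reduce
#' Monte-Carlo noise in the comparison. Gradient-based optimization over the
#' hyperparameters is deliberately out of scope; the marginal likelihood is
#' non-convex and badly scaled.
#'
#' @param G `M x J` count matrix.
#' @param candidates data frame with columns `mean_lumps`, `amplitude`,
#'   `lump_variance` (one candidate per row).
#' @param system an [ect_system()].
#' @param Jprime Monte-Carlo size per evaluation.
#' @param seed seed re-used for every candidate (common random numbers).
#' @param domain center-sampling box for candidate priors.
#' @return List with `best` (the winning row, first encountered on ties),
#'   `loglik` vector over candidates, and `candidates`.
#' @export
population_mle <- function(G, candidates, system, Jprime = 256L, seed = 1L,
                           domain = c(0, 1, 0, 1)) {
  candidates <- as.data.frame(candidates)
  need <- c("mean_lumps", "amplitude", "lump_variance")
  if (!all(need %in% names(candidates)))
    stop("candidates needs columns mean_lumps, amplitude, lump_variance")
  ll <- vapply(seq_len(nrow(candidates)), function(i) {
    pr <- lump_prior(candidates$mean_lumps[i], candidates$amplitude[i],
                     candidates$lump_variance[i], domain = domain)
    population_loglik(G, pr, system, Jprime = Jprime, share_draws = TRUE,
                      seed = seed)
  }, numeric(1))
  best_i <- which.max(ll)
  list(best = candidates[best_i, , drop = FALSE], loglik = ll,
       candidates = candidates, best_index = best_i)
}
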