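test_that("a fully fixed single member reproduces a direct forward solve", {
  g <- space_grid(24)
  n0 <- gaussian_initial_condition(g, variance = 5e-3)
  D <- matrix(1e-5, 24, 24); rho <- matrix(0.08, 24, 24)
  kap <- matrix(1e6, 24, 24)
  vp <- generate_vpp(n0, D, rho, kap, g, times = c(0, 40, 80), J = 1, seed = 3)
  direct <- tumor_burden(solve_rde(coefficient_set(D, rho, kap, g), n0,
                                   c(0, 40, 80)))
  expect_equal(vp$burden[, 1], direct, tolerance = 1e-12)
})

test_that("virtual populations are reproducible from their seeds", {
  g <- space_grid(24)
  n0 <- gaussian_initial_condition(g, variance = 5e-3)
  pr <- lump_prior(30, 0.2, 0.01)
  make <- function() generate_vpp(n0, D = matrix(1e-6, 24, 24), rho = pr,
                                  kappa = matrix(1e6, 24, 24), g,
                                  times = c(0, 60), J = 4, seed = 99)
  v1 <- make(); v2 <- make()
  expect_identical(v1$burden, v2$burden)
  # bitwise-identical coefficient draws
  expect_identical(v1$members[[2]]$coefficients$rho$centers,
                   v2$members[[2]]$coefficients$rho$centers)
})

test_that("biomarker samples read the burden functional", {
  g <- space_grid(96)
  n0 <- gaussian_initial_condition(g)
  pr <- lump_prior(30, 0.2, 0.01)
  vp <- generate_vpp(n0, D = matrix(1e-6, 96, 96), rho = pr,
                     kappa = matrix(1e7, 96, 96), g,
                     times = c(0, 50, 100), J = 3, seed = 7)
  # all members share the 5-cell initial condition
  Q0 <- biomarker_sample(vp, at = 0)
  expect_equal(as.numeric(Q0), rep(5, 3), tolerance = 1e-3)
  # J members -> length-J sample; default functional reads the final burden
  Q <- biomarker_sample(vp)
  expect_length(Q, 3L)
  expect_equal(as.numeric(Q), vp$burden[3, ])
  # arbitrary functionals are supported
  Qf <- biomarker_sample(vp, functional = function(b, t) max(b))
  expect_equal(as.numeric(Qf), apply(vp$burden, 2, max))
})

test_that("burden distributions shift upward with the growth-amplitude hyperparameter", {
  g <- space_grid(48)
  n0 <- gaussian_initial_condition(g)
  mean_at_b0 <- function(b0) {
    vp <- generate_vpp(n0, D = matrix(1e-6, 48, 48),
                       rho = lump_prior(200, b0, 0.002),
                       kappa = matrix(5e8, 48, 48), g,
                       times = c(0, 100), J = 32, seed = 17)
    mean(biomarker_sample(vp, at = 100))
  }
  expect_gt(mean_at_b0(0.25), mean_at_b0(0.1))
})

test_that("ensemble summaries follow the sample-moment definitions", {
  tt <- 0:5
  c1 <- exp(0.1 * tt)
  b <- cbind(c1, 3 * c1)
  es <- ensemble_summary(b)
  expect_equal(es$mean, 2 * c1)
  expect_equal(es$sd, sqrt(2) * c1)   # sample sd with denominator J - 1
  expect_equal(es$upper - es$lower, 2 * es$sd)
  # identical members: zero-width band
  es0 <- ensemble_summary(cbind(c1, c1, c1))
  expect_equal(es0$sd, numeric(6))
  expect_error(ensemble_summary(cbind(c1)), "2 members")
})

test_that("population likelihood reduces to the plain Poisson likelihood for a forced draw", {
  sys <- toy_system(nbins = 8, sigma_blur = 0.08)
  truth <- lump_field(cbind(0.5, 0.5), 800, 0.01)
  set.seed(40)
  g <- sample_counts(forward_mean_lumpy(sys, truth))
  pr <- lump_prior(1, 800, 0.01)
  ll <- population_loglik(matrix(g), pr, sys, draws = list(truth))
  expect_equal(ll, poisson_loglik(g, forward_mean_lumpy(sys, truth)))
})

test_that("Monte-Carlo marginal likelihood converges to the exact two-outcome average", {
  # a prior with exactly two (essentially) distinct realizations: Poisson
  # lump count truncated at 1 with mean log(2) gives the empty field and the
  # single centered lump each with probability 1/2
  sys <- toy_system(nbins = 6, sigma_blur = 0.1)
  eps <- 1e-9
  pr <- lump_prior(log(2), 500, 0.005,
                   domain = c(0.5 - eps, 0.5 + eps, 0.5 - eps, 0.5 + eps),
                   max_lumps = 1)
  f1 <- lump_field(NULL, numeric(0), 0.005)
  f2 <- lump_field(cbind(0.5, 0.5), 500, 0.005)
  set.seed(41)
  g <- sample_counts(forward_mean_lumpy(sys, f2))
  ll1 <- poisson_loglik(g, forward_mean_lumpy(sys, f1))
  ll2 <- poisson_loglik(g, forward_mean_lumpy(sys, f2))
  m <- max(ll1, ll2)
  exact <- m + log((exp(ll1 - m) + exp(ll2 - m)) / 2)
  mc <- population_loglik(matrix(g), pr, sys, Jprime = 4096L, seed = 42)
  # MC error ~ binomial fluctuation of the draw frequencies
  expect_lt(abs(mc - exact), 0.2)
})

test_that("population grid search returns dominating candidates", {
  sys <- toy_system(nbins = 8, sigma_blur = 0.08)
  true_pr <- lump_prior(10, 100, 0.01)
  set.seed(50)
  G <- vapply(1:8, function(j)
    sample_counts(forward_mean_lumpy(sys, sample_lump_field(true_pr))),
    numeric(sys$M))
  # single-point grid returns that point
  one <- data.frame(mean_lumps = 10, amplitude = 100, lump_variance = 0.01)
  expect_equal(population_mle(G, one, sys, Jprime = 16, seed = 1)$best, one)
  # a zero-amplitude candidate has -Inf likelihood whenever counts are observed
  two <- data.frame(mean_lumps = c(10, 10), amplitude = c(0, 100),
                    lump_variance = 0.01)
  res <- population_mle(G, two, sys, Jprime = 32, seed = 1)
  expect_identical(res$best_index, 2L)
  expect_identical(res$loglik[1], -Inf)
})

test_that("Monte-Carlo likelihood noise scales like 1/Jprime", {
  # smooth, overlapping field draws keep the importance weights light-tailed,
  # the regime where the delta method gives var ~ 1/Jprime for the
  # log-marginal estimate
  sys <- toy_system(nbins = 2, sigma_blur = 0.1)
  pr <- lump_prior(20, 1, 0.05)
  set.seed(60)
  g <- sample_counts(forward_mean_lumpy(sys, sample_lump_field(pr)))
  vars <- sapply(c(16, 64, 256), function(jp) {
    vals <- sapply(1:40, function(r)
      population_loglik(matrix(g), pr, sys, Jprime = jp, seed = 7000 + r))
    var(vals)
  })
  expect_true(all(diff(vars) < 0))
  expect_gt(vars[1] / vars[3], 6)   # nominal 16
  expect_lt(vars[1] / vars[3], 45)
})
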