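test_that("Poisson log-likelihood matches hand-computed values", {
  # M = 2, g = (3, 1), gbar = (2, 2): 3 ln2 - 2 + 1 ln2 - 2
  expect_equal(poisson_loglik(c(3, 1), c(2, 2)), 4 * log(2) - 4)
  # all-zero counts: only the -gbar terms survive
  gbar <- c(0.5, 1.2, 3)
  expect_equal(poisson_loglik(c(0, 0, 0), gbar), -sum(gbar))
  # gbar = g > 0 is the unconstrained maximum: sum g (ln g - 1)
  g <- c(4, 7, 2)
  expect_equal(poisson_loglik(g, g), sum(g * (log(g) - 1)))
  # ... and no other gbar beats it
  set.seed(2)
  for (i in 1:10)
    expect_lte(poisson_loglik(g, runif(3, 0.1, 10)), poisson_loglik(g, g))
  # zero mean with observed counts has zero likelihood
  expect_identical(poisson_loglik(c(1, 0), c(0, 1)), -Inf)
  # 0 * ln 0 convention: zero count with zero mean is fine
  expect_equal(poisson_loglik(c(0, 2), c(0, 2)), 2 * log(2) - 2)
})

test_that("MLEM fixes its fixed points and increases the likelihood", {
  set.seed(42)
  H <- matrix(runif(20 * 5, 0.1, 1), 20, 5)
  theta_star <- runif(5, 0.5, 2)
  g_exact <- drop(H %*% theta_star)
  # data equal to the model mean: one update leaves theta unchanged
  res1 <- mlem(H, g_exact, theta0 = theta_star, iterations = 1)
  expect_equal(res1$theta, theta_star, tolerance = 1e-12)

  # noisy data: log-likelihood trace is non-decreasing over 200 iterations
  g <- rpois(20, g_exact * 50)
  res <- mlem(H, g, iterations = 200)
  expect_true(all(diff(res$trace) > -1e-8 * abs(res$trace[-1])))
  expect_true(all(res$theta >= 0))
})

test_that("high-count nonlinear MLE recovers a single-lump truth", {
  sys <- ect_system(32, sigma_blur = 0.042, gain = 1)
  truth <- c(x = 0.52, y = 0.47, b = 5000, s2 = 4e-3)
  g <- forward_mean_lumpy(sys, lump_field(cbind(0.52, 0.47), 5000, 4e-3))
  ly <- lump_layout("shared", max_lumps = 1)
  set.seed(3)
  fit <- fit_lumpy_mle(g, sys, ly, method = "nonlinear",
                       theta0 = c(0.5, 0.5, 3000, 0.01),
                       lower = c(0, 0, 1e-12, 1e-6),
                       upper = c(1, 1, Inf, 0.1))
  th <- coef(fit)
  expect_lt(abs(th[1] - truth["x"]), 1e-3)
  expect_lt(abs(th[2] - truth["y"]), 1e-3)
  expect_lt(abs(th[3] - truth["b"]) / truth["b"], 0.01)
  # box constraints honored
  expect_true(all(th[1:2] >= 0 & th[1:2] <= 1))
  expect_lte(th[4], 0.1)
})

test_that("MLE error shrinks as counts grow (consistency)", {
  sys <- toy_system()
  ly <- lump_layout("amplitudes", centers = lump_center_grid(3, c(0.4, 0.6)),
                    lump_variance = 5e-3)
  theta_star <- c(2, 5, 3, 8, 4, 1, 6, 2, 7)
  H <- build_system_matrix(sys, ly$centers, ly$lump_variance)
  err <- sapply(c(1e2, 1e5), function(scale) {
    set.seed(7)
    g <- rpois(sys$M, drop(H %*% theta_star) * scale)
    fit <- fit_lumpy_mle(g / scale, sys, ly, iterations = 2000)
    # MLEM on scaled data: rescale counts back to intensity units
    sqrt(mean((coef(fit) - theta_star)^2))
  })
  expect_lt(err[2], err[1])
})

test_that("Fisher information matches its definition and a Monte-Carlo oracle", {
  # one amplitude parameter, one bin: gbar = theta * h  ->  F = h / theta
  sys1 <- structure(list(nbins = c(1L, 1L), bx = 0.5, by = 0.5,
                         bin_centers = cbind(0.5, 0.5), M = 1L,
                         sigma_blur = 0.1, gain = 1, fov = c(0, 1, 0, 1)),
                    class = "ect_system")
  ly1 <- lump_layout("amplitudes", centers = cbind(0.5, 0.5),
                     lump_variance = 0.02)
  h <- drop(build_system_matrix(sys1, ly1$centers, ly1$lump_variance))
  theta <- 37
  expect_equal(fisher_information(theta, ly1, sys1)[1, 1], h / theta,
               tolerance = 1e-12)

  # small amplitudes model: analytic F vs -E[hessian of loglik] by simulation
  sys <- toy_system(nbins = 8, sigma_blur = 0.08)
  ly <- lump_layout("amplitudes",
                    centers = rbind(c(0.45, 0.5), c(0.55, 0.5), c(0.5, 0.6)),
                    lump_variance = 8e-3)
  th0 <- c(40, 60, 50)
  Fa <- fisher_information(th0, ly, sys)
  expect_equal(Fa, t(Fa))
  expect_true(all(eigen(Fa, symmetric = TRUE, only.values = TRUE)$values > -1e-10))

  H <- build_system_matrix(sys, ly$centers, ly$lump_variance)
  gbar0 <- drop(H %*% th0)
  num_hess <- function(g) {
    f <- function(th) poisson_loglik(g, drop(H %*% th))
    hh <- 1e-3 * th0
    Hm <- matrix(0, 3, 3)
    for (a in 1:3) for (b in 1:3) {
      ea <- eb <- numeric(3); ea[a] <- hh[a]; eb[b] <- hh[b]
      Hm[a, b] <- (f(th0 + ea + eb) - f(th0 + ea - eb) -
                   f(th0 - ea + eb) + f(th0 - ea - eb)) / (4 * hh[a] * hh[b])
    }
    Hm
  }
  set.seed(55)
  acc <- matrix(0, 3, 3)
  nrep <- 1000
  for (i in seq_len(nrep)) acc <- acc + num_hess(rpois(sys$M, gbar0))
  Fmc <- -acc / nrep
  expect_lt(max(abs(Fmc - Fa)) / max(abs(Fa)), 0.1)
})

test_that("sampling covariance of the MLE tracks the inverse Fisher information", {
  # 2-parameter well-conditioned linear model at high counts
  sys <- toy_system(nbins = 8, sigma_blur = 0.08)
  ly <- lump_layout("amplitudes", centers = rbind(c(0.4, 0.5), c(0.6, 0.5)),
                    lump_variance = 0.01)
  th0 <- c(4000, 7000)
  H <- build_system_matrix(sys, ly$centers, ly$lump_variance)
  gbar0 <- drop(H %*% th0)
  set.seed(66)
  ests <- t(replicate(300, {
    g <- rpois(sys$M, gbar0)
    mlem(H, g, theta0 = th0, iterations = 400)$theta
  }))
  V_emp <- stats::cov(ests)
  V_asy <- solve(fisher_information(th0, ly, sys))
  ratio <- diag(V_emp) / diag(V_asy)
  expect_true(all(ratio > 1 / 1.5 & ratio < 1.5))
})

test_that("lumpy_fit behaves like a standard fitted-model object", {
  sys <- toy_system(nbins = 8, sigma_blur = 0.08)
  ly <- lump_layout("amplitudes", centers = rbind(c(0.45, 0.5), c(0.55, 0.5)),
                    lump_variance = 0.01)
  H <- build_system_matrix(sys, ly$centers, ly$lump_variance)
  set.seed(12)
  g <- rpois(sys$M, drop(H %*% c(3000, 5000)))
  fit <- fit_lumpy_mle(g, sys, ly, iterations = 500)

  expect_s3_class(fit, "lumpy_fit")
  expect_length(coef(fit), 2L)
  expect_equal(fitted(fit), drop(H %*% coef(fit)), tolerance = 1e-10)
  expect_equal(as.numeric(logLik(fit)), poisson_loglik(g, fitted(fit)))
  expect_equal(residuals(fit), (g - fitted(fit)) / sqrt(fitted(fit)))
  expect_lt(abs(stats::sd(residuals(fit)) - 1), 0.35)
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sim), c(sys$M, 3L))
  V <- vcov(fit)
  expect_identical(dim(V), c(2L, 2L))
  expect_true(all(diag(V) > 0))
  fld <- predict(fit, type = "field", grid = space_grid(16))
  expect_identical(dim(fld), c(16L, 16L))
  expect_output(print(summary(fit)), "Lumpy emission-model fit")
})
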