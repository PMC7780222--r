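test_that("synthesize matches the definition: empty sum, center value, brute force", {
  g <- space_grid(16)
  empty <- lump_field(NULL, numeric(0), 0.01)
  expect_equal(synthesize(empty, g), matrix(0, 16, 16))
  expect_equal(synthesize(empty, cbind(0.2, 0.7)), 0)

  # an unnormalized lump evaluated at its own center equals its amplitude
  one <- lump_field(cbind(0.37, 0.61), 3.5, 0.02)
  expect_equal(synthesize(one, cbind(0.37, 0.61)), 3.5)

  # vectorized evaluation agrees with an independent double loop to rounding
  set.seed(11)
  f <- lump_field(cbind(runif(7), runif(7)), runif(7, 0, 2), 0.015)
  pts <- cbind(runif(40), runif(40))
  expect_equal(synthesize(f, pts), naive_synthesize(f, pts), tolerance = 1e-14)
  # and the grid path agrees with the point path
  vals <- synthesize(f, g)
  expect_equal(as.vector(vals), naive_synthesize(f, grid_points(g)),
               tolerance = 1e-13)
})

test_that("invalid lump parameters are rejected", {
  expect_error(lump_field(cbind(0.5, 0.5), -1, 0.01), "non-negative")
  expect_error(lump_field(cbind(0.5, 0.5), 1, 0), "positive")
  expect_error(lump_field(cbind(0.5, 0.5), 1, 0.1, max_lumps = 0), "max_lumps")
  expect_error(lump_prior(0, 1, 0.1), "mean_lumps")
})

test_that("sampled fields follow the LB(mean_lumps, b0, sigma0^2) construction", {
  pr <- lump_prior(20, 1e-7, 0.04)  # the diffusion-coefficient prior
  set.seed(101)
  n_draws <- 1e4
  counts <- integer(n_draws)
  for (i in seq_len(n_draws)) {
    f <- sample_lump_field(pr)
    counts[i] <- nrow(f$centers)
    if (i <= 50) {
      expect_true(all(f$amplitudes == 1e-7))
      expect_identical(f$lump_variance, 0.04)
      expect_true(all(f$centers >= 0 & f$centers <= 1))
    }
  }
  # Poisson property: empirical mean and variance both near mean_lumps
  se <- sqrt(20 / n_draws)
  expect_lt(abs(mean(counts) - 20), 3 * se)
  se_var <- sqrt(2 * 20^2 / n_draws + 20 / n_draws)  # approx SE of var
  expect_lt(abs(var(counts) - 20), 4 * se_var)

  # vanishing rate gives the empty field almost surely
  tiny <- lump_prior(1e-12, 1, 0.01)
  set.seed(5)
  f0 <- sample_lump_field(tiny)
  expect_identical(nrow(f0$centers), 0L)
  expect_equal(synthesize(f0, space_grid(8)), matrix(0, 8, 8))
})

test_that("Monte-Carlo field mean matches the Campbell closed form at interior points", {
  pr <- lump_prior(200, 0.25, 0.002)  # the growth-rate prior
  pts <- rbind(c(0.5, 0.5), c(0.35, 0.6), c(0.62, 0.44))
  n_draws <- 1e4
  set.seed(202)
  acc <- matrix(0, n_draws, nrow(pts))
  for (i in seq_len(n_draws)) acc[i, ] <- synthesize(sample_lump_field(pr), pts)
  # Campbell's theorem for a uniform Poisson process of Gaussian lumps (2D):
  # E[phi(x)] = mean_lumps * b0 * 2*pi*sigma0^2 / |V| at interior points
  campbell <- 200 * 0.25 * 2 * pi * 0.002 / 1
  for (k in seq_len(nrow(pts))) {
    se <- sd(acc[, k]) / sqrt(n_draws)
    expect_lt(abs(mean(acc[, k]) - campbell), 3 * se)
  }
  # every realization is non-negative and bounded by L * max amplitude
  expect_true(all(acc >= 0))
})

test_that("synthesized realizations are non-negative and bounded", {
  set.seed(77)
  g <- space_grid(24)
  for (i in 1:20) {
    L <- sample(0:30, 1)
    f <- lump_field(cbind(runif(L), runif(L)), runif(L, 0, 5),
                    runif(1, 1e-4, 0.05))
    v <- synthesize(f, g)
    expect_true(all(v >= 0))
    if (L > 0) expect_true(max(v) <= L * max(f$amplitudes) + 1e-12)
  }
})

test_that("pack/unpack round-trips across layouts and gives the documented lengths", {
  # amplitudes-only on the 25 x 25 reconstruction grid: 625 parameters
  ly <- lump_layout("amplitudes", centers = lump_center_grid(25),
                    lump_variance = 1e-2 / 256)
  expect_identical(ly$n_par, 625L)
  set.seed(3)
  theta <- runif(625)
  f <- unpack_lumps(theta, ly)
  expect_equal(pack_lumps(f, ly), theta)

  # shared-width free-center layout with 60 lumps: 2*60 + 2 = 122 <= 3*60
  ly2 <- lump_layout("shared", max_lumps = 60)
  expect_identical(ly2$n_par, 122L)
  expect_lte(ly2$n_par, (2 + 1) * 60)
  theta2 <- c(runif(60), runif(60), 2.5, 0.03)
  f2 <- unpack_lumps(theta2, ly2)
  expect_equal(pack_lumps(f2, ly2), theta2)

  # free layout: 3 * max_lumps, inactive lumps encoded as amplitude 0
  ly3 <- lump_layout("free", max_lumps = 5, lump_variance = 0.01)
  f3 <- lump_field(cbind(runif(3), runif(3)), c(1, 2, 3), 0.01, max_lumps = 5)
  th3 <- pack_lumps(f3, ly3)
  expect_length(th3, 15L)
  expect_equal(th3[4:5], c(0, 0))
  g <- space_grid(12)
  expect_equal(synthesize(unpack_lumps(th3, ly3), g), synthesize(f3, g))

  # length mismatches error
  expect_error(unpack_lumps(runif(10), ly3), "length")
})

test_that("lumpy objects round-trip through JSON", {
  f <- lump_field(cbind(c(0.2, 0.8), c(0.3, 0.9)), c(1.5, 2.5), 0.012,
                  max_lumps = 4)
  p1 <- tempfile(fileext = ".json")
  write_lumpy_json(f, p1)
  f2 <- read_lumpy_json(p1)
  expect_equal(f2$centers, f$centers)
  expect_equal(f2$amplitudes, f$amplitudes)
  expect_equal(f2$lump_variance, f$lump_variance)

  pr <- lump_prior(20, 1e-7, 0.04)
  p2 <- tempfile(fileext = ".json")
  write_lumpy_json(pr, p2)
  pr2 <- read_lumpy_json(p2)
  expect_equal(pr2$mean_lumps, pr$mean_lumps)
  expect_equal(pr2$domain, pr$domain)
  unlink(c(p1, p2))
})
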