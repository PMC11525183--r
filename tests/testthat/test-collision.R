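test_that("collision probability follows the Poisson approximation", {
  expect_equal(collision_probability(0, 2, 1000), 0)
  expect_equal(collision_probability(10, 0, 1000), 0)
  # 1 - exp(-10*2/1000), frozen from direct evaluation
  expect_equal(collision_probability(10, 2, 1000), 0.019801326693245,
               tolerance = 1e-12)
  expect_error(collision_probability(10, 2, 0), "positive")
  expect_warning(collision_probability(100, 20, 1000), "pack")
})

test_that("expected collisions return nP and nP(1-P)", {
  e0 <- expected_collisions(0, 2, 1000)
  expect_equal(unlist(e0), c(P = 0, expected = 0, variance = 0))
  e <- expected_collisions(10, 2, 1000)
  expect_equal(e$expected, 0.19801326693245, tolerance = 1e-12)
  expect_equal(e$variance, 0.19409235, tolerance = 1e-6)
  # P -> 1 limit: expected -> n, variance -> 0
  e1 <- suppressWarnings(expected_collisions(10, 1000, 10))
  expect_equal(e1$expected, 10, tolerance = 1e-6)
  expect_lt(e1$variance, 1e-3)
  expect_true(e$variance <= e$expected)
})

test_that("the placement simulator matches the exact spacing law", {
  # oracle: P(one spacing < x) = 1 - (1 - x/y)^(n-1) exactly for uniform
  # points on a circle
  b0 <- brute_force_collisions(10, 0, 1000, reps = 500, seed = 1)
  expect_equal(b0$mean, 0)
  # n = 2, x = y/2: exactly one of the two arcs is below y/2 almost surely
  b2 <- brute_force_collisions(2, 500, 1000, reps = 2000, seed = 2)
  expect_equal(b2$mean, 1, tolerance = 1e-9)
  for (geom in list(c(10, 2, 1000), c(50, 5, 2000), c(5, 10, 500))) {
    exact <- geom[1] * exact_spacing_probability(geom[1], geom[2], geom[3])
    for (m in c("gaps", "placement")) {
      b <- brute_force_collisions(geom[1], geom[2], geom[3], reps = 3e4,
                                  seed = 11, method = m)
      expect_lt(abs(b$mean - exact), 3.5 * b$se)
    }
  }
})

test_that("gap and placement samplers agree with each other", {
  b1 <- brute_force_collisions(30, 4, 1500, reps = 3e4, seed = 5,
                               method = "gaps")
  b2 <- brute_force_collisions(30, 4, 1500, reps = 3e4, seed = 6,
                               method = "placement")
  expect_lt(abs(b1$mean - b2$mean), 3 * sqrt(b1$se^2 + b2$se^2))
  # determinism given seed
  b3 <- brute_force_collisions(30, 4, 1500, reps = 1000, seed = 5)
  b4 <- brute_force_collisions(30, 4, 1500, reps = 1000, seed = 5)
  expect_identical(b3$counts, b4$counts)
})

test_that("the small-argument limit P ~ nx/y holds to first order", {
  # all geometries satisfy n*x/y < 0.02
  for (geom in list(c(100, 1, 10000), c(10, 2, 5000), c(3, 1, 200))) {
    rho <- geom[1] * geom[2] / geom[3]
    P <- collision_probability(geom[1], geom[2], geom[3])
    expect_lt(abs(P - rho) / rho, 0.01)
  }
})

test_that("growth collision simulation handles degenerate cases", {
  rates <- c(0.02, 0.04, 0.06)
  single <- growth_sim_config(n_founders = 1, growth_rates = rates,
                              endpoint_day = 100, n_seeds = 50, seed = 1)
  r1 <- simulate_growth_collisions(single)
  expect_true(all(r1$per_seed$n_collisions == 0))
  expect_true(all(r1$per_seed$n_clusters == 1))
  # endpoint 0 with tiny radius: no overlaps
  tiny <- growth_sim_config(n_founders = 10, growth_rates = rates,
                            r0_mm = 1e-6, endpoint_day = 0, n_seeds = 50,
                            seed = 2)
  r2 <- simulate_growth_collisions(tiny)
  expect_true(all(r2$per_seed$n_collisions == 0))
  expect_error(growth_sim_config(n_founders = 5, growth_rates = numeric(0),
                                 endpoint_day = 10), "non-empty")
})

test_that("growth collision counts are deterministic and monotone in founders", {
  rates <- c(0.03, 0.05)
  cfg <- function(k, seed) {
    growth_sim_config(n_founders = k, growth_rates = rates, r0_mm = 0.05,
                      endpoint_day = 60, n_seeds = 400, seed = seed)
  }
  a1 <- simulate_growth_collisions(cfg(12, 3))
  a2 <- simulate_growth_collisions(cfg(12, 3))
  expect_identical(a1$per_seed, a2$per_seed)
  b <- simulate_growth_collisions(cfg(24, 3))
  # more founders -> strictly more observable heterotypic clusters on average
  expect_gt(b$summary$mean_heterotypic, a1$summary$mean_heterotypic)
  expect_true(all(b$per_seed$n_heterotypic <= b$per_seed$n_clusters))
})

test_that("cluster merging is transitive and order-independent", {
  # three discs in a chain: A overlaps B, B overlaps C, A far from C
  xs <- c(0, 1.5, 3); ys <- c(0, 0, 0); r <- c(1, 1, 1)
  expect_equal(polyclone:::disc_clusters(xs, ys, r), c(1L, 1L, 1L))
  perm <- c(3, 1, 2)
  memb <- polyclone:::disc_clusters(xs[perm], ys[perm], r[perm])
  expect_equal(length(unique(memb)), 1)
  # far apart: three singletons
  expect_equal(length(unique(polyclone:::disc_clusters(c(0, 10, 20), ys, r))),
               3)
})

test_that("paired observed/expected comparison behaves at the boundaries", {
  obs <- c(3, 5, 2, 4)
  res <- compare_observed_expected(obs, obs)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(compare_observed_expected(3, 3), "two segments")
  # consistency: a constant shift with no noise drives p to 0
  res2 <- compare_observed_expected(obs + 2, obs)
  expect_equal(res2$p_value, 0)
  res3 <- compare_observed_expected(obs + rnorm(4, 2, 0.01), obs)
  expect_lt(res3$p_value, 0.001)
  # agrees with stats::t.test when variance is positive
  set.seed(1)
  a <- rnorm(10); b <- rnorm(10)
  ref <- t.test(a, b, paired = TRUE)
  res4 <- compare_observed_expected(a, b)
  expect_equal(res4$statistic, unname(ref$statistic))
  expect_equal(res4$p_value, ref$p.value)
})

test_that("local density field reflects clustering", {
  # single point with bandwidth h: density is the self-contribution
  h <- 0.5
  expect_equal(local_density_field(1, 1, bandwidth = h),
               1 / (2 * pi * h^2))
  expect_error(local_density_field(1, 1), "bandwidth")
  # coincident tumours share a density value
  d <- local_density_field(c(2, 2, 8), c(3, 3, 9), bandwidth = 1)
  expect_equal(d[1], d[2])
  # clustered pair exceeds an isolated point
  expect_gt(d[1], d[3])
})

test_that("heterotypia density test detects shifts and validates groups", {
  dens <- c(rlnorm(30), rlnorm(30))
  expect_error(heterotypia_density_test(dens, rep("homotypic", 60)),
               "required")
  set.seed(42)
  dens_shift <- c(rlnorm(100, meanlog = 1.5), rlnorm(100))
  statuses <- c(rep("heterotypic", 100), rep("homotypic", 100))
  res <- heterotypia_density_test(dens_shift, statuses)
  expect_gt(res$statistic, 0)
  expect_lt(res$p_value, 1e-6)
  expect_equal(nrow(res$qq), 100)
  expect_true(all(diff(res$qq$q_heterotypic) >= 0))
})

test_that("density/fraction regression reports adjusted R-squared", {
  x <- c(1, 2, 3, 4, 5)
  # collinear input triggers summary.lm's perfect-fit warning by design
  res <- suppressWarnings(density_fraction_regression(x, 0.1 + 0.05 * x))
  expect_equal(res$adj_r_squared, 1)
  expect_equal(res$slope, 0.05)
  expect_error(density_fraction_regression(c(1, 2), c(0.3, 0.4)),
               "three segments")
  # independent inputs: mean adjusted R^2 near zero (may be negative)
  set.seed(3)
  vals <- replicate(300, {
    density_fraction_regression(rnorm(50), runif(50))$adj_r_squared
  })
  expect_lt(abs(mean(vals)), 0.02)
})
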