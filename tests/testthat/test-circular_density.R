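test_that("ML concentration solves A(kappa) = Rbar", {
  # evenly spaced angles have zero resultant length
  expect_equal(kappa_ml(seq(0, 2 * pi, length.out = 9)[-9]), 0)
  expect_equal(kappa_ml(c(0.3, 0.3 + pi)), 0)
  set.seed(101)
  khat <- kappa_ml(rvonmises(10000, pi, 4))
  expect_lt(abs(khat - 4) / 4, 0.05)
  expect_warning(kcap <- kappa_ml(rep(1.2, 20)), "capping")
  expect_equal(kcap, 500)
})

test_that("plug-in bandwidth matches a direct evaluation of the formula", {
  set.seed(7)
  theta <- rvonmises(100, 1, 2)
  k <- kappa_ml(theta)
  n <- length(theta)
  direct <- (3 * n * k^2 * besselI(2 * k, 2) /
               (4 * sqrt(pi) * besselI(k, 1)^2))^(2 / 5)
  expect_equal(plugin_bandwidth(theta), direct, tolerance = 1e-10)
  # the adjust factor is a plain multiplier
  expect_equal(plugin_bandwidth(theta, adjust = 2), 2 * direct,
               tolerance = 1e-10)
  expect_equal(plugin_bandwidth(theta, adjust = 0.8), 0.8 * direct,
               tolerance = 1e-10)
  # dispersed data collapse to the bandwidth floor
  expect_equal(plugin_bandwidth(seq(0, 2 * pi, length.out = 13)[-13]), 0.01)
})

test_that("kernel density matches the brute-force kernel sum", {
  set.seed(8)
  theta <- rvonmises(50, 4, 3)
  fit <- fit_vonmises_kde(theta, bw = 5)
  expect_equal(fit$kappa, 5)
  brute <- brute_vm_density(fit$grid, theta, 5)
  expect_equal(fit$density, brute, tolerance = 1e-12)
  # evaluation off the grid uses the same exact kernel sum
  pts <- c(0.1, 2.2, 5.9)
  expect_equal(vmkde_eval(fit, pts), brute_vm_density(pts, theta, 5),
               tolerance = 1e-12)
})

test_that("fitted densities integrate to one and stay normalised as the grid grows", {
  set.seed(9)
  samples <- list(rvonmises(30, 0, 8), rvonmises(200, pi, 1),
                  runif(100, 0, 2 * pi),
                  c(rvonmises(60, pi / 2, 6), rvonmises(60, 3 * pi / 2, 6)))
  for (theta in samples) {
    err64 <- abs(vmkde_integral(fit_vonmises_kde(theta, grid_size = 64)) - 1)
    err512 <- abs(vmkde_integral(fit_vonmises_kde(theta, grid_size = 512)) - 1)
    expect_lt(err64, 1e-3)
    expect_lte(err512, err64 + 1e-12)
  }
})

test_that("single-point and uniform-limit behaviour", {
  fit1 <- fit_vonmises_kde(2.0)
  expect_equal(fit1$grid[which.max(fit1$density)], 2.0,
               tolerance = 2 * pi / 128)
  # tiny kernel concentration flattens the density to 1/(2*pi)
  flat <- fit_vonmises_kde(seq(0, 2 * pi, length.out = 41)[-41], bw = 0.01)
  expect_equal(flat$density, rep(1 / (2 * pi), 128), tolerance = 1e-4)
  expect_error(fit_vonmises_kde(numeric(0)), "empty")
})

test_that("rotating the sample rotates the density", {
  set.seed(10)
  theta <- rvonmises(150, 1, 3)
  shift_slots <- 17L
  delta <- 2 * pi * shift_slots / 128
  f0 <- fit_vonmises_kde(theta, grid_size = 128)
  f1 <- fit_vonmises_kde(wrap_angle(theta + delta), grid_size = 128)
  expect_equal(f0$kappa, f1$kappa, tolerance = 1e-12)
  rotated <- c(utils::tail(f1$density, -shift_slots),
               utils::head(f1$density, shift_slots))
  expect_lt(max(abs(f0$density - rotated)), 1e-9)
})

test_that("estimation error of the density shrinks with sample size", {
  true_f <- function(t) 0.6 * dvonmises(t, pi, 2) + 0.4 * dvonmises(t, 5, 6)
  grid <- seq(0, 2 * pi, length.out = 513)[-513]
  iae <- function(n, seed) {
    set.seed(seed)
    theta <- c(rvonmises(round(0.6 * n), pi, 2), rvonmises(n - round(0.6 * n), 5, 6))
    fit <- fit_vonmises_kde(theta, grid_size = 512)
    mean(abs(fit$density - true_f(grid))) * 2 * pi
  }
  mean_iae <- vapply(c(50, 500, 5000),
                     function(n) mean(vapply(1:5, function(s) iae(n, s), numeric(1))),
                     numeric(1))
  expect_true(all(diff(mean_iae) < 0))
})

test_that("activity level is the mean-to-peak ratio with honest bootstrap", {
  set.seed(12)
  theta <- rvonmises(120, pi, 2)
  lvl <- activity_level(theta, n_boot = 100, seed = 31)
  fit <- fit_vonmises_kde(theta)
  expect_equal(lvl$estimate, 1 / (2 * pi * max(fit$density)), tolerance = 1e-12)
  expect_true(lvl$ci[1] <= lvl$estimate && lvl$estimate <= lvl$ci[2])
  # same seed reproduces se and ci exactly
  lvl2 <- activity_level(theta, n_boot = 100, seed = 31)
  expect_identical(lvl$se, lvl2$se)
  expect_identical(lvl$ci, lvl2$ci)
  # flat activity saturates the estimate near 1; concentrated activity is low
  flat <- activity_level(seq(0, 2 * pi, length.out = 61)[-61],
                         n_boot = 50, seed = 1)
  expect_gt(flat$estimate, 0.95)
  conc <- activity_level(rvonmises(120, 0, 20), n_boot = 50, seed = 1)
  expect_lt(conc$estimate, 0.35)
  # below the inclusion floor the species is flagged, not estimated
  few <- activity_level(rvonmises(9, 0, 2), n_boot = 50, seed = 1)
  expect_true(few$excluded)
  expect_true(is.na(few$estimate))
})

test_that("Wald comparison of activity levels", {
  a <- fake_level(0.5, 0.05)
  b <- fake_level(0.3, 0.05)
  cmp <- compare_activity_levels(list(S1 = a, S2 = b))
  expect_equal(cmp$statistic, 8.0)
  expect_equal(cmp$p_value, pchisq(8, 1, lower.tail = FALSE))
  # three sites: Bonferroni threshold 0.05/3
  cmp3 <- compare_activity_levels(list(S1 = a, S2 = b, S3 = fake_level(0.4, 0.05)))
  expect_equal(nrow(cmp3), 3)
  expect_equal(unique(cmp3$alpha_adjusted), 0.05 / 3)
  # identical groups: W = 0, p = 1
  same <- compare_activity_levels(list(S1 = a, S2 = a))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  expect_error(compare_activity_levels(list(S1 = a, S2 = fake_level(0.3, 0))),
               "positive")
})
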