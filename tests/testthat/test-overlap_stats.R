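test_that("Dhat1 agrees with a fine-grid integration oracle", {
  set.seed(21)
  cases <- list(list(a = rvonmises(40, 0, 2), b = rvonmises(55, 2, 3)),
                list(a = rvonmises(70, pi, 1), b = runif(60, 0, 2 * pi)),
                list(a = c(rvonmises(30, 1, 6), rvonmises(30, 4, 6)),
                     b = rvonmises(45, 4, 4)))
  for (cs in cases) {
    d <- delta1(cs$a, cs$b)
    # oracle: brute-force kernel densities on a 4096-point grid
    grid <- seq(0, 2 * pi, length.out = 4097)[-4097]
    ka <- plugin_bandwidth(cs$a, adjust = 0.8)
    kb <- plugin_bandwidth(cs$b, adjust = 0.8)
    oracle <- grid_overlap(brute_vm_density(grid, cs$a, ka),
                           brute_vm_density(grid, cs$b, kb))
    expect_equal(d, oracle, tolerance = 1e-3)
  }
})

test_that("Dhat4 matches a brute-force per-point loop", {
  set.seed(22)
  a <- rvonmises(80, 1, 2)
  b <- rvonmises(90, 4, 3)
  d <- delta4(a, b)
  ka <- plugin_bandwidth(a, adjust = 1)
  kb <- plugin_bandwidth(b, adjust = 1)
  fa_x <- brute_vm_density(a, a, ka); fb_x <- brute_vm_density(a, b, kb)
  fa_y <- brute_vm_density(b, a, ka); fb_y <- brute_vm_density(b, b, kb)
  s1 <- 0; for (i in seq_along(a)) s1 <- s1 + min(1, fb_x[i] / fa_x[i])
  s2 <- 0; for (j in seq_along(b)) s2 <- s2 + min(1, fa_y[j] / fb_y[j])
  oracle <- 0.5 * (s1 / length(a) + s2 / length(b))
  expect_equal(d, oracle, tolerance = 1e-12)
})

test_that("overlap identities: identical, disjoint, symmetric, bounded", {
  set.seed(23)
  x <- rvonmises(100, 2, 3)
  expect_identical(delta4(x, x), 1)          # every ratio min is exactly 1
  expect_equal(delta1(x, x), 1, tolerance = 0.02)
  # tightly concentrated antipodal densities barely overlap
  a <- rvonmises(100, 0, 50); b <- rvonmises(100, pi, 50)
  expect_lt(delta1(a, b), 0.05)
  expect_lt(delta4(a, b), 0.05)
  # symmetry and range over random pairs
  for (i in 1:5) {
    p <- rvonmises(40 + 10 * i, runif(1, 0, 2 * pi), runif(1, 0, 5))
    q <- runif(35 + 5 * i, 0, 2 * pi)
    expect_equal(delta1(p, q), delta1(q, p), tolerance = 1e-9)
    expect_equal(delta4(p, q), delta4(q, p), tolerance = 1e-12)
    expect_true(delta1(p, q) >= 0 && delta1(p, q) <= 1)
    expect_true(delta4(p, q) >= 0 && delta4(p, q) <= 1)
  }
})

test_that("estimator selection follows the 75-photo rule", {
  set.seed(24)
  mk <- function(n) rvonmises(n, 1, 2)
  expect_equal(estimate_overlap(mk(60), mk(200), n_boot = 10, seed = 1)$estimator,
               "Dhat1")
  expect_equal(estimate_overlap(mk(200), mk(200), n_boot = 10, seed = 1)$estimator,
               "Dhat4")
  # the boundary n = 75 goes to Dhat4
  expect_equal(estimate_overlap(mk(75), mk(75), n_boot = 10, seed = 1)$estimator,
               "Dhat4")
  # pairs under the inclusion floor are flagged, not estimated
  ex <- estimate_overlap(mk(9), mk(200), n_boot = 10, seed = 1)
  expect_true(ex$excluded)
})

test_that("smoothed bootstrap is reproducible and covers the estimate", {
  set.seed(25)
  a <- rvonmises(90, 0, 2); b <- rvonmises(90, 1, 2)
  o1 <- estimate_overlap(a, b, n_boot = 60, seed = 99)
  o2 <- estimate_overlap(a, b, n_boot = 60, seed = 99)
  expect_identical(o1$ci, o2$ci)
  expect_identical(o1$delta, o2$delta)
  expect_true(o1$ci[1] <= o1$ci[2])
  expect_true(o1$delta >= o1$ci[1] - 0.1 && o1$delta <= o1$ci[2] + 0.1)
})

test_that("splitting one sample in half gives near-complete overlap", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    theta <- rvonmises(400, 0, 3)  # canonical unimodal diel density
    idx <- sample.int(400, 200)
    delta4(theta[idx], theta[-idx]) >= 0.85
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("overlap categories follow the 0.50/0.75 cut points", {
  expect_equal(categorize_overlap(0.41), "low")
  expect_equal(categorize_overlap(0.50), "low")       # boundary: <= 0.50 is low
  expect_equal(categorize_overlap(0.63), "moderate")
  expect_equal(categorize_overlap(0.75), "moderate")  # boundary: <= 0.75
  expect_equal(categorize_overlap(0.95), "high")
  expect_equal(categorize_overlap(c(0, 1)), c("low", "high"))
  expect_error(categorize_overlap(1.2), "0, 1")
  expect_error(categorize_overlap(-0.1), "0, 1")
})
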