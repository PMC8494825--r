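test_that("selection ratios satisfy their algebraic identities", {
  # used exactly at availability: no selection at all
  s0 <- selection_ratio_test(c(night = 100, day = 100, twilight = 40))
  expect_equal(s0$chisq, 0)
  expect_equal(unname(s0$w), c(1, 1, 1))
  expect_equal(unname(s0$sign), rep("neither", 3))
  # all events at night
  s1 <- selection_ratio_test(c(night = 24, day = 0, twilight = 0))
  expect_equal(unname(s1$w["night"]), 24 / 10)
  expect_equal(unname(s1$w["day"]), 0)
  # hand-computed Pearson sum for counts (26, 2, 3)
  o <- c(26, 2, 3); p <- c(10, 10, 4) / 24; n <- 31
  s2 <- selection_ratio_test(c(night = 26, day = 2, twilight = 3))
  expect_equal(s2$chisq, sum((o - n * p)^2 / (n * p)), tolerance = 1e-12)
  expect_equal(s2$df, 2L)
  # weighted identity sum(pi_i * w_i) = 1 and chi-square count scaling
  set.seed(31)
  for (i in 1:10) {
    cnt <- c(night = rpois(1, 20) + 1, day = rpois(1, 15) + 1,
             twilight = rpois(1, 5) + 1)
    s <- selection_ratio_test(cnt)
    expect_equal(sum(s$availability * s$w), 1, tolerance = 1e-9)
    expect_equal(selection_ratio_test(cnt * 3)$chisq, 3 * s$chisq,
                 tolerance = 1e-9)
  }
  expect_error(selection_ratio_test(c(night = 1, day = 1, twilight = 1),
                                    availability = c(night = 0.5, day = 0.5,
                                                     twilight = 0)),
               "positive")
})

test_that("period GLMM finds no effect in balanced counts and respects offsets", {
  # every camera records the same count in every period
  cams <- sprintf("c%02d", 1:12)
  sites <- rep(c("S1", "S2", "S3"), each = 4)
  times <- c("02:00", "12:00", "18:00")  # one night, one day, one twilight
  det <- do.call(rbind, lapply(seq_along(cams), function(i) {
    d <- make_detections(rep(times, 2), camera = cams[i], site = sites[i])
    d$timestamp <- d$timestamp + (i - 1) * 86400 * 7  # separate events
    d
  }))
  class(det) <- c("event_table", "detection_table", "data.frame")
  dep <- deployments_for(cams, sites, days = 100)
  fit <- fit_period_glmm(det, dep)
  expect_gt(fit$p_value, 0.9)
  expect_equal(classify_activity_pattern(fit), "cathemeral")
  # doubling every camera's effort shifts the intercept only
  dep2 <- deployments_for(cams, sites, days = 200)
  fit2 <- fit_period_glmm(det, dep2)
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-6)
  expect_equal(fit$wald_chisq, fit2$wald_chisq, tolerance = 1e-4)
})

test_that("a strongly nocturnal species yields a significant night-twilight contrast", {
  set.seed(33)
  profile <- species_profile("noct", "nocturnal-unimodal")
  theta <- sample_activity_times(profile, 200)
  ev <- events_from_angles(theta, species = "noct")
  dep <- deployments_for()
  fit <- fit_period_glmm(ev, dep)
  nt <- fit$pairwise[grepl("twilight", fit$pairwise$contrast) &
                       grepl("night", fit$pairwise$contrast), ]
  expect_lt(nt$p_adj, 0.01)
  expect_lt(nt$estimate, 0)  # twilight rate below night rate
  expect_equal(classify_activity_pattern(fit), "nocturnal")
  # permuting the event clock times destroys the period signal
  set.seed(34)
  ev_perm <- events_from_angles(runif(200, 0, 2 * pi), species = "noct")
  fit_perm <- fit_period_glmm(ev_perm, dep, offset = "day_period_hours")
  expect_lt(fit_perm$wald_chisq, fit$wald_chisq)
  expect_gt(fit_perm$p_value, 0.05)
})

test_that("classification covers single, compound and cathemeral outcomes", {
  # selection-route archetypal outcomes, built from period counts
  noct <- selection_ratio_test(c(night = 40, day = 2, twilight = 3))
  expect_equal(classify_activity_pattern(noct), "nocturnal")
  di <- selection_ratio_test(c(night = 1, day = 40, twilight = 4))
  expect_equal(classify_activity_pattern(di), "diurnal")
  # day dominant but not separable from twilight: compound label
  dc <- selection_ratio_test(c(night = 2, day = 28, twilight = 12))
  expect_equal(classify_activity_pattern(dc), "diurnal+crepuscular")
  flat <- selection_ratio_test(c(night = 12, day = 13, twilight = 5))
  expect_equal(classify_activity_pattern(flat), "cathemeral")
})

test_that("the report routes species by sample size", {
  set.seed(35)
  dep <- deployments_for()
  mk <- function(n, sp, prof) events_from_angles(
    sample_activity_times(species_profile(sp, prof), n), species = sp)
  ev <- rbind(mk(8, "rare", "cathemeral"),
              mk(30, "mid", "nocturnal-unimodal"),
              mk(120, "common", "diurnal"))
  class(ev) <- c("event_table", "detection_table", "data.frame")
  rep <- suppressWarnings(activity_pattern_report(ev, dep, offset = "day_period_hours"))
  rep <- rep[order(rep$species), ]
  expect_equal(rep$route[rep$species == "rare"], "excluded")
  expect_equal(rep$route[rep$species == "mid"], "selection")
  expect_equal(rep$route[rep$species == "common"], "glmm")
  expect_equal(rep$pattern[rep$species == "mid"], "nocturnal")
  expect_equal(rep$pattern[rep$species == "common"], "diurnal")
  expect_true(is.na(rep$pattern[rep$species == "rare"]))
})
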