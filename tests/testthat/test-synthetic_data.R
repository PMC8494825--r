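test_that("profile sampling matches the requested archetype", {
  cath <- species_profile("c", "cathemeral")
  th <- sample_activity_times(cath, 10000, seed = 41)
  expect_lt(mean_resultant_length(th), 0.05)
  noct <- species_profile("n", "nocturnal-unimodal")
  th2 <- sample_activity_times(noct, 5000, seed = 42)
  night_frac <- mean(classify_period(th2 / (2 * pi) * 24) == "night")
  expect_gt(night_frac, 0.70)
  expect_length(sample_activity_times(noct, 0), 0)
  # identical seed, identical draws
  expect_identical(sample_activity_times(noct, 50, seed = 7),
                   sample_activity_times(noct, 50, seed = 7))
  expect_error(species_profile("bad", mixture = data.frame(
    mean = 0, kappa = 2, weight = 0.5)), "sum to 1")
  expect_error(species_profile("bad2", "no-such-archetype"), "archetype")
})

test_that("simulated studies are reproducible and account effort correctly", {
  cfg <- study_config(seed = 43)
  s1 <- simulate_camera_study(cfg)
  s2 <- simulate_camera_study(cfg)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$deployments, s2$deployments)
  expect_identical(s1$truth$n_events, s2$truth$n_events)
  # per-site camera counts and effort bounds follow the configuration
  dep <- as.data.frame(s1$deployments)
  expect_equal(as.vector(table(dep$site)), c(15, 30, 28))
  for (i in seq_len(nrow(cfg$sites))) {
    st <- cfg$sites[i, ]
    days <- dep$operating_days[dep$site == st$site]
    expect_true(all(days <= st$max_days))
    expect_true(all(days >= floor(st$min_days * (1 - cfg$failure_frac)) - 1))
  }
  # with no failures, operating days equal the full window
  cfg0 <- study_config(failure_frac = 0, seed = 44)
  dep0 <- as.data.frame(simulate_camera_study(cfg0)$deployments)
  expect_true(all(dep0$operating_days >= cfg0$sites$min_days[
    match(dep0$site, cfg0$sites$site)]))
})

test_that("burst structure interacts with the independence filter as designed", {
  prof <- list(species_profile("solo", "cathemeral", rate = 0.02))
  # burst size 1, events forced > 40 min apart: the filter is the identity
  cfg1 <- study_config(species = prof, burst_size = 1,
                       min_event_gap_minutes = 40, seed = 45)
  s1 <- simulate_camera_study(cfg1)
  expect_equal(nrow(independent_events(s1$detections)),
               unname(s1$truth$n_events["solo"]))
  # burst of 4 photos at 2-min gaps collapses 4:1
  cfg4 <- study_config(species = prof, burst_size = 4, burst_gap_minutes = 2,
                       min_event_gap_minutes = 40, seed = 46)
  s4 <- simulate_camera_study(cfg4)
  expect_equal(nrow(s4$detections), 4 * unname(s4$truth$n_events["solo"]))
  expect_equal(nrow(independent_events(s4$detections)),
               nrow(s4$detections) / 4)
})

test_that("identical profiles have unit true overlap and are recovered", {
  twin <- list(species_profile("t1", "nocturnal-unimodal", rate = 0.012),
               species_profile("t2", "nocturnal-unimodal", rate = 0.012))
  cfg <- study_config(species = twin, seed = 47)
  s <- simulate_camera_study(cfg)
  expect_equal(s$truth$true_overlap["t1", "t2"], 1, tolerance = 1e-9)
  ev <- independent_events(s$detections)
  th1 <- to_radians(ev$timestamp[ev$species == "t1"])
  th2 <- to_radians(ev$timestamp[ev$species == "t2"])
  expect_gte(length(th1), 300)  # default effort yields ample events
  d <- estimate_overlap(th1, th2, n_boot = 20, seed = 48)
  expect_gte(d$delta, 0.9)
  # antipodal archetypes: the true overlap is small
  expect_lt(true_overlap(species_profile("a", "diurnal"),
                         species_profile("b", "nocturnal-unimodal")), 0.10)
})
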