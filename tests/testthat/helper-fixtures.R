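# Shared fixture builders and independent oracles.

# Detections at given "HH:MM" (or "YYYY-MM-DD HH:MM") clock times.
make_detections <- function(times, camera = "cam1", site = "S1", species = "sp",
                            date = "2020-06-01") {
  full <- ifelse(grepl(" ", times), times, paste(date, times))
  detection_table(camera_id = rep_len(camera, length(full)),
                  site = rep_len(site, length(full)),
                  species = rep_len(species, length(full)),
                  timestamp = full)
}

# Event table for one species from radian activity times, spread over
# cameras/sites so the GLMM route has grouping structure.
events_from_angles <- function(theta, species = "sp",
                               cameras = sprintf("c%02d", 1:20),
                               sites = rep(c("S1", "S2"), each = 10),
                               start = as.Date("2020-01-01"), n_days = 300) {
  n <- length(theta)
  idx <- rep_len(seq_along(cameras), n)
  day <- start + sample.int(n_days, n, replace = TRUE) - 1
  secs <- round(theta / (2 * pi) * 86400)
  det <- detection_table(camera_id = cameras[idx], site = sites[idx],
                         species = rep(species, n),
                         timestamp = as.POSIXct(paste(day, "00:00:00"),
                                                tz = "UTC") + secs)
  class(det) <- c("event_table", class(det))
  det
}

deployments_for <- function(cameras = sprintf("c%02d", 1:20),
                            sites = rep(c("S1", "S2"), each = 10),
                            days = 300) {
  deployment_table(cameras, sites, rep_len(days, length(cameras)))
}

# Published per-site event counts and effort from a three-site Bornean
# carnivore survey, used to exercise the effort arithmetic.
published_counts <- function() {
  read.csv(system.file("extdata", "borneo_capture_counts.csv",
                       package = "dielkit"), stringsAsFactors = FALSE)
}

published_effort <- function() {
  read_deployments(system.file("extdata", "borneo_site_effort.csv",
                               package = "dielkit"))
}

# Expand (species, site, n_events) count rows into a dummy event table so
# count-based statistics can be recomputed through the real code path.
events_from_counts <- function(counts) {
  idx <- rep(seq_len(nrow(counts)), counts$n_events)
  ts <- as.POSIXct("2011-01-01 12:00", tz = "UTC") + seq_along(idx) * 3600
  det <- detection_table(camera_id = paste0(counts$site[idx], "-all"),
                         site = counts$site[idx],
                         species = counts$species[idx], timestamp = ts)
  class(det) <- c("event_table", class(det))
  det
}

# Independent brute-force von Mises kernel density (naive double loop).
brute_vm_density <- function(t_eval, theta, kappa) {
  out <- numeric(length(t_eval))
  for (i in seq_along(t_eval)) {
    s <- 0
    for (x in theta) s <- s + exp(kappa * cos(t_eval[i] - x))
    out[i] <- s / (length(theta) * 2 * pi * besselI(kappa, 0))
  }
  out
}

# Fine-grid trapezoidal overlap of two density vectors on an even circular
# grid of m points.
grid_overlap <- function(fa, fb) {
  mean(pmin(fa, fb)) * 2 * pi
}

# Minimal activity_level stand-in for Wald-comparison arithmetic tests.
fake_level <- function(estimate, se) {
  structure(list(estimate = estimate, se = se, ci = c(NA, NA), n = 100,
                 n_boot = 0, seed = NULL, excluded = FALSE),
            class = "activity_level")
}
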