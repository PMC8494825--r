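# Synthetic camera-trap studies with known ground truth. Event counts per
# camera follow a homogeneous Poisson process over operating days; event
# clock times are drawn from the species' diel density (a von Mises
# mixture), deliberately conflating activity and detectability; each event
# is expanded into a burst of closely spaced photos to exercise the
# independence filter.

.archetype_mixtures <- list(
  # means in hours on the 24-h clock
  "nocturnal-unimodal" = data.frame(mean_h = 0,            kappa = 3,    weight = 1),
  "nocturnal-bimodal"  = data.frame(mean_h = c(21, 4),     kappa = 4,    weight = c(0.5, 0.5)),
  "diurnal"            = data.frame(mean_h = 12,           kappa = 3,    weight = 1),
  "crepuscular"        = data.frame(mean_h = c(6, 18),     kappa = 8,    weight = c(0.5, 0.5)),
  "cathemeral"         = data.frame(mean_h = 0,            kappa = 0,    weight = 1)
)

#' Species activity profile for simulation
#'
#' A named diel activity density (von Mises mixture on the 24-h circle)
#' plus a daily detection rate per camera. The five built-in archetypes
#' place activity at midnight (kappa 3), at 21:00 and 04:00 (kappa 4
#' each), at noon (kappa 3), at 06:00 and 18:00 (kappa 8 each), and
#' uniformly over the day.
#'
#' @param name species label.
#' @param archetype one of `"nocturnal-unimodal"`, `"nocturnal-bimodal"`,
#'   `"diurnal"`, `"crepuscular"`, `"cathemeral"`; ignored when `mixture`
#'   is given.
#' @param rate expected detections per camera per operating day (default
#'   0.005, i.e. 0.5 events per 100 camera-trap days, a typical
#'   camera-trap frequency for an uncommon forest carnivore).
#' @param mixture optional data frame with columns `mean` (radians),
#'   `kappa`, `weight` overriding the archetype.
#' @return Object of class `species_profile`.
#' @export
species_profile <- function(name, archetype = "cathemeral", rate = 0.005,
                            mixture = NULL) {
  if (is.null(mixture)) {
    if (!archetype %in% names(.archetype_mixtures))
      stop("unknown archetype: ", archetype)
    m <- .archetype_mixtures[[archetype]]
    mixture <- data.frame(mean = 2 * pi * m$mean_h / 24,
                          kappa = m$kappa, weight = m$weight)
  } else {
    archetype <- "custom"
  }
  if (abs(sum(mixture$weight) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (any(mixture$kappa < 0)) stop("concentrations must be >= 0")
  if (rate < 0) stop("rate must be >= 0")
  structure(list(name = name, archetype = archetype, mixture = mixture,
                 rate = rate),
            class = "species_profile")
}

#' Sample activity times from a species profile
#'
#' @param profile a [species_profile()].
#' @param n number of draws (`n = 0` gives an empty vector).
#' @param seed optional RNG seed.
#' @return `n` angles in `[0, 2*pi)` drawn i.i.d. from the profile's
#'   von Mises mixture.
#' @export
sample_activity_times <- function(profile, n, seed = NULL) {
  stopifnot(inherits(profile, "species_profile"), n >= 0)
  with_seed(seed, rvm_mixture(n, profile$mixture))
}

#' True diel density of a species profile
#'
#' @param profile a [species_profile()].
#' @param theta angles in radians.
#' @return Density of the generating von Mises mixture at `theta`.
#' @export
true_density <- function(profile, theta) {
  dvm_mixture(theta, profile$mixture)
}

#' True overlap between two species profiles
#'
#' Fine-grid trapezoidal integral of the pointwise minimum of the two
#' generating mixtures.
#'
#' @param profile_a,profile_b [species_profile()] objects.
#' @param grid_size integration grid (default 4096).
#' @return Overlap coefficient in `[0, 1]`.
#' @export
true_overlap <- function(profile_a, profile_b, grid_size = 4096) {
  grid <- seq(0, 2 * pi, length.out = grid_size + 1)[-(grid_size + 1)]
  mean(pmin(true_density(profile_a, grid), true_density(profile_b, grid))) * 2 * pi
}

#' Study configuration for the synthetic generator
#'
#' The default layout mirrors a three-site Bornean study: sites `DV`
#' (15 cameras, long steady deployments), `LK` (30 cameras, highly uneven
#' effort) and `TW` (28 cameras, short deployments), with per-camera
#' operating-day ranges of roughly 680-1230, 30-1315 and 26-540 days.
#'
#' @param sites data frame with columns `site`, `n_cameras`, `start`
#'   (deployment start date, `Date` or `"YYYY-MM-DD"`), `min_days`,
#'   `max_days` (uniform range of per-camera window length).
#' @param species list of [species_profile()] objects.
#' @param burst_size photos per detection event (>= 1; default 3).
#' @param burst_gap_minutes spacing of photos within a burst (default 2).
#' @param failure_frac fraction of each camera's window lost to failure
#'   gaps (default 0.1); operating days = window days minus failure days.
#' @param min_event_gap_minutes optional minimum spacing enforced between
#'   same-camera same-species events (useful to make filter behaviour
#'   exactly predictable); `NULL` (default) leaves the Poisson process
#'   unthinned.
#' @param seed RNG seed recorded in the configuration.
#' @return Object of class `study_config`.
#' @export
study_config <- function(sites = NULL, species = NULL, burst_size = 3,
                         burst_gap_minutes = 2, failure_frac = 0.1,
                         min_event_gap_minutes = NULL, seed = 1) {
  if (is.null(sites)) {
    sites <- data.frame(
      site = c("DV", "LK", "TW"),
      n_cameras = c(15L, 30L, 28L),
      start = as.Date(c("2010-07-01", "2010-07-01", "2010-05-01")),
      min_days = c(682, 30, 26),
      max_days = c(1229, 1315, 539),
      stringsAsFactors = FALSE)
  }
  sites$start <- as.Date(sites$start)
  if (is.null(species)) {
    species <- list(
      species_profile("civet A",  "nocturnal-unimodal", rate = 0.020),
      species_profile("civet B",  "nocturnal-unimodal", rate = 0.012),
      species_profile("linsang",  "nocturnal-bimodal",  rate = 0.004),
      species_profile("marten",   "diurnal",            rate = 0.004),
      species_profile("bear",     "cathemeral",         rate = 0.006))
  }
  stopifnot(burst_size >= 1, burst_gap_minutes > 0,
            failure_frac >= 0, failure_frac < 1,
            all(sites$n_cameras > 0), all(sites$min_days >= 1),
            all(sites$max_days >= sites$min_days))
  structure(list(sites = sites, species = species, burst_size = burst_size,
                 burst_gap_minutes = burst_gap_minutes,
                 failure_frac = failure_frac,
                 min_event_gap_minutes = min_event_gap_minutes, seed = seed),
            class = "study_config")
}

#' Simulate a complete camera-trap study
#'
#' Draws per-camera deployments (window length uniform on the site's
#' range, a fraction of days knocked out as failure gaps), places
#' independent events by a homogeneous Poisson process over the camera's
#' operating days, assigns clock times from each species' diel density,
#' and expands every event into a photo burst. The returned truth record
#' carries the generating profiles, per-species event counts, and the true
#' pairwise overlap of every species pair, so downstream estimates can be
#' checked against ground truth.
#'
#' @param config a [study_config()].
#' @return List with `detections` (a [detection_table()], burst photos
#'   included), `deployments` (a [deployment_table()]), and `truth` (list:
#'   `profiles`, `n_events` per species, `true_overlap` matrix, `seed`).
#' @export
simulate_camera_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  with_seed(config$seed, {
    dep_rows <- list()
    det_rows <- list()
    active_days <- list()  # per camera: Date vector of operating days
    for (s in seq_len(nrow(config$sites))) {
      st <- config$sites[s, ]
      for (cam in seq_len(st$n_cameras)) {
        cam_id <- sprintf("%s-%02d", st$site, cam)
        window <- floor(stats::runif(1, st$min_days, st$max_days + 1))
        days <- st$start + seq_len(window) - 1
        n_fail <- floor(config$failure_frac * window)
        if (n_fail > 0) days <- days[-sample.int(window, n_fail)]
        active_days[[cam_id]] <- days
        dep_rows[[cam_id]] <- data.frame(camera_id = cam_id, site = st$site,
                                         operating_days = length(days),
                                         stringsAsFactors = FALSE)
      }
    }
    deployments <- do.call(rbind, dep_rows)
    n_events <- stats::setNames(integer(length(config$species)),
                                vapply(config$species, `[[`, "", "name"))
    for (profile in config$species) {
      for (cam_id in names(active_days)) {
        days <- active_days[[cam_id]]
        k <- stats::rpois(1, profile$rate * length(days))
        if (k == 0) next
        day <- sample(days, k, replace = TRUE)
        theta <- rvm_mixture(k, profile$mixture)
        secs <- round(theta / (2 * pi) * 86400)
        ts <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC") + secs
        ts <- sort(ts)
        if (!is.null(config$min_event_gap_minutes) && k > 1) {
          keep <- c(TRUE, diff(as.numeric(ts)) > config$min_event_gap_minutes * 60)
          ts <- ts[keep]
          k <- length(ts)
        }
        n_events[profile$name] <- n_events[profile$name] + k
        burst <- rep(ts, each = config$burst_size) +
          rep((seq_len(config$burst_size) - 1) * config$burst_gap_minutes * 60,
              times = k)
        det_rows[[length(det_rows) + 1]] <- data.frame(
          camera_id = cam_id,
          site = deployments$site[deployments$camera_id == cam_id],
          species = profile$name, timestamp = burst,
          stringsAsFactors = FALSE)
      }
    }
    det <- if (length(det_rows) > 0) do.call(rbind, det_rows) else NULL
    detections <- if (is.null(det)) detection_table() else
      detection_table(det$camera_id, det$site, det$species, det$timestamp)
    nm <- names(n_events)
    ov <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      ov[i, j] <- true_overlap(config$species[[i]], config$species[[j]])
    }
    list(detections = detections,
         deployments = deployment_table(deployments$camera_id,
                                        deployments$site,
                                        deployments$operating_days),
         truth = list(profiles = config$species, n_events = n_events,
                      true_overlap = ov, seed = config$seed))
  })
}
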