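# Clock time -> circular coordinates, diel period classification and
# per-species period-use summaries.

#' Convert timestamps to radian time of day
#'
#' Maps clock time to the circle: midnight is 0, 06:00 is `pi/2`, noon is
#' `pi`. Dates are ignored.
#'
#' @param timestamp `POSIXct` vector (or character parseable as
#'   `"YYYY-MM-DD HH:MM"`), or a numeric vector of hours since midnight.
#' @return Angles in `[0, 2*pi)`.
#' @export
to_radians <- function(timestamp) {
  if (is.character(timestamp)) timestamp <- .parse_timestamp(timestamp)
  if (inherits(timestamp, "POSIXct")) {
    lt <- as.POSIXlt(timestamp, tz = "UTC")
    hours <- lt$hour + lt$min / 60 + lt$sec / 3600
  } else if (is.numeric(timestamp)) {
    hours <- timestamp %% 24
  } else {
    stop("timestamp must be POSIXct, character, or numeric hours")
  }
  wrap_angle(2 * pi * hours / 24)
}

.hm_to_min <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) as.integer(p[1]) * 60L + as.integer(p[2]), integer(1))
}

#' Diel period specification
#'
#' Defines the four clock windows (night, dawn, day, dusk) that partition
#' the 24-h day at minute resolution; dawn and dusk jointly form twilight.
#' Windows are half-open: the end minute is excluded, so with the defaults
#' 04:59 is night and 05:00 is dawn. The default windows are
#' night 19:00-05:00, dawn 05:00-07:00, day 07:00-17:00, dusk 17:00-19:00
#' (availabilities 10/24, 10/24 and 4/24 of the day for night, day and
#' twilight).
#'
#' @param night,dawn,day,dusk length-2 character vectors `c(start, end)` in
#'   `"HH:MM"`; a window wraps midnight when end <= start.
#' @return An object of class `diel_period_spec` with the windows, the block
#'   boundaries, and the availability fractions `pi_night`, `pi_day`,
#'   `pi_twilight`.
#' @export
diel_period_spec <- function(night = c("19:00", "05:00"),
                             dawn = c("05:00", "07:00"),
                             day = c("07:00", "17:00"),
                             dusk = c("17:00", "19:00")) {
  windows <- list(night = night, dawn = dawn, day = day, dusk = dusk)
  mins <- lapply(windows, function(w) {
    s <- .hm_to_min(w[1]); e <- .hm_to_min(w[2])
    if (anyNA(c(s, e))) stop("windows must be 'HH:MM' strings")
    if (e <= s) e <- e + 1440L  # wraps midnight
    c(start = s, end = e)
  })
  # partition check: each of the 1440 minutes labelled exactly once
  cover <- integer(1440)
  for (m in mins) {
    idx <- (m["start"]:(m["end"] - 1L)) %% 1440L + 1L
    cover[idx] <- cover[idx] + 1L
  }
  if (any(cover != 1L))
    stop("period windows must partition the 24-h day exactly (",
         sum(cover == 0L), " uncovered, ", sum(cover > 1L), " overlapping minutes)")
  hours <- vapply(mins, function(m) (m["end"] - m["start"]) / 60, numeric(1))
  spec <- list(windows = windows, minutes = mins,
               hours = c(night = unname(hours["night"]),
                         day = unname(hours["day"]),
                         twilight = unname(hours["dawn"] + hours["dusk"])),
               pi_night = unname(hours["night"]) / 24,
               pi_day = unname(hours["day"]) / 24,
               pi_twilight = unname(hours["dawn"] + hours["dusk"]) / 24)
  class(spec) <- "diel_period_spec"
  spec
}

#' Availability fractions of the three diel periods
#'
#' @param spec a [diel_period_spec()].
#' @return Named numeric vector `(night, day, twilight)` summing to 1.
#' @export
period_availability <- function(spec = diel_period_spec()) {
  c(night = spec$pi_night, day = spec$pi_day, twilight = spec$pi_twilight)
}

#' Classify timestamps into diel periods
#'
#' @param timestamp `POSIXct`/character timestamps or numeric hours.
#' @param spec a [diel_period_spec()].
#' @param collapse_twilight if `TRUE` (default) dawn and dusk are both
#'   labelled `"twilight"`; otherwise the four labels are kept.
#' @return Factor of period labels, one per timestamp.
#' @export
classify_period <- function(timestamp, spec = diel_period_spec(),
                            collapse_twilight = TRUE) {
  theta <- to_radians(timestamp)
  # epsilon guards the float round trip hours -> radians -> minutes
  minute <- floor(theta / (2 * pi) * 1440 + 1e-6) %% 1440
  lab <- character(length(minute))
  for (nm in names(spec$minutes)) {
    m <- spec$minutes[[nm]]
    idx0 <- (m["start"]:(m["end"] - 1L)) %% 1440L
    lab[minute %in% idx0] <- nm
  }
  if (collapse_twilight) {
    lab[lab %in% c("dawn", "dusk")] <- "twilight"
    factor(lab, levels = c("night", "day", "twilight"))
  } else {
    factor(lab, levels = c("night", "dawn", "day", "dusk"))
  }
}

# Five clock blocks used in period-use summaries: late night (0000-0459),
# dawn (0500-0659), day (0700-1659), dusk (1700-1859), early night
# (1900-2359). Derived from the spec's windows by splitting night at
# midnight.
.classify_block <- function(timestamp, spec = diel_period_spec()) {
  theta <- to_radians(timestamp)
  minute <- floor(theta / (2 * pi) * 1440 + 1e-6) %% 1440
  lab4 <- as.character(classify_period(timestamp, spec, collapse_twilight = FALSE))
  block <- lab4
  night_first_half <- lab4 == "night" & minute < .hm_to_min(spec$windows$night[1])
  block[lab4 == "night"] <- ifelse(night_first_half[lab4 == "night"],
                                   "night_late", "night_early")
  factor(block, levels = c("night_late", "dawn", "day", "dusk", "night_early"))
}

#' Per-species diel period proportions
#'
#' For each species, the proportion of independent events falling in each of
#' five clock blocks (late night 0000-0459, dawn, day, dusk, early night
#' 1900-2359 under the default spec) and aggregated over the three periods
#' night / day / twilight. Proportions sum to 1 per species; the night
#' proportion is the sum of the two night blocks.
#'
#' @param events an event table (or any [detection_table()]).
#' @param spec a [diel_period_spec()].
#' @return Data frame with one row per species: `species`, `n`, the five
#'   block proportions, and `night`, `day`, `twilight`.
#' @export
period_proportions <- function(events, spec = diel_period_spec()) {
  df <- as.data.frame(events)
  if (nrow(df) == 0)
    return(data.frame(species = character(), n = integer()))
  block <- .classify_block(df$timestamp, spec)
  tab <- table(species = df$species, block = block)
  prop <- prop.table(tab, margin = 1)
  out <- data.frame(species = rownames(tab),
                    n = as.integer(rowSums(tab)),
                    stringsAsFactors = FALSE)
  for (b in colnames(prop)) out[[b]] <- as.numeric(prop[, b])
  out$night <- out$night_late + out$night_early
  out$day <- out$day
  out$twilight <- out$dawn + out$dusk
  rownames(out) <- NULL
  out[order(out$species), , drop = FALSE]
}
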