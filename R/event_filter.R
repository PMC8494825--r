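# Independence filtering of photo records and effort-standardised capture
# frequencies.

#' Collapse photos into independent detection events
#'
#' Within each (camera, species) series sorted by time, a photo taken within
#' `window_minutes` of the previously *retained* photo of that series is
#' absorbed into the current event (gap-chaining); otherwise it opens a new
#' event. A gap of exactly `window_minutes` is absorbed. The event carries
#' the timestamp of its first photo. Photos at different cameras are never
#' merged, whatever their spacing.
#'
#' With `anchor = "first"` the window is instead measured from the event's
#' first photo, so long bursts are broken into fixed-width events.
#'
#' @param detections a [detection_table()].
#' @param window_minutes independence window in minutes (default 30;
#'   0 keeps every photo with a distinct timestamp).
#' @param anchor `"previous"` (gap-chaining, default) or `"first"`
#'   (fixed window from the event's first photo).
#' @return A [detection_table()] of independent events (class
#'   `event_table` prepended).
#' @export
independent_events <- function(detections, window_minutes = 30,
                               anchor = c("previous", "first")) {
  anchor <- match.arg(anchor)
  if (!is.numeric(window_minutes) || length(window_minutes) != 1 ||
      is.na(window_minutes) || window_minutes < 0)
    stop("window_minutes must be a single non-negative number")
  df <- as.data.frame(detections)
  if (nrow(df) == 0) {
    out <- detection_table()
    class(out) <- c("event_table", class(out))
    return(out)
  }
  df <- df[order(df$camera_id, df$species, df$timestamp), , drop = FALSE]
  grp <- paste(df$camera_id, df$species, sep = "\r")
  keep <- logical(nrow(df))
  win <- window_minutes * 60  # seconds
  for (g in split(seq_len(nrow(df)), grp)) {
    ref <- -Inf
    first <- -Inf
    for (i in g) {
      t <- as.numeric(df$timestamp[i])
      cmp <- if (anchor == "previous") ref else first
      if (t - cmp > win) {
        keep[i] <- TRUE
        first <- t
      }
      ref <- t
    }
  }
  out <- df[keep, , drop = FALSE]
  out <- out[order(out$camera_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_table", "detection_table", "data.frame")
  out
}

#' Events per 100 camera-trap days
#'
#' @param n_events event count(s).
#' @param effort_days camera-trap days of effort (> 0).
#' @return Capture frequency in events per 100 camera-trap days.
#' @export
capture_rate <- function(n_events, effort_days) {
  stopifnot(all(effort_days > 0))
  100 * n_events / effort_days
}

#' Capture frequency per species and site
#'
#' One row per (species, site) pair with the independent-event count and the
#' photo-capture frequency (independent events per 100 camera-trap days for
#' that site's pooled effort). Species/site combinations with no events get
#' an explicit zero row.
#'
#' @param events an event table from [independent_events()].
#' @param deployments a [deployment_table()] covering every detection camera.
#' @return Data frame with columns `species`, `site`, `n_events`, `rate`
#'   (full precision) and `rate_display` (rounded to 2 decimals).
#' @export
capture_frequency <- function(events, deployments) {
  .check_cameras_deployed(events, deployments)
  eff <- site_effort(deployments)
  if (any(eff$effort_days <= 0))
    stop("site(s) with zero effort: ",
         paste(eff$site[eff$effort_days <= 0], collapse = ", "))
  species <- sort(unique(events$species))
  combos <- expand.grid(species = species, site = eff$site,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(combos) == 0) {
    return(data.frame(species = character(), site = character(),
                      n_events = integer(), rate = numeric(),
                      rate_display = numeric()))
  }
  cnt <- as.data.frame(table(species = events$species, site = events$site),
                       stringsAsFactors = FALSE)
  names(cnt)[3] <- "n_events"
  out <- merge(combos, cnt, by = c("species", "site"), all.x = TRUE)
  out$n_events[is.na(out$n_events)] <- 0L
  out <- merge(out, eff, by = "site")
  out$rate <- capture_rate(out$n_events, out$effort_days)
  out$rate_display <- round(out$rate, 2)
  out <- out[order(out$species, out$site),
             c("species", "site", "n_events", "rate", "rate_display")]
  rownames(out) <- NULL
  out
}
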