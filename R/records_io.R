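# Reading, validating and writing detection and deployment tables.
# Timestamps are naive local clock time (the study clock, GMT+8); they are
# parsed as UTC internally purely to avoid daylight-saving arithmetic.

.parse_timestamp <- function(x) {
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                            "%Y/%m/%d %H:%M:%OS", "%Y/%m/%d %H:%M",
                            "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M"),
             optional = TRUE)
}

#' Construct a detection table
#'
#' @param camera_id,site,species character vectors (recycled to a common
#'   length).
#' @param timestamp `POSIXct` vector, or character parseable as
#'   `"YYYY-MM-DD HH:MM"`.
#' @return A `data.frame` of class `detection_table`, sorted by
#'   `(camera_id, timestamp)`.
#' @export
detection_table <- function(camera_id = character(), site = character(),
                            species = character(), timestamp = as.POSIXct(character(), tz = "UTC")) {
  if (is.character(timestamp)) {
    ts <- .parse_timestamp(timestamp)
    if (anyNA(ts) && !anyNA(timestamp)) {
      bad <- which(is.na(ts))
      stop("unparseable timestamp(s) at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
    }
    timestamp <- ts
  }
  df <- data.frame(camera_id = as.character(camera_id),
                   site = as.character(site),
                   species = as.character(species),
                   timestamp = timestamp,
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(!nzchar(df$species)) || anyNA(df$species))
      stop("species labels must be non-empty")
    if (anyNA(df$timestamp))
      stop("timestamps must be complete")
    df <- df[order(df$camera_id, df$timestamp), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("detection_table", "data.frame")
  df
}

#' Construct a deployment table
#'
#' One row per camera with its site and total operating effort in
#' camera-trap days.
#'
#' @param camera_id,site character vectors.
#' @param operating_days positive numeric vector of camera-trap days.
#' @return A `data.frame` of class `deployment_table`.
#' @export
deployment_table <- function(camera_id = character(), site = character(),
                             operating_days = numeric()) {
  df <- data.frame(camera_id = as.character(camera_id),
                   site = as.character(site),
                   operating_days = as.numeric(operating_days),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (anyNA(df$operating_days) || any(df$operating_days <= 0))
      stop("operating_days must be positive")
    key <- paste(df$camera_id, df$site, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate camera_id: ",
           paste(unique(df$camera_id[duplicated(key)]), collapse = ", "))
  }
  class(df) <- c("deployment_table", "data.frame")
  df
}

#' Read camera-trap detections from a delimited text file
#'
#' Expected columns (renameable through `schema`): `camera_id`, `site`,
#' `species`, `timestamp` with timestamps in `"YYYY-MM-DD HH:MM"` local
#' time. Rows are returned sorted by `(camera_id, timestamp)`.
#'
#' @param path file path.
#' @param schema named character vector mapping canonical names to the
#'   file's column names, e.g. `c(timestamp = "DateTime")`.
#' @param sep field delimiter (default comma).
#' @return A [detection_table()].
#' @export
read_detections <- function(path, schema = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  cols <- c(camera_id = "camera_id", site = "site",
            species = "species", timestamp = "timestamp")
  if (!is.null(schema)) cols[names(schema)] <- schema
  missing_cols <- cols[!cols %in% names(raw)]
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) return(detection_table())
  ts <- .parse_timestamp(raw[[cols["timestamp"]]])
  if (anyNA(ts)) {
    bad <- which(is.na(ts)) + 1L  # +1 for the header line
    stop("unparseable timestamp at line(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  detection_table(camera_id = raw[[cols["camera_id"]]],
                  site = raw[[cols["site"]]],
                  species = raw[[cols["species"]]],
                  timestamp = ts)
}

#' Read camera deployments from a delimited text file
#'
#' Expected columns: `camera_id`, `site`, `operating_days`.
#'
#' @inheritParams read_detections
#' @return A [deployment_table()].
#' @export
read_deployments <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, quote = "\"",
                           comment.char = "")
  need <- c("camera_id", "site", "operating_days")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  deployment_table(camera_id = raw$camera_id, site = raw$site,
                   operating_days = raw$operating_days)
}

#' Write a detections or deployments table to CSV
#'
#' Writes with a header row, stable column order, and timestamps formatted
#' as `"YYYY-MM-DD HH:MM"`, so that a write/read round trip reproduces the
#' table exactly.
#'
#' @param x a [detection_table()], [deployment_table()], or plain data frame.
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path, sep = ",") {
  out <- as.data.frame(x)
  if ("timestamp" %in% names(out) && inherits(out$timestamp, "POSIXct"))
    out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M", tz = "UTC")
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-site camera-trap effort
#'
#' @param deployments a [deployment_table()].
#' @return A data frame with columns `site` and `effort_days` (sum of member
#'   cameras' operating days).
#' @export
site_effort <- function(deployments) {
  agg <- stats::aggregate(operating_days ~ site, data = as.data.frame(deployments), FUN = sum)
  names(agg)[2] <- "effort_days"
  agg[order(agg$site), , drop = FALSE]
}

# Every detection camera must be in the deployment table before effort-based
# statistics are computed.
.check_cameras_deployed <- function(detections, deployments) {
  missing_cams <- setdiff(unique(detections$camera_id), deployments$camera_id)
  if (length(missing_cams) > 0)
    stop("camera(s) absent from deployment table: ",
         paste(utils::head(missing_cams, 10), collapse = ", "))
  invisible(TRUE)
}
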