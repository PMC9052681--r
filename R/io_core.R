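# Core data model: detection, station, deployment and environmental tables,
# plus the geodesy and calendar-day helpers shared by every analysis stage.
# All timestamps are stored as POSIXct in UTC; calendar-day operations apply a
# configurable fixed offset (default +3 h, local time at the study site).

REGION_CODES <- c("CH", "C", "W", "S", "N", "OFFSHORE")

#' Default fixed UTC offset (hours) for calendar-day operations
#'
#' Local time at the Sudanese Red Sea coast is UTC+3 year-round; the day
#' boundary used by daily-presence and residence-index calculations is
#' configurable because archived detection exports carry UTC timestamps only.
#' @export
DEFAULT_TZ_OFFSET <- 3

#' Mean Earth radius (m) used for all great-circle distances
#' @export
EARTH_RADIUS_M <- 6371000

parse_utc <- function(x, what = "timestamp") {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (f in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
              "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], format = f, tz = "UTC"),
                            tz = "UTC")
  }
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop(sprintf("unparseable %s at row(s) %s: '%s'", what,
                 paste(head(bad, 5L), collapse = ", "), x[bad[1L]]),
         call. = FALSE)
  }
  out
}

#' Great-circle distance in metres
#'
#' Haversine distance on a sphere of radius 6,371 km, the accuracy class
#' appropriate for receiver-to-receiver distances of a coastal array.
#' Vectorised over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84).
#' @return distance(s) in metres.
#' @examples
#' haversine_m(0, 0, 1, 0)   # ~111,195 m, one degree of latitude
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  ok <- function(lat, lon) all(lat >= -90 & lat <= 90, na.rm = TRUE) &&
    all(lon > -180 & lon <= 180, na.rm = TRUE)
  if (!ok(lat1, lon1) || !ok(lat2, lon2)) {
    stop("coordinates out of range: lat in [-90,90], lon in (-180,180]",
         call. = FALSE)
  }
  n <- max(length(lat1), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M))
}

#' Map a UTC instant to a local calendar day
#'
#' @param timestamp POSIXct (UTC).
#' @param tz_offset fixed offset from UTC in hours (default +3).
#' @return `Date` vector.
#' @export
to_calendar_day <- function(timestamp, tz_offset = DEFAULT_TZ_OFFSET) {
  as.Date(as.POSIXct(as.numeric(timestamp) + tz_offset * 3600,
                     origin = "1970-01-01", tz = "UTC"))
}

#' Read a receiver station table
#'
#' Expects columns `receiver_id,lat,lon,region,active_start,active_end`, one
#' row per activity interval (repeated rows per receiver allowed). Intervals
#' of one receiver must not overlap.
#'
#' @param path CSV file path.
#' @return data.frame with parsed activity intervals.
#' @export
read_receivers <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("receiver_id", "lat", "lon", "region", "active_start", "active_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("receivers file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$receiver_id <- as.character(df$receiver_id)
  df$active_start <- parse_utc(df$active_start, "active_start")
  df$active_end <- parse_utc(df$active_end, "active_end")
  validate_stations(df)
  df
}

validate_stations <- function(stations) {
  stopifnot(is.data.frame(stations))
  if (any(stations$lat < -90 | stations$lat > 90) ||
      any(stations$lon <= -180 | stations$lon > 180)) {
    stop("station coordinates out of range", call. = FALSE)
  }
  bad <- setdiff(unique(stations$region), REGION_CODES)
  if (length(bad)) stop("unknown region code(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (id in unique(stations$receiver_id)) {
    iv <- stations[stations$receiver_id == id, ]
    if (nrow(iv) > 1L) {
      o <- order(iv$active_start)
      if (any(diff(order(iv$active_start[o])) < 0) ||
          any(head(iv$active_end[o], -1) > tail(iv$active_start[o], -1))) {
        stop("overlapping active intervals for receiver ", id, call. = FALSE)
      }
    }
    if (any(iv$active_end <= iv$active_start)) {
      stop("empty active interval for receiver ", id, call. = FALSE)
    }
  }
  invisible(stations)
}

#' Unique station positions (one row per receiver)
#' @param stations station table as from [read_receivers()].
#' @export
station_positions <- function(stations) {
  unique(stations[, c("receiver_id", "lat", "lon", "region")])
}

#' Read an acoustic detection table
#'
#' Expects columns `timestamp,receiver_id,tag_id` (VUE-style export). Rows
#' are returned sorted by tag, then timestamp, ties broken by receiver then
#' tag so that downstream scans are deterministic.
#'
#' @param path CSV file path.
#' @param stations station table; detections at unknown receivers are an
#'   error naming the offending IDs.
#' @return data.frame with columns `tag_id, receiver_id, timestamp, valid`.
#' @export
read_detections <- function(path, stations) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "receiver_id", "tag_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("detections file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) {
    warning("empty detections file: ", path, call. = FALSE)
    return(data.frame(tag_id = character(), receiver_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      valid = logical()))
  }
  df$timestamp <- parse_utc(df$timestamp)
  df$receiver_id <- as.character(df$receiver_id)
  df$tag_id <- as.character(df$tag_id)
  unknown <- setdiff(unique(df$receiver_id), unique(stations$receiver_id))
  if (length(unknown)) {
    rows <- which(df$receiver_id %in% unknown)
    stop(sprintf("detections reference unknown receiver(s) %s (rows %s)",
                 paste(unknown, collapse = ", "),
                 paste(head(rows, 10L), collapse = ", ")), call. = FALSE)
  }
  out <- df[, c("tag_id", "receiver_id", "timestamp")]
  out$valid <- TRUE
  out <- sort_detections(out)
  message(sprintf("read %d detections from %s", nrow(out), path))
  out
}

#' Deterministic detection ordering
#'
#' Sorts by (tag_id, timestamp, receiver_id): stable total order with ties
#' broken lexicographically so identical inputs always yield identical scans.
#' @param detections detection data.frame.
#' @export
sort_detections <- function(detections) {
  o <- order(detections$tag_id, detections$timestamp,
             detections$receiver_id, method = "radix")
  out <- detections[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a tag deployment table
#'
#' Columns `animal_id,tag_id,release_time,sex,wingspan_cm,maturity,
#' satellite_tag`. One acoustic tag per animal; wingspans must be positive.
#' @param path CSV file path.
#' @export
read_deployments <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "tag_id", "release_time", "sex", "wingspan_cm",
            "maturity", "satellite_tag")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("deployments file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$release_time <- parse_utc(df$release_time, "release_time")
  stopifnot(all(df$wingspan_cm > 0),
            all(df$sex %in% c("F", "M")),
            all(df$maturity %in% c("immature", "mature")),
            all(df$satellite_tag %in% c("none", "SPOT", "PSAT")))
  if (anyDuplicated(df$animal_id) || anyDuplicated(df$tag_id)) {
    stop("one active acoustic tag per animal required", call. = FALSE)
  }
  df
}

#' Read a daily environmental series (chlorophyll-a and lunar fraction)
#'
#' Columns `date,chla,moon_frac`; one row per date with no gaps. Short gaps
#' can be linearly interpolated (flagged in an `interpolated` column).
#'
#' @param path CSV file path.
#' @param max_gap_days largest internal gap to fill by interpolation.
#' @export
read_environment <- function(path, max_gap_days = 5) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "chla", "moon_frac")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("environment file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$date <- as.Date(df$date)
  df <- df[order(df$date), ]
  if (anyDuplicated(df$date)) stop("duplicate environment dates", call. = FALSE)
  full <- data.frame(date = seq(min(df$date), max(df$date), by = "day"))
  out <- merge(full, df, by = "date", all.x = TRUE)
  out$interpolated <- is.na(out$chla) | is.na(out$moon_frac)
  if (any(out$interpolated)) {
    runs <- rle(out$interpolated)
    if (max(runs$lengths[runs$values]) > max_gap_days) {
      stop("environment series has gaps longer than ", max_gap_days, " days",
           call. = FALSE)
    }
    for (v in c("chla", "moon_frac")) {
      out[[v]] <- approx(full$date, df[[v]][match(full$date, df$date)],
                         xout = as.numeric(full$date), rule = 2)$y
    }
  }
  stopifnot(all(out$chla >= 0), all(out$moon_frac >= -1e-9 & out$moon_frac <= 1 + 1e-9))
  out$moon_frac <- pmin(pmax(out$moon_frac, 0), 1)
  out
}

#' Write a detection table in the canonical CSV dialect
#'
#' ISO-8601 UTC timestamps; round-trips field-for-field through
#' [read_detections()].
#' @param detections detection data.frame.
#' @param path output CSV path.
#' @export
write_detections <- function(detections, path) {
  out <- detections
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @importFrom stats approx
NULL
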