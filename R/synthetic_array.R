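# Synthetic receiver array emulating the Dungonab Bay layout: 15 in-bay
# stations in five regions (channel, central, west, south, north) spaced at
# least 1 km apart, the two furthest in-bay stations (N1, S3) 29 km apart,
# plus two offshore stations roughly 70 and 125 km from the array centroid.

.DUNGONAB_STATIONS <- data.frame(
  receiver_id = c("CH1", "CH2", "CH3",
                  "C1", "C2", "C3",
                  "W1", "W2", "W3",
                  "S1", "S2", "S3", "S4", "S5",
                  "N1",
                  "OFF1", "OFF2"),
  lat = c(20.800, 20.789, 20.806,
          20.840, 20.851, 20.862,
          20.880, 20.868, 20.896,
          20.760, 20.748, 20.757, 20.770, 20.766,
          21.0173,
          20.218, 19.720),
  lon = c(37.280, 37.293, 37.266,
          37.230, 37.244, 37.228,
          37.180, 37.196, 37.168,
          37.240, 37.220, 37.258, 37.198, 37.276,
          37.240,
          37.400, 37.440),
  region = c("CH", "CH", "CH", "C", "C", "C", "W", "W", "W",
             "S", "S", "S", "S", "S", "N", "OFFSHORE", "OFFSHORE"),
  stringsAsFactors = FALSE)

#' Synthetic Dungonab-style receiver array
#'
#' Fifteen in-bay stations in five regions at least 1 km apart (N1 to S3
#' spanning 29 km) plus two offshore stations ~70 and ~125 km away. A
#' configurable subset of in-bay receivers stops early, emulating battery
#' failure towards the end of a deployment and producing a varying
#' active-receiver count (the `nStations` effort covariate).
#'
#' @param start,end activity window (Date or POSIXct, UTC).
#' @param battery_failures named vector of early end times (receiver_id ->
#'   end), or `NULL` for the default pattern: three receivers failing over
#'   the final four months of the window.
#' @return station table with one row per activity interval.
#' @export
dungonab_array <- function(start = as.Date("2012-10-28"),
                           end = as.Date("2014-10-24"),
                           battery_failures = NULL) {
  st <- .DUNGONAB_STATIONS
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (is.null(battery_failures)) {
    span <- as.numeric(difftime(end, start, units = "days"))
    if (span > 240) {
      fail_at <- end - c(120, 90, 50) * 86400
      battery_failures <- setNames(fail_at, c("S4", "W3", "CH3"))
    } else {
      battery_failures <- setNames(as.POSIXct(character(), tz = "UTC"),
                                   character())
    }
  }
  st$active_start <- start
  st$active_end <- end
  if (length(battery_failures)) {
    idx <- match(names(battery_failures), st$receiver_id)
    st$active_end[idx] <- as.POSIXct(battery_failures, tz = "UTC")
  }
  validate_stations(st)
  st
}

#' Number of active receivers at given instants
#'
#' @param stations station table (rows are activity intervals).
#' @param times POSIXct vector.
#' @param regions regions to count (default: all in-bay, i.e. not OFFSHORE).
#' @return integer vector parallel to `times`.
#' @export
n_active_stations <- function(stations, times,
                              regions = setdiff(REGION_CODES, "OFFSHORE")) {
  st <- stations[stations$region %in% regions, ]
  out <- integer(length(times))
  for (i in seq_len(nrow(st))) {
    out <- out + (times >= st$active_start[i] & times <= st$active_end[i])
  }
  out
}
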