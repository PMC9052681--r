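# Detection quality control: the three filtering rules applied, in order,
# to a raw detection table -- (1) isolated single detections (except at
# offshore stations, where lone detections are considered valid), (2)
# detections within 48 h of release, (3) detections implying swim speeds
# above 2 m/s between receivers -- followed by the two-detections-per-day
# presence rule. Each removed record is attributed to exactly one stage.

#' Remove isolated single detections
#'
#' A detection is removed iff no other detection of the same tag exists
#' anywhere in the array within +/- `window_min` minutes, unless its
#' receiver's region is exempt (offshore stations by default, where low tag
#' density makes false detections unlikely and lone records are retained).
#'
#' @param detections detection table sorted per tag.
#' @param stations station table (for region lookup).
#' @param window_min isolation window, minutes.
#' @param exempt_regions regions whose lone detections are kept.
#' @return list `retained`, `removed`.
#' @export
remove_isolated_singles <- function(detections, stations, window_min = 60,
                                    exempt_regions = "OFFSHORE") {
  if (nrow(detections) == 0L) return(list(retained = detections,
                                          removed = detections))
  det <- sort_detections(detections)
  pos <- station_positions(stations)
  region <- pos$region[match(det$receiver_id, pos$receiver_id)]
  w <- window_min * 60
  iso <- rep(TRUE, nrow(det))
  tt <- as.numeric(det$timestamp)
  for (tag in unique(det$tag_id)) {
    ix <- which(det$tag_id == tag)
    if (length(ix) == 1L) next
    t <- tt[ix]
    near_prev <- c(FALSE, diff(t) <= w)
    near_next <- c(diff(t) <= w, FALSE)
    iso[ix] <- !(near_prev | near_next)
  }
  drop <- iso & !(region %in% exempt_regions)
  message(sprintf("isolated-single filter removed %d of %d detections",
                  sum(drop), nrow(det)))
  list(retained = det[!drop, , drop = FALSE],
       removed = det[drop, , drop = FALSE])
}

#' Remove detections within a post-release settling window
#'
#' Excludes detections earlier than `hours` after the tagging release, so
#' that capture-associated behaviour does not enter the analysis. The clock
#' uses exact timestamps.
#'
#' @param detections detection table.
#' @param deployments deployment table with `tag_id` and `release_time`.
#' @param hours exclusion window after release (default 48).
#' @return list `retained`, `removed`.
#' @export
remove_post_release <- function(detections, deployments, hours = 48) {
  if (nrow(detections) == 0L) return(list(retained = detections,
                                          removed = detections))
  i <- match(detections$tag_id, deployments$tag_id)
  if (anyNA(i)) {
    stop("no deployment row for tag(s): ",
         paste(unique(detections$tag_id[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  cutoff <- deployments$release_time[i] + hours * 3600
  drop <- detections$timestamp < cutoff
  message(sprintf("post-release filter removed %d of %d detections",
                  sum(drop), nrow(detections)))
  list(retained = detections[!drop, , drop = FALSE],
       removed = detections[drop, , drop = FALSE])
}

#' Swim-speed filter
#'
#' Scans each tag's chronological sequence; whenever consecutive detections
#' at different receivers imply a straight-line (great-circle) speed above
#' `vmax`, the later detection is removed and the scan re-evaluates the next
#' detection against the surviving predecessor. Same-receiver pairs are
#' never removed. Removing the later record preserves the already-validated
#' earlier track; set `drop = "both"` to remove both ends of a violating
#' pair instead.
#'
#' @param detections detection table.
#' @param stations station table with coordinates.
#' @param vmax maximum plausible sustained speed, m/s (default 2).
#' @param drop `"later"` (default) or `"both"`.
#' @return list `retained`, `removed`.
#' @export
speed_filter <- function(detections, stations, vmax = 2.0,
                         drop = c("later", "both")) {
  drop <- match.arg(drop)
  if (nrow(detections) == 0L) return(list(retained = detections,
                                          removed = detections))
  det <- sort_detections(detections)
  pos <- station_positions(stations)
  ri <- match(det$receiver_id, pos$receiver_id)
  tt <- as.numeric(det$timestamp)
  # pairwise receiver distance matrix (small)
  D <- outer(seq_len(nrow(pos)), seq_len(nrow(pos)), function(a, b) {
    haversine_m(pos$lat[a], pos$lon[a], pos$lat[b], pos$lon[b])
  })
  keep <- rep(TRUE, nrow(det))
  for (tag in unique(det$tag_id)) {
    ix <- which(det$tag_id == tag)
    if (length(ix) < 2L) next
    last <- NA_integer_
    for (k in ix) {
      if (is.na(last)) { last <- k; next }
      d <- D[ri[last], ri[k]]
      dt <- tt[k] - tt[last]
      if (d > 0 && (dt <= 0 || d / dt > vmax)) {
        keep[k] <- FALSE
        if (drop == "both") {
          keep[last] <- FALSE
          prev <- ix[ix < last & keep[ix]]
          last <- if (length(prev)) max(prev) else NA_integer_
        }
        # with drop = "later" the scan continues against the survivor
      } else {
        last <- k
      }
    }
  }
  message(sprintf("speed filter removed %d of %d detections",
                  sum(!keep), nrow(det)))
  list(retained = det[keep, , drop = FALSE],
       removed = det[!keep, , drop = FALSE])
}

#' Run the full QC cascade
#'
#' Applies the three filters in the documented order (isolated singles,
#' post-release, speed), tags every record with its removal stage, and
#' returns a conservation-checked filter report. Because a removal can make
#' a previously supported record isolated (or expose a new speed
#' violation), the cascade is repeated until no further record is removed
#' (usually two passes); each record keeps the stage that removed it, so the
#' whole pipeline is idempotent on its own output.
#'
#' @param detections raw detection table.
#' @param stations,deployments supporting tables.
#' @param window_min,exempt_regions,hours,vmax stage parameters.
#' @param max_passes safety bound on cascade iterations.
#' @return list: `retained` (with `qc_stage = "retained"`), `all` (every
#'   input record with its `qc_stage`), `report` (a `filter_report`),
#'   `per_animal` stage breakdown, `passes`.
#' @export
filter_detections <- function(detections, stations, deployments,
                              window_min = 60, exempt_regions = "OFFSHORE",
                              hours = 48, vmax = 2.0, max_passes = 10) {
  det <- sort_detections(detections)
  stage <- function(df, lab) {
    if (nrow(df)) df$qc_stage <- lab
    df
  }
  removed <- det[0, , drop = FALSE]
  removed$qc_stage <- character(0)
  current <- det
  passes <- 0L
  repeat {
    passes <- passes + 1L
    s1 <- remove_isolated_singles(current, stations, window_min,
                                  exempt_regions)
    s2 <- remove_post_release(s1$retained, deployments, hours)
    s3 <- speed_filter(s2$retained, stations, vmax)
    removed <- rbind(removed,
                     stage(s1$removed, "isolated_single"),
                     stage(s2$removed, "post_release"),
                     stage(s3$removed, "speed"))
    n_removed <- nrow(s1$removed) + nrow(s2$removed) + nrow(s3$removed)
    current <- s3$retained
    if (n_removed == 0L || passes >= max_passes) break
  }
  all <- sort_detections(rbind(removed, stage(current, "retained")))
  counts <- table(factor(all$qc_stage,
                         levels = c("isolated_single", "post_release",
                                    "speed", "retained")))
  report <- filter_report(n_raw = nrow(det),
                          n_isolated_singles = unname(counts["isolated_single"]),
                          n_post_release = unname(counts["post_release"]),
                          n_speed = unname(counts["speed"]),
                          n_retained = unname(counts["retained"]))
  by_animal <- table(all$tag_id, all$qc_stage)
  list(retained = current, all = all, report = report,
       per_animal = as.data.frame.matrix(by_animal), passes = passes)
}

#' Construct and validate a filter report
#'
#' Enforces the conservation identity: retained = raw - singles -
#' post-release - speed (each record removed by exactly one stage, stages
#' applied in the documented order).
#'
#' @param n_raw,n_isolated_singles,n_post_release,n_speed,n_retained counts.
#' @return named numeric vector of class `filter_report`.
#' @export
filter_report <- function(n_raw, n_isolated_singles, n_post_release,
                          n_speed, n_retained = NULL) {
  expected <- n_raw - n_isolated_singles - n_post_release - n_speed
  if (is.null(n_retained)) n_retained <- expected
  if (n_retained != expected) {
    stop(sprintf(
      "filter report violates conservation: %d - %d - %d - %d = %d != %d",
      n_raw, n_isolated_singles, n_post_release, n_speed, expected,
      n_retained), call. = FALSE)
  }
  structure(c(n_raw = n_raw, n_isolated_singles = n_isolated_singles,
              n_post_release = n_post_release, n_speed = n_speed,
              n_retained = n_retained),
            class = "filter_report", stage_order = c("isolated_single",
                                                     "post_release", "speed"))
}

#' Daily presence matrix
#'
#' An animal is present on a calendar day iff it has at least two retained
#' detections that day. The matrix spans the first to last detection date of
#' the cohort; a cohort-level count of days with any animal present is
#' attached.
#'
#' @param detections filtered detection table.
#' @param tz_offset fixed UTC offset (hours) defining the day boundary.
#' @return list: `matrix` (logical, animals x days), `days`, `animals`,
#'   `n_days_any_present`, `n_days_total`.
#' @export
daily_presence <- function(detections, tz_offset = DEFAULT_TZ_OFFSET) {
  if (nrow(detections) == 0L) {
    return(list(matrix = matrix(logical(), 0, 0), days = as.Date(character()),
                animals = character(), n_days_any_present = 0L,
                n_days_total = 0L))
  }
  day <- to_calendar_day(detections$timestamp, tz_offset)
  days <- seq(min(day), max(day), by = "day")
  animals <- sort(unique(detections$tag_id))
  counts <- table(factor(detections$tag_id, levels = animals),
                  factor(as.character(day), levels = as.character(days)))
  m <- matrix(counts >= 2L, nrow = length(animals),
              dimnames = list(animals, as.character(days)))
  list(matrix = m, days = days, animals = animals,
       n_days_any_present = sum(colSums(m) > 0L),
       n_days_total = length(days))
}
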