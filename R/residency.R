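# Residency statistics: residence index, receiver residency-event
# segmentation (two-detection trigger, one-hour timeout), maximum
# non-residence gaps, minimum straight-line distance travelled, movement
# networks, and the cohort group comparisons (Welch's t-test on RI by sex,
# Pearson correlations of wingspan against detections and RI).

#' Residence index
#'
#' Days detected divided by days spanned from first to last detection day,
#' both endpoints inclusive (last - first + 1), which reproduces the
#' published per-animal ratios; set `inclusive = FALSE` for the
#' exclusive-span variant (last - first).
#'
#' @param detection_days number of days with confirmed presence.
#' @param track_days days between first and last detection (inclusive span).
#' @return RI in [0, 1], kept at full precision (report at 2 decimals).
#' @export
residence_index <- function(detection_days, track_days) {
  if (any(track_days <= 0)) stop("track_days must be >= 1", call. = FALSE)
  stopifnot(all(detection_days >= 0), all(detection_days <= track_days))
  round(detection_days / track_days, 4)
}

#' Per-animal residency summary
#'
#' Computes, per animal: total detections, track days (first to last
#' detection day, inclusive), detection days (days with >= 2 detections),
#' RI, minimum distance travelled and maximum consecutive days of absence --
#' the columns of a standard acoustic residency summary table.
#'
#' @param detections filtered detection table.
#' @param stations station table.
#' @param tz_offset day-boundary offset, hours.
#' @return data.frame, one row per tag, plus cohort means/SDs as attributes
#'   `cohort_mean` and `cohort_sd`.
#' @export
residency_summary <- function(detections, stations,
                              tz_offset = DEFAULT_TZ_OFFSET) {
  dp <- daily_presence(detections, tz_offset)
  dist <- min_distance_travelled(detections, stations)
  gaps <- max_nonresidence(dp)
  day <- to_calendar_day(detections$timestamp, tz_offset)
  rows <- lapply(dp$animals, function(a) {
    ix <- detections$tag_id == a
    d <- day[ix]
    track <- as.integer(max(d) - min(d)) + 1L
    detd <- sum(dp$matrix[a, ])
    data.frame(tag_id = a,
               total_detections = sum(ix),
               track_days = track,
               detection_days = detd,
               ri = residence_index(detd, track),
               min_distance_km = dist$total_km[match(a, dist$tag_id)],
               max_absence_days = gaps[a],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  num <- c("total_detections", "track_days", "detection_days", "ri",
           "min_distance_km", "max_absence_days")
  attr(out, "cohort_mean") <- vapply(out[num], mean, numeric(1))
  attr(out, "cohort_sd") <- vapply(out[num], sd, numeric(1))
  out
}

#' Segment receiver residency events
#'
#' An event is triggered by two consecutive detections of an animal at the
#' same receiver with a gap below the timeout, and ends when the animal is
#' detected at a different receiver or when the timeout elapses with no
#' further detections. A single detection at a receiver opens nothing; an
#' intervening other-receiver detection resets the candidate. Event end is
#' the last member detection's time.
#'
#' @param detections filtered, sorted detection table.
#' @param timeout_min silence that closes an open event, minutes.
#' @return data.frame of events: `tag_id, receiver_id, start, end,
#'   n_detections, duration_min`.
#' @export
segment_residency_events <- function(detections, timeout_min = 60) {
  det <- sort_detections(detections)
  w <- timeout_min * 60
  ev <- list(); ne <- 0L
  for (tag in unique(det$tag_id)) {
    d <- det[det$tag_id == tag, ]
    tt <- as.numeric(d$timestamp)
    cur_rec <- NA_character_   # receiver of the open or candidate visit
    start_i <- NA_integer_     # first detection of the visit
    last_i <- NA_integer_
    n_in <- 0L
    flush <- function(i_end) {
      if (!is.na(start_i) && n_in >= 2L) {
        ne <<- ne + 1L
        ev[[ne]] <<- data.frame(tag_id = tag, receiver_id = cur_rec,
                                start = d$timestamp[start_i],
                                end = d$timestamp[i_end],
                                n_detections = n_in,
                                stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(d))) {
      if (is.na(cur_rec)) {
        cur_rec <- d$receiver_id[i]; start_i <- i; last_i <- i; n_in <- 1L
        next
      }
      gap <- tt[i] - tt[last_i]
      if (d$receiver_id[i] != cur_rec) {
        # receiver switch closes any open event; new candidate starts here
        flush(last_i)
        cur_rec <- d$receiver_id[i]; start_i <- i; n_in <- 1L
      } else if (gap > w) {
        # timeout closes the event; same receiver starts a fresh candidate
        flush(last_i)
        start_i <- i; n_in <- 1L
      } else {
        n_in <- n_in + 1L
      }
      last_i <- i
    }
    flush(last_i)
  }
  if (!ne) {
    return(data.frame(tag_id = character(), receiver_id = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      n_detections = integer(), duration_min = numeric()))
  }
  out <- do.call(rbind, ev)
  out$duration_min <- as.numeric(difftime(out$end, out$start, units = "mins"))
  out
}

#' Maximum non-residence gap per animal
#'
#' Longest run of absent days strictly between two present days within each
#' animal's own first-to-last presence window.
#'
#' @param dp daily presence list from [daily_presence()].
#' @return named integer vector (days), one entry per animal.
#' @export
max_nonresidence <- function(dp) {
  vapply(seq_along(dp$animals), function(i) {
    p <- which(dp$matrix[i, ])
    if (length(p) < 2L) return(0L)
    max(diff(p) - 1L)
  }, integer(1)) -> g
  setNames(g, dp$animals)
}

#' Minimum distance travelled
#'
#' Sums great-circle distances between consecutive detections of each animal
#' at distinct receivers (same-receiver pairs contribute zero) per day and
#' over the whole record: a lower bound on distance actually swum.
#'
#' @param detections filtered detection table.
#' @param stations station table.
#' @param tz_offset day-boundary offset, hours.
#' @return list-like data.frame: `tag_id`, `total_km`, and attribute
#'   `daily` (tag_id, date, km).
#' @export
min_distance_travelled <- function(detections, stations,
                                   tz_offset = DEFAULT_TZ_OFFSET) {
  det <- sort_detections(detections)
  pos <- station_positions(stations)
  ri <- match(det$receiver_id, pos$receiver_id)
  tags <- unique(det$tag_id)
  daily <- list(); tot <- numeric(length(tags))
  for (k in seq_along(tags)) {
    ix <- which(det$tag_id == tags[k])
    if (length(ix) < 2L) { tot[k] <- 0; next }
    a <- ri[head(ix, -1)]; b <- ri[tail(ix, -1)]
    hop <- ifelse(a == b, 0,
                  haversine_m(pos$lat[a], pos$lon[a], pos$lat[b], pos$lon[b]))
    tot[k] <- sum(hop) / 1000
    day <- to_calendar_day(det$timestamp[tail(ix, -1)], tz_offset)
    agg <- tapply(hop / 1000, day, sum)
    daily[[k]] <- data.frame(tag_id = tags[k], date = as.Date(names(agg)),
                             km = as.numeric(agg), stringsAsFactors = FALSE)
  }
  out <- data.frame(tag_id = tags, total_km = tot, stringsAsFactors = FALSE)
  attr(out, "daily") <- do.call(rbind, daily)
  out
}

#' Movement network between receivers
#'
#' Nodes are receivers weighted by total detection count (zero-detection
#' receivers carried as isolated nodes); directed edges count consecutive
#' retained detections of an animal at two distinct receivers. An undirected
#' collapse is attached for plotting.
#'
#' @param detections filtered detection table.
#' @param stations station table (defines the node set).
#' @return list: `nodes` (receiver_id, n_detections), `edges` (from, to,
#'   weight, directed), `edges_undirected`.
#' @export
build_network <- function(detections, stations) {
  det <- sort_detections(detections)
  pos <- station_positions(stations)
  nodes <- data.frame(receiver_id = pos$receiver_id,
                      n_detections = as.integer(
                        table(factor(det$receiver_id,
                                     levels = pos$receiver_id))),
                      stringsAsFactors = FALSE)
  from <- character(0); to <- character(0)
  for (tag in unique(det$tag_id)) {
    r <- det$receiver_id[det$tag_id == tag]
    if (length(r) < 2L) next
    a <- head(r, -1); b <- tail(r, -1)
    sw <- a != b
    from <- c(from, a[sw]); to <- c(to, b[sw])
  }
  if (length(from)) {
    tab <- aggregate(list(weight = rep(1L, length(from))),
                     by = list(from = from, to = to), FUN = sum)
    key <- paste(pmin(tab$from, tab$to), pmax(tab$from, tab$to), sep = "|")
    und <- aggregate(list(weight = tab$weight), by = list(key = key), sum)
    und <- data.frame(
      a = sub("\\|.*", "", und$key), b = sub(".*\\|", "", und$key),
      weight = und$weight, stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(from = character(), to = character(), weight = integer())
    und <- data.frame(a = character(), b = character(), weight = integer())
  }
  stopifnot(sum(nodes$n_detections) == nrow(det))
  list(nodes = nodes, edges = tab, edges_undirected = und)
}

#' Convert a movement network to an igraph object
#' @param network list from [build_network()].
#' @param directed logical.
#' @export
as_igraph_network <- function(network, directed = TRUE) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("igraph not installed", call. = FALSE)
  }
  edges <- if (directed) network$edges else
    setNames(network$edges_undirected, c("from", "to", "weight"))
  igraph::graph_from_data_frame(edges, directed = directed,
                                vertices = network$nodes)
}

#' Cohort group comparisons
#'
#' Welch's unequal-variance two-sided t-test of RI between sexes, Pearson
#' correlations of wingspan against total detections and against RI, with
#' Shapiro-Wilk normality and Levene homogeneity diagnostics. Degenerate
#' groups (n < 2 or zero variance) are flagged and the test skipped.
#'
#' @param summary residency summary with columns `ri`, `total_detections`.
#' @param deployments deployment table with `tag_id`/`animal_id`, `sex`,
#'   `wingspan_cm`.
#' @param by column of `deployments` joining to `summary$tag_id`
#'   (default `"tag_id"`).
#' @return list of test results.
#' @export
group_stats <- function(summary, deployments, by = "tag_id") {
  i <- match(summary$tag_id, deployments[[by]])
  sex <- deployments$sex[i]
  size <- deployments$wingspan_cm[i]
  out <- list()
  grp <- split(summary$ri, sex)
  if (length(grp) == 2L && all(vapply(grp, length, 1L) >= 2L) &&
      all(vapply(grp, var, 1) > 0)) {
    out$welch_ri_sex <- t.test(summary$ri ~ sex)
    out$shapiro_ri <- shapiro.test(summary$ri)
    lev <- data.frame(ri = summary$ri, sex = factor(sex))
    out$levene_ri_sex <- car::leveneTest(ri ~ sex, data = lev)
  } else {
    out$welch_ri_sex <- structure(list(skipped = TRUE,
                                       reason = "degenerate group"),
                                  class = "skipped_test")
  }
  if (var(size) > 0) {
    out$pearson_size_detections <- cor.test(size, summary$total_detections,
                                            method = "pearson")
    out$pearson_size_ri <- cor.test(size, summary$ri, method = "pearson")
  }
  out
}
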