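# Shared fixture builders and independent oracles.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# Minimal station table: receivers on a north-south line `spacing_km` apart.
line_stations <- function(n = 2, spacing_km = 5, region = "C",
                          start = utc("2012-01-01"), end = utc("2015-01-01"),
                          ids = NULL) {
  lat <- 20 + (seq_len(n) - 1) * spacing_km / 111.195
  data.frame(receiver_id = ids %||% paste0("R", seq_len(n)),
             lat = lat, lon = rep(37, n),
             region = rep_len(region, n),
             active_start = start, active_end = end,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_det <- function(tag, rec, times) {
  data.frame(tag_id = tag, receiver_id = rec, timestamp = utc(times),
             valid = TRUE, stringsAsFactors = FALSE)
}

tiny_deployments <- function(tags, release = "2012-01-01 00:00:00") {
  n <- length(tags)
  data.frame(animal_id = paste0("A", seq_len(n)), tag_id = tags,
             release_time = utc(rep_len(release, n)),
             sex = rep_len(c("F", "M"), n),
             wingspan_cm = seq(250, 360, length.out = n),
             maturity = rep_len(c("mature", "immature"), n),
             satellite_tag = "none", stringsAsFactors = FALSE)
}

# ---- speed-filter oracle -------------------------------------------------
# Enumerates all keep/drop subsets of a (short) single-tag sequence; a subset
# is consistent when no consecutive kept pair at distinct receivers implies a
# speed above vmax. Among consistent subsets the scan's solution is the one
# that greedily prefers keeping earlier records (lexicographically greatest
# keep vector).
speed_oracle <- function(det, stations, vmax = 2) {
  n <- nrow(det)
  pos <- unique(stations[, c("receiver_id", "lat", "lon")])
  ri <- match(det$receiver_id, pos$receiver_id)
  tt <- as.numeric(det$timestamp)
  consistent <- function(keep) {
    ix <- which(keep)
    if (length(ix) < 2) return(TRUE)
    for (j in seq_len(length(ix) - 1)) {
      a <- ix[j]; b <- ix[j + 1]
      if (ri[a] == ri[b]) next
      d <- haversine_m(pos$lat[ri[a]], pos$lon[ri[a]],
                       pos$lat[ri[b]], pos$lon[ri[b]])
      if (d == 0) next   # co-located receivers imply no movement
      dt <- tt[b] - tt[a]
      if (dt <= 0 || d / dt > vmax) return(FALSE)
    }
    TRUE
  }
  best <- NULL
  for (m in (2^n - 1):0) {
    keep <- as.logical(bitwAnd(m, 2^(seq_len(n) - 1)))
    if (!consistent(keep)) next
    if (is.null(best) || lex_greater(keep, best)) best <- keep
  }
  best
}

lex_greater <- function(a, b) {
  d <- which(a != b)
  if (!length(d)) return(FALSE)
  a[d[1]]
}

# ---- residency-event oracle ----------------------------------------------
# Explicit state-machine replay, written independently of the package
# implementation: walks the sequence keeping a list of member indices.
event_oracle <- function(det, timeout_min = 60) {
  w <- timeout_min * 60
  out <- list()
  emit <- function(members) {
    if (length(members) >= 2) {
      out[[length(out) + 1L]] <<- data.frame(
        receiver_id = det$receiver_id[members[1]],
        start = det$timestamp[members[1]],
        end = det$timestamp[members[length(members)]],
        n_detections = length(members))
    }
  }
  members <- integer(0)
  for (i in seq_len(nrow(det))) {
    if (!length(members)) { members <- i; next }
    prev <- members[length(members)]
    same <- det$receiver_id[i] == det$receiver_id[prev]
    gap_ok <- as.numeric(det$timestamp[i]) - as.numeric(det$timestamp[prev]) <= w
    if (same && gap_ok) {
      members <- c(members, i)
    } else {
      emit(members)
      members <- i
    }
  }
  emit(members)
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# ---- dense HMM forward-backward oracle -----------------------------------
# Unscaled matrix-product computation of the smoothed marginals: forward
# messages via explicit matrix products, backward likewise, combined and
# normalized once per day at the end. Valid for short sequences (no
# underflow), independent of the package's scaled recursion.
fb_oracle <- function(L, K, prior) {
  T_ <- nrow(L); n <- ncol(L)
  alpha <- matrix(0, T_, n)
  alpha[1, ] <- prior * L[1, ]
  if (T_ > 1) for (t in 2:T_) {
    alpha[t, ] <- as.numeric(t(K) %*% alpha[t - 1, ]) * L[t, ]
  }
  beta <- matrix(1, T_, n)
  if (T_ > 1) for (t in (T_ - 1):1) {
    beta[t, ] <- as.numeric(K %*% (L[t + 1, ] * beta[t + 1, ]))
  }
  post <- alpha * beta
  post / rowSums(post)
}

# Entropy of a discrete distribution (nats).
entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Small seeded synthetic dataset reused by several files.
small_dataset <- function(seed = 42, n_animals = 4,
                          start = "2012-11-02", end = "2013-01-31") {
  cfg <- sim_config(n_animals = n_animals, study_start = as.Date(start),
                    study_end = as.Date(end), seed = seed)
  list(cfg = cfg, data = suppressMessages(simulate_dataset(cfg)))
}
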