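# Seeded synthetic telemetry generator. Emulates the statistical structure
# the analysis pipeline assumes -- a two-year coastal deployment of ~20
# acoustically tagged rays on a 15+2 receiver array, seasonal presence driven
# by chlorophyll-a and lunar phase, V16-style transmission delays of
# 310-410 s, a 540-m 50% detection range, and detection noise (spurious
# collision artefacts and isolated false detections) -- with full ground
# truth, so every downstream stage can be tested without real data.

#' Simulation configuration
#'
#' Defaults mirror the monitored study conditions: 20 tagged animals, a
#' 2012-11-02 to 2014-10-24 window, uniform 310-410 s transmission delays, a
#' logistic detection-range curve with 50% detection at 540 m (dropping to
#' 0.05 by twice that range), a 2 m/s hard speed cap on movement, and a
#' seasonal presence model peaking in boreal fall.
#'
#' @param n_animals number of tagged animals.
#' @param study_start,study_end study window (Dates).
#' @param array station table; default [dungonab_array()] over the window.
#' @param ping_delay_s uniform transmission-delay range in seconds.
#' @param detect_r50_m distance with 50% detection probability.
#' @param detect_p_max detection probability at zero range; sets the
#'   logistic slope so that p drops to `1 - detect_p_max` at `2 * r50`.
#' @param speed_cap_mps hard cap on simulated displacement speed.
#' @param step_minutes movement time step.
#' @param step_sd_m random-walk innovation scale per step (0 pins animals to
#'   their anchor station).
#' @param reversion mean-reversion rate per step towards the current target.
#' @param anchor_switch_prob daily probability of a within-day anchor-station
#'   switch (produces between-receiver movements).
#' @param presence coefficients of the daily presence model on the logit
#'   scale: `intercept`, `day_amp` (cyclic day-of-year amplitude),
#'   `day_peak_doy`, `chla_coef` (per mg/m3 anomaly), `moon_coef`.
#' @param presence_persistence day-to-day autocorrelation of the latent
#'   presence process (probit-threshold AR(1); the configured daily
#'   probability is preserved marginally). Produces the multi-week absence
#'   runs seen in long acoustic records; 0 gives independent days.
#' @param echo_rate probability a genuine detection spawns a spurious
#'   same-second collision artefact at a distant receiver.
#' @param false_single_rate expected isolated false detections per tag-day.
#' @param offshore_hold_km how far outside the bay absent animals hold.
#' @param seed integer seed; mandatory, all draws derive from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_animals = 20,
                       study_start = as.Date("2012-11-02"),
                       study_end = as.Date("2014-10-24"),
                       array = NULL,
                       ping_delay_s = c(310, 410),
                       detect_r50_m = 540,
                       detect_p_max = 0.95,
                       speed_cap_mps = 2.0,
                       step_minutes = 10,
                       step_sd_m = 60,
                       reversion = 0.1,
                       anchor_switch_prob = 0.4,
                       presence = list(intercept = -0.5, day_amp = 1.1,
                                       day_peak_doy = 288, chla_coef = 0.5,
                                       moon_coef = 0.4),
                       presence_persistence = 0.95,
                       echo_rate = 0.005,
                       false_single_rate = 0.05,
                       offshore_hold_km = 40,
                       seed = 1L) {
  stopifnot(length(ping_delay_s) == 2L, all(ping_delay_s > 0),
            diff(ping_delay_s) >= 0, speed_cap_mps > 0,
            detect_r50_m > 0, detect_p_max > 0.5, detect_p_max < 1,
            !is.null(seed))
  if (is.null(array)) {
    array <- dungonab_array(start = study_start - 5, end = study_end)
  }
  cfg <- list(n_animals = as.integer(n_animals),
              study_start = as.Date(study_start),
              study_end = as.Date(study_end),
              array = array,
              ping_delay_s = ping_delay_s,
              detect_r50_m = detect_r50_m,
              detect_p_max = detect_p_max,
              speed_cap_mps = speed_cap_mps,
              step_minutes = step_minutes,
              step_sd_m = step_sd_m,
              reversion = reversion,
              anchor_switch_prob = anchor_switch_prob,
              presence = presence,
              presence_persistence = presence_persistence,
              echo_rate = echo_rate,
              false_single_rate = false_single_rate,
              offshore_hold_km = offshore_hold_km,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Seasonal habitat preference: probability that an animal's daily anchor
# station falls in each array region. Fall concentrates animals in the
# central/channel array; winter shifts use north (where a single station
# sits) while retaining some central activity, dispersing the cohort and
# enlarging winter home ranges; spring shifts south; summer favours the
# channel mouth.
season_region_weights <- function(month) {
  if (month %in% c(12, 1, 2, 3)) {
    c(CH = 0.15, C = 0.20, W = 0.05, S = 0.05, N = 0.55)
  } else if (month %in% c(4, 5)) {
    c(CH = 0.20, C = 0.20, W = 0.10, S = 0.50, N = 0.00)
  } else if (month %in% c(6, 7, 8)) {
    c(CH = 0.50, C = 0.25, W = 0.15, S = 0.10, N = 0.00)
  } else {
    c(CH = 0.30, C = 0.50, W = 0.15, S = 0.05, N = 0.00)
  }
}

#' Synthetic tag deployments
#'
#' Animals tagged over the five days preceding the study window, alternating
#' sex, wingspans spread over 240-370 cm with maturity assigned by the
#' 3.2 m disc-width rule; the first three animals carry satellite tags.
#' @param config a [sim_config()].
#' @export
simulate_deployments <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_animals
  tag_days <- sort(rep_len(0:4, n))
  release <- as.POSIXct(config$study_start, tz = "UTC") -
    (5 - tag_days) * 86400 + 3600 * round(runif(n, 6, 14))
  wingspan <- round(runif(n, 240, 370))
  data.frame(
    animal_id = sprintf("M%d", seq_len(n)),
    tag_id = sprintf("A69-%04d", 1000L + seq_len(n)),
    release_time = release,
    sex = rep_len(c("F", "M"), n),
    wingspan_cm = wingspan,
    maturity = ifelse(wingspan >= 320, "mature", "immature"),
    satellite_tag = c("SPOT", "PSAT", "PSAT", rep("none", max(0, n - 3L)))[seq_len(n)],
    stringsAsFactors = FALSE)
}

#' Synthetic daily environmental series
#'
#' Lunar illuminated fraction follows a 29.53-day sinusoidal cycle in [0,1];
#' chlorophyll-a is a positive seasonal curve peaking in summer with
#' lognormal noise.
#' @param config a [sim_config()].
#' @return data.frame `date, chla, moon_frac`.
#' @export
simulate_environment <- function(config) {
  set.seed(config$seed + 2L)
  dates <- seq(config$study_start - 7, config$study_end, by = "day")
  # reference new moon: 2012-11-13
  phase <- 2 * pi * as.numeric(dates - as.Date("2012-11-13")) / 29.53
  moon <- (1 - cos(phase)) / 2
  doy <- as.integer(format(dates, "%j"))
  chla <- exp(log(0.9) + 0.9 * cos(2 * pi * (doy - 200) / 365) +
                rnorm(length(dates), 0, 0.15))
  data.frame(date = dates, chla = chla, moon_frac = moon)
}

# Daily presence probability on the logit scale for given dates/env rows.
presence_logit <- function(presence, dates, env) {
  i <- match(as.Date(dates), env$date)
  doy <- as.integer(format(as.Date(dates), "%j"))
  presence$intercept +
    presence$day_amp * cos(2 * pi * (doy - presence$day_peak_doy) / 365) +
    presence$chla_coef * (env$chla[i] - mean(env$chla)) +
    presence$moon_coef * (env$moon_frac[i] - 0.5)
}

#' Simulate animal movement with ground truth
#'
#' Discrete-time mean-reverting biased walk. Each present day an animal
#' anchors at a station drawn from the season's regional habitat weights
#' (dwelling behaviour at aggregation sites, with occasional within-day
#' anchor switches producing between-receiver movements); on absent days
#' its target switches to an offshore holding point. Daily presence is
#' drawn from the configured logit model. Per-step displacement is
#' hard-capped at `speed_cap_mps`.
#'
#' @param config a [sim_config()].
#' @param deployments as from [simulate_deployments()].
#' @param env as from [simulate_environment()].
#' @return list with `positions` (animal_id, time, lat, lon, present) at
#'   `step_minutes` resolution and `daily` truth (animal_id, date, present,
#'   p_present, anchor station).
#' @export
simulate_movement <- function(config, deployments = simulate_deployments(config),
                              env = simulate_environment(config)) {
  dt <- config$step_minutes * 60
  cap_m <- config$speed_cap_mps * dt
  days <- seq(config$study_start, config$study_end, by = "day")
  months <- as.integer(format(days, "%m"))
  steps_per_day <- as.integer(86400 / dt)
  n <- config$n_animals
  lat0 <- 20.83; lon0 <- 37.23
  pos <- station_positions(config$array)
  inbay <- pos[pos$region != "OFFSHORE", ]
  st_xy <- project_local(inbay$lat, inbay$lon, lat0, lon0)

  draw_anchor <- function(month) {
    w <- season_region_weights(month)
    reg <- sample(names(w), 1L, prob = w)
    cand <- which(inbay$region == reg)
    cand[sample.int(length(cand), 1L)]
  }

  # daily presence truth and per-step anchor schedule, per animal substream
  daily <- vector("list", n)
  anchor <- matrix(1L, length(days) * steps_per_day, n)
  rho <- config$presence_persistence %||% 0
  for (i in seq_len(n)) {
    set.seed(config$seed + 100L + i)
    lp <- presence_logit(config$presence, days, env)
    # probit-threshold AR(1): marginal daily probability is exactly
    # plogis(lp); rho controls run lengths of presence/absence
    z <- rnorm(length(days))
    if (rho > 0) {
      for (d in 2:length(days)) {
        z[d] <- rho * z[d - 1L] + sqrt(1 - rho^2) * z[d]
      }
    }
    present <- z < qnorm(plogis(lp))
    base <- vapply(months, draw_anchor, integer(1))
    for (d in seq_along(days)) {
      rows <- (d - 1L) * steps_per_day + seq_len(steps_per_day)
      anchor[rows, i] <- base[d]
      if (runif(1) < config$anchor_switch_prob) {
        sw <- sample.int(steps_per_day, 1L)
        anchor[rows[rows >= rows[sw]], i] <- draw_anchor(months[d])
      }
    }
    daily[[i]] <- data.frame(animal_id = deployments$animal_id[i],
                             date = days, p_present = plogis(lp),
                             present = present,
                             anchor = inbay$receiver_id[base],
                             stringsAsFactors = FALSE)
  }
  daily <- do.call(rbind, daily)

  # winter cohort disperses (larger step noise) relative to the tight fall
  # aggregation; drives the seasonal kernel-area contrast
  spread <- ifelse(months %in% c(12, 1, 2, 3), 1.5, 1.0)
  hold_xy <- project_local(20.83, 37.23 + config$offshore_hold_km / 103.9,
                           lat0, lon0)

  times <- as.POSIXct(config$study_start, tz = "UTC") +
    seq(0, length(days) * 86400 - dt, by = dt)
  n_steps <- length(times)
  X <- matrix(0, n_steps, n); Y <- matrix(0, n_steps, n)
  set.seed(config$seed + 99L)
  # start at the first day's anchor with individual scatter
  x <- st_xy[anchor[1, ], 1] + rnorm(n, 0, 300)
  y <- st_xy[anchor[1, ], 2] + rnorm(n, 0, 300)
  pres_mat <- matrix(daily$present, nrow = length(days))
  day_idx <- rep(seq_along(days), each = steps_per_day)
  for (s in seq_len(n_steps)) {
    d <- day_idx[s]
    on <- pres_mat[d, ]
    tx <- ifelse(on, st_xy[anchor[s, ], 1], hold_xy[1, 1])
    ty <- ifelse(on, st_xy[anchor[s, ], 2], hold_xy[1, 2])
    sdm <- config$step_sd_m * spread[d]
    dx <- config$reversion * (tx - x) + rnorm(n, 0, sdm)
    dy <- config$reversion * (ty - y) + rnorm(n, 0, sdm)
    # cap applied with a small margin so the bound also holds for the
    # great-circle step length after unprojection
    sc <- pmin(1, 0.999 * cap_m / pmax(sqrt(dx^2 + dy^2), 1e-12))
    x <- x + dx * sc
    y <- y + dy * sc
    X[s, ] <- x; Y[s, ] <- y
  }
  ll <- unproject_local(as.numeric(X), as.numeric(Y), lat0, lon0)
  positions <- data.frame(
    animal_id = rep(deployments$animal_id, each = n_steps),
    time = rep(times, n),
    lat = ll[, "lat"], lon = ll[, "lon"],
    present = as.vector(pres_mat[day_idx, , drop = FALSE]),
    stringsAsFactors = FALSE)
  list(positions = positions, daily = daily,
       origin = c(lat = lat0, lon = lon0))
}

detect_prob <- function(dist_m, r50, p_max) {
  s <- r50 / log(p_max / (1 - p_max))
  plogis(-(dist_m - r50) / s)
}

#' Simulate acoustic detections with truth labels
#'
#' Transmissions per tag at i.i.d. uniform delays; each transmission is
#' heard by each active receiver independently with logistic probability in
#' distance (50% at `detect_r50_m`). Noise: collision artefacts duplicate a
#' genuine detection at a distant receiver within seconds (caught by the
#' speed filter) and isolated false detections appear at low rate on quiet
#' days (caught by the isolated-single filter).
#'
#' @param movement output of [simulate_movement()].
#' @param config a [sim_config()].
#' @param deployments matching deployment table.
#' @return list `detections` (tag_id, receiver_id, timestamp, valid) sorted
#'   canonically and `labels` (parallel truth label per detection:
#'   genuine/echo/false_single).
#' @export
simulate_detections <- function(movement, config,
                                deployments = simulate_deployments(config)) {
  st <- station_positions(config$array)
  arr <- config$array
  if (nrow(arr) == 0L) stop("no active receivers", call. = FALSE)
  dt <- config$step_minutes * 60
  t0 <- min(movement$positions$time)
  n_steps <- length(unique(movement$positions$time))
  end_s <- as.numeric(max(movement$positions$time)) + dt - as.numeric(t0)

  out <- vector("list", config$n_animals)
  for (i in seq_len(config$n_animals)) {
    set.seed(config$seed + 500L + i)
    aid <- deployments$animal_id[i]
    tag <- deployments$tag_id[i]
    pos <- movement$positions[movement$positions$animal_id == aid, ]
    rel_s <- max(0, as.numeric(deployments$release_time[i]) - as.numeric(t0))
    # transmission schedule
    n_guess <- ceiling((end_s - rel_s) / config$ping_delay_s[1]) + 10L
    gaps <- runif(n_guess, config$ping_delay_s[1], config$ping_delay_s[2])
    tx_s <- rel_s + cumsum(gaps)
    tx_s <- tx_s[tx_s < end_s]
    step_i <- pmin(floor(tx_s / dt) + 1L, n_steps)
    plat <- pos$lat[step_i]; plon <- pos$lon[step_i]
    # candidate transmissions: within 3 km of some receiver (coarse box cut)
    near <- rep(FALSE, length(tx_s))
    for (r in seq_len(nrow(st))) {
      near <- near | (abs(plat - st$lat[r]) < 0.03 &
                        abs(plon - st$lon[r]) < 0.03)
    }
    keep <- which(near)
    if (!length(keep)) { out[[i]] <- NULL; next }
    det <- vector("list", nrow(st))
    for (r in seq_len(nrow(st))) {
      dists <- haversine_m(plat[keep], plon[keep], st$lat[r], st$lon[r])
      p <- detect_prob(dists, config$detect_r50_m, config$detect_p_max)
      heard <- keep[runif(length(keep)) < p]
      if (!length(heard)) next
      ts <- t0 + round(tx_s[heard])
      act <- arr[arr$receiver_id == st$receiver_id[r], ]
      ok <- rep(FALSE, length(ts))
      for (j in seq_len(nrow(act))) {
        ok <- ok | (ts >= act$active_start[j] & ts <= act$active_end[j])
      }
      if (!any(ok)) next
      det[[r]] <- data.frame(tag_id = tag, receiver_id = st$receiver_id[r],
                             timestamp = ts[ok], label = "genuine",
                             stringsAsFactors = FALSE)
    }
    det <- do.call(rbind, det)
    if (is.null(det) || nrow(det) == 0L) { out[[i]] <- NULL; next }

    # collision artefacts: duplicate at a receiver >= 5 km away, seconds later
    n_echo <- rbinom(1L, nrow(det), config$echo_rate)
    if (n_echo > 0L) {
      src <- sample.int(nrow(det), n_echo)
      echo <- det[src, ]
      for (k in seq_len(n_echo)) {
        r0 <- match(echo$receiver_id[k], st$receiver_id)
        far <- which(haversine_m(st$lat[r0], st$lon[r0], st$lat, st$lon) > 5000 &
                       st$region != "OFFSHORE")
        if (!length(far)) next
        echo$receiver_id[k] <- st$receiver_id[sample(far, 1L)]
        echo$timestamp[k] <- echo$timestamp[k] + sample(1:5, 1L)
        echo$label[k] <- "echo"
      }
      det <- rbind(det, echo[echo$label == "echo", ])
    }

    # isolated false detections on quiet days
    tr <- movement$daily[movement$daily$animal_id == aid, ]
    quiet <- tr$date[!tr$present]
    n_false <- rbinom(1L, length(quiet), min(1, config$false_single_rate))
    if (n_false > 0L && length(quiet)) {
      fdays <- sample(quiet, n_false)
      fts <- as.POSIXct(fdays, tz = "UTC") + round(runif(n_false, 0, 86399))
      inbay <- which(st$region != "OFFSHORE")
      frec <- st$receiver_id[sample(inbay, n_false, replace = TRUE)]
      iso <- vapply(fts, function(tt) {
        min(abs(as.numeric(det$timestamp) - as.numeric(tt))) > 65 * 60
      }, logical(1))
      if (any(iso)) {
        det <- rbind(det, data.frame(tag_id = tag, receiver_id = frec[iso],
                                     timestamp = fts[iso],
                                     label = "false_single",
                                     stringsAsFactors = FALSE))
      }
    }
    out[[i]] <- det
  }
  det <- do.call(rbind, out)
  if (is.null(det)) {
    det <- data.frame(tag_id = character(), receiver_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      label = character(), stringsAsFactors = FALSE)
  }
  o <- order(det$tag_id, det$timestamp, det$receiver_id, method = "radix")
  det <- det[o, , drop = FALSE]
  rownames(det) <- NULL
  detections <- det[, c("tag_id", "receiver_id", "timestamp")]
  detections$valid <- TRUE
  list(detections = detections, labels = det$label)
}

#' Simulate daily geosensor series for the geolocation model
#'
#' Daily light-based longitude estimates (true longitude plus Gaussian
#' error) and tag-recorded SST (a smooth meridional SST field evaluated at
#' the true position plus Gaussian error). Latitude information enters only
#' through SST, as in equinox-adjacent light geolocation.
#'
#' @param movement output of [simulate_movement()] (noon positions used).
#' @param animal_id which animal's track to sense.
#' @param config a [sim_config()].
#' @param sigma_lon longitude error SD, degrees.
#' @param sigma_sst SST error SD, degrees C.
#' @return data.frame `date, lon_est, sst_tag, true_lat, true_lon`.
#' @export
simulate_geosensor <- function(movement, animal_id, config,
                               sigma_lon = 1.0, sigma_sst = 0.5) {
  set.seed(config$seed + 7000L)
  pos <- movement$positions[movement$positions$animal_id == animal_id, ]
  dts <- to_calendar_day(pos$time, 0)
  idx <- tapply(seq_len(nrow(pos)), dts, function(ix) {
    ix[which.min(abs(as.numeric(pos$time[ix]) %% 86400 - 43200))]
  })
  dates <- as.Date(names(idx))
  idx <- as.integer(idx)
  truth_lat <- pos$lat[idx]; truth_lon <- pos$lon[idx]
  data.frame(date = dates,
             lon_est = truth_lon + rnorm(length(idx), 0, sigma_lon),
             sst_tag = sst_field(truth_lat, dates) +
               rnorm(length(idx), 0, sigma_sst),
             true_lat = truth_lat, true_lon = truth_lon)
}

#' Smooth meridional sea-surface-temperature field
#'
#' SST (deg C) as a function of latitude and date: a linear north-south
#' gradient (cooler north) with a mild seasonal cycle. Supplies the latitude
#' information for the geolocation likelihood.
#' @param lat latitude(s), degrees.
#' @param date date(s).
#' @export
sst_field <- function(lat, date) {
  doy <- as.integer(format(as.Date(date), "%j"))
  31 - 0.55 * (lat - 18) + 1.5 * cos(2 * pi * (doy - 228) / 365)
}

#' Generate a complete synthetic dataset
#'
#' Runs deployments, environment, movement, and detections from one seed;
#' returns every table the pipeline consumes plus ground truth.
#' @param config a [sim_config()].
#' @return list: detections, labels, stations, deployments, environment,
#'   truth (positions + daily presence).
#' @export
simulate_dataset <- function(config) {
  dep <- simulate_deployments(config)
  env <- simulate_environment(config)
  mov <- simulate_movement(config, dep, env)
  det <- simulate_detections(mov, config, dep)
  list(detections = det$detections, labels = det$labels,
       stations = config$array, deployments = dep, environment = env,
       truth = mov)
}

#' Simulate an hourly presence table from a known logit model
#'
#' Direct generator for presence-model validation: builds animal-hour rows
#' with covariates (cyclic day-of-year and hour-of-day effects, moon,
#' chlorophyll-a, active-station count, sex, maturity, per-animal random
#' intercept) and draws the binomial response from the specified truth.
#'
#' @param n_animals,n_days cohort size and window length.
#' @param coefs list of truth coefficients: `intercept`, `day_amp`,
#'   `day_peak_doy`, `hour_amp`, `hour_peak`, `moon_coef`, `chla_coef`,
#'   `ns_coef`, `re_sd`.
#' @param start first date.
#' @param seed integer seed.
#' @return list: `table` (HourlyObservation rows), `truth` (day/hour effect
#'   functions and the drawn random intercepts).
#' @export
simulate_hourly_presence <- function(n_animals = 12, n_days = 180,
                                     coefs = list(intercept = -0.6,
                                                  day_amp = 1.2,
                                                  day_peak_doy = 288,
                                                  hour_amp = 0.5,
                                                  hour_peak = 8,
                                                  moon_coef = 0.4,
                                                  chla_coef = 0.5,
                                                  ns_coef = 0.08,
                                                  re_sd = 0.4),
                                     start = as.Date("2012-11-02"),
                                     seed = 1L) {
  set.seed(seed)
  dates <- seq(start, by = "day", length.out = n_days)
  cfg <- sim_config(seed = seed, study_start = dates[1],
                    study_end = dates[n_days])
  env <- simulate_environment(cfg)
  ei <- match(dates, env$date)
  doy <- as.integer(format(dates, "%j"))
  # receiver effort: full array early, a few failures in the final quarter
  ns_daily <- rep(15L, n_days)
  if (n_days >= 40) {
    ns_daily[seq(floor(0.75 * n_days), n_days)] <- 13L
    ns_daily[seq(floor(0.9 * n_days), n_days)] <- 12L
  }
  f_day <- function(d) coefs$day_amp * cos(2 * pi * (d - coefs$day_peak_doy) / 365)
  f_hour <- function(h) coefs$hour_amp * cos(2 * pi * (h - coefs$hour_peak) / 24)
  re <- rnorm(n_animals, 0, coefs$re_sd)
  sex <- rep_len(c("F", "M"), n_animals)
  maturity <- rep_len(c("mature", "mature", "immature"), n_animals)
  grid <- expand.grid(hour = 0:23, day = seq_len(n_days),
                      animal = seq_len(n_animals))
  chla_c <- env$chla[ei] - mean(env$chla[ei])
  moon_c <- env$moon_frac[ei] - 0.5
  ns_c <- ns_daily - mean(ns_daily)
  eta <- coefs$intercept + f_day(doy[grid$day]) + f_hour(grid$hour) +
    coefs$moon_coef * moon_c[grid$day] + coefs$chla_coef * chla_c[grid$day] +
    coefs$ns_coef * ns_c[grid$day] + re[grid$animal]
  y <- rbinom(nrow(grid), 1L, plogis(eta))
  table <- data.frame(
    animal_id = sprintf("M%d", grid$animal),
    hour_start = as.POSIXct(dates[grid$day], tz = "UTC") + 3600 * grid$hour,
    y = y,
    day_of_year = doy[grid$day],
    hour = grid$hour,
    moon_frac = env$moon_frac[ei][grid$day],
    chla = env$chla[ei][grid$day],
    n_stations = ns_daily[grid$day],
    sex = sex[grid$animal],
    maturity = maturity[grid$animal],
    stringsAsFactors = FALSE)
  list(table = table,
       truth = list(f_day = f_day, f_hour = f_hour, re = re, coefs = coefs))
}

#' Write a synthetic dataset to a directory of CSV files
#'
#' Emits the canonical file schemas consumed by the pipeline readers plus
#' the ground-truth tables.
#' @param data list from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_detections(data$detections, file.path(dir, "detections.csv"))
  st <- data$stations
  st$active_start <- format(st$active_start, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  st$active_end <- format(st$active_end, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(st, file.path(dir, "receivers.csv"), row.names = FALSE, quote = FALSE)
  dep <- data$deployments
  dep$release_time <- format(dep$release_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(dep, file.path(dir, "deployments.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data$environment, file.path(dir, "environment.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(data.frame(label = data$labels),
            file.path(dir, "truth_labels.csv"), row.names = FALSE, quote = FALSE)
  daily <- data$truth$daily
  write.csv(daily, file.path(dir, "truth_daily.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
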