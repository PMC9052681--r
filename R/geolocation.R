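# Gridded hidden Markov model geolocation. States are water cells of a
# regular lat/lon grid (default 0.25 degrees); daily transitions follow a
# Gaussian diffusion kernel hard-truncated at the a-priori speed bound
# (2 m/s -> 172.8 km/day); observations are a light-based longitude
# estimate and tag SST matched against a smooth SST field, both Gaussian,
# masked by bathymetry. Days with an acoustic centre of activity are
# treated as fixed: the filtered distribution is clamped to that cell and
# the constraint propagates through smoothing.

#' Build a geolocation grid
#'
#' @param lat_range,lon_range extents in degrees.
#' @param cell cell size in degrees (default 0.25).
#' @param water logical matrix (nlat x nlon) marking water cells, or `NULL`
#'   for all-water.
#' @return `geo_grid` list with cell centres, water mask, and per-state
#'   lookup tables (states are water cells only).
#' @export
geo_grid <- function(lat_range = c(18, 23), lon_range = c(36.5, 39.5),
                     cell = 0.25, water = NULL) {
  lat <- seq(lat_range[1] + cell / 2, lat_range[2] - cell / 2, by = cell)
  lon <- seq(lon_range[1] + cell / 2, lon_range[2] - cell / 2, by = cell)
  if (is.null(water)) water <- matrix(TRUE, length(lat), length(lon))
  stopifnot(nrow(water) == length(lat), ncol(water) == length(lon))
  if (sum(water) < 2L) stop("need at least 2 water cells", call. = FALSE)
  idx <- which(water, arr.ind = TRUE)
  structure(list(lat = lat, lon = lon, cell = cell, water = water,
                 state_lat = lat[idx[, 1]], state_lon = lon[idx[, 2]],
                 state_idx = idx, n_states = nrow(idx)),
            class = "geo_grid")
}

#' Synthetic Red Sea grid with a western coastline mask
#'
#' A stand-in bathymetry mask for testing: cells west of the (synthetic)
#' coastline longitude are land, everything else water.
#'
#' @param coast_lon land/water boundary longitude.
#' @param ... passed to [geo_grid()].
#' @export
synthetic_red_sea_grid <- function(coast_lon = 37.0, ...) {
  g <- geo_grid(...)
  water <- outer(g$lat, g$lon, function(la, lo) lo >= coast_lon)
  geo_grid(lat_range = range(g$lat) + c(-1, 1) * g$cell / 2,
           lon_range = range(g$lon) + c(-1, 1) * g$cell / 2,
           cell = g$cell, water = water)
}

#' Find the state (water cell) containing a position
#' @param grid a `geo_grid`.
#' @param lat,lon position, degrees.
#' @export
nearest_state <- function(grid, lat, lon) {
  d2 <- (grid$state_lat - lat)^2 +
    ((grid$state_lon - lon) * cospi(lat / 180))^2
  which.min(d2)
}

#' Daily movement kernel
#'
#' Row-stochastic transition matrix over water cells: Gaussian diffusion in
#' great-circle distance, hard-truncated at `speed_mps * 86400 * dt_days`
#' metres (172.8 km for 2 m/s and one day). The diffusion scale is set so
#' that 99% of unconstrained daily mass lies within the speed bound.
#'
#' @param grid a `geo_grid`.
#' @param speed_mps a-priori speed (default 2 m/s).
#' @param dt_days time step in days.
#' @return list: `K` (row-stochastic matrix), `support` (logical reach
#'   matrix), `max_km`, `sigma_km`.
#' @export
build_movement_kernel <- function(grid, speed_mps = 2.0, dt_days = 1) {
  if (speed_mps <= 0) stop("speed must be positive", call. = FALSE)
  max_km <- speed_mps * 86400 * dt_days / 1000
  sigma_km <- max_km / sqrt(2 * log(100))   # 99% of mass within the bound
  n <- grid$n_states
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    D[i, ] <- haversine_m(grid$state_lat[i], grid$state_lon[i],
                          grid$state_lat, grid$state_lon) / 1000
  }
  K <- exp(-D^2 / (2 * sigma_km^2))
  K[D > max_km] <- 0
  K <- K / rowSums(K)
  list(K = K, support = D <= max_km, max_km = max_km, sigma_km = sigma_km,
       dist_km = D)
}

#' Daily observation likelihood over the grid
#'
#' Product of a Gaussian likelihood for the light-based longitude estimate,
#' a Gaussian SST-match likelihood against the day's field, and the water
#' mask. A missing sensor contributes no information (uniform); a fixed
#' acoustic cell yields a delta.
#'
#' @param grid a `geo_grid`.
#' @param lon_est,sigma_lon light-based longitude and its SD (degrees); NA
#'   for missing.
#' @param sst_tag,sigma_sst tag SST and its SD (deg C); NA for missing.
#' @param date date (for the SST field).
#' @param sst_fun field function `f(lat, date)` (default [sst_field()]).
#' @param fixed_state optional state index of an acoustically fixed cell.
#' @return likelihood vector over states (unnormalized, max 1).
#' @export
daily_likelihood <- function(grid, lon_est = NA, sigma_lon = 1.0,
                             sst_tag = NA, sigma_sst = 0.5, date = NULL,
                             sst_fun = sst_field, fixed_state = NULL) {
  if (!is.null(fixed_state)) {
    L <- rep(0, grid$n_states); L[fixed_state] <- 1
    return(L)
  }
  L <- rep(1, grid$n_states)
  if (!is.na(lon_est)) {
    L <- L * dnorm(grid$state_lon, lon_est, sigma_lon)
  }
  if (!is.na(sst_tag)) {
    L <- L * dnorm(sst_tag, sst_fun(grid$state_lat, date), sigma_sst)
  }
  if (max(L) <= 0 || !any(is.finite(L))) {
    stop("observation inconsistent with all water cells on ",
         format(date %||% NA), call. = FALSE)
  }
  L / max(L)
}

#' Forward-backward smoothing over the grid
#'
#' Standard scaled HMM filtering and backward smoothing. Days listed in
#' `fixed` clamp the filtered distribution to a delta at the given state.
#'
#' @param likelihoods T x n matrix of per-day state likelihoods.
#' @param kernel movement kernel from [build_movement_kernel()].
#' @param prior initial distribution over states (day 1, before the first
#'   observation update).
#' @param fixed optional integer vector (length T, NA = free) of clamped
#'   states.
#' @return list: `posterior` (T x n, rows sum to 1), `filtered`,
#'   `log_evidence`.
#' @export
forward_backward <- function(likelihoods, kernel, prior, fixed = NULL) {
  K <- kernel$K
  T_ <- nrow(likelihoods); n <- ncol(likelihoods)
  stopifnot(length(prior) == n)
  if (is.null(fixed)) fixed <- rep(NA_integer_, T_)
  alpha <- matrix(0, T_, n)
  logev <- 0
  pred <- prior
  for (t in seq_len(T_)) {
    if (t > 1L) pred <- as.numeric(crossprod(K, alpha[t - 1L, ]))
    a <- pred * likelihoods[t, ]
    s <- sum(a)
    if (s <= 0) stop("filtering failed (zero mass) at step ", t, call. = FALSE)
    logev <- logev + log(s)
    a <- a / s
    if (!is.na(fixed[t])) {
      a <- rep(0, n); a[fixed[t]] <- 1
    }
    alpha[t, ] <- a
  }
  beta <- matrix(0, T_, n)
  beta[T_, ] <- 1
  if (T_ > 1L) {
    for (t in (T_ - 1L):1L) {
      b <- as.numeric(K %*% (likelihoods[t + 1L, ] * beta[t + 1L, ]))
      if (!is.na(fixed[t + 1L])) {
        # the clamped day transmits information only through its fixed cell
        b <- as.numeric(K[, fixed[t + 1L]] * beta[t + 1L, fixed[t + 1L]] *
                          likelihoods[t + 1L, fixed[t + 1L]])
      }
      s <- sum(b)
      if (s <= 0) stop("smoothing failed (zero mass) at step ", t,
                       call. = FALSE)
      beta[t, ] <- b / s
    }
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  list(posterior = post, filtered = alpha, log_evidence = logev)
}

#' Most probable track and per-day uncertainty
#'
#' Joint Viterbi path over the grid (steps restricted to the kernel
#' support) plus, per day, the posterior mode and the area of the 95%
#' highest-posterior-density cell set.
#'
#' @param posteriors T x n smoothed posterior matrix.
#' @param likelihoods T x n likelihood matrix (for the Viterbi pass).
#' @param kernel movement kernel.
#' @param grid the `geo_grid`.
#' @param prior initial distribution.
#' @return data.frame: day index, Viterbi lat/lon, posterior-mode lat/lon,
#'   `hpd95_km2`.
#' @export
most_probable_track <- function(posteriors, likelihoods, kernel, grid,
                                prior) {
  T_ <- nrow(likelihoods); n <- ncol(likelihoods)
  logK <- log(kernel$K); logK[kernel$K == 0] <- -Inf
  d <- matrix(-Inf, T_, n); ptr <- matrix(NA_integer_, T_, n)
  d[1, ] <- log(prior) + log(likelihoods[1, ])
  for (t in 2:T_) {
    for (j in seq_len(n)) {
      v <- d[t - 1L, ] + logK[, j]
      b <- which.max(v)
      d[t, j] <- v[b] + log(likelihoods[t, j])
      ptr[t, j] <- b
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(d[T_, ])
  for (t in (T_ - 1L):1L) path[t] <- ptr[t + 1L, path[t + 1L]]
  cell_km2 <- (111.195 * grid$cell)^2 * cospi(grid$state_lat / 180)
  mode_i <- apply(posteriors, 1L, which.max)
  hpd <- vapply(seq_len(T_), function(t) {
    o <- order(posteriors[t, ], decreasing = TRUE)
    m <- which(cumsum(posteriors[t, o]) >= 0.95)[1]
    sum(cell_km2[o[seq_len(m)]])
  }, numeric(1))
  data.frame(day = seq_len(T_),
             lat = grid$state_lat[path], lon = grid$state_lon[path],
             mode_lat = grid$state_lat[mode_i],
             mode_lon = grid$state_lon[mode_i],
             hpd95_km2 = hpd)
}

#' Run the geolocation HMM on a daily geosensor series
#'
#' Convenience wrapper: builds likelihoods from `date, lon_est, sst_tag`
#' rows, clamps days with acoustic COA fixes, runs forward-backward and the
#' track decoder.
#'
#' @param geosensor data.frame `date, lon_est, sst_tag` (NAs allowed).
#' @param grid a `geo_grid`.
#' @param start c(lat, lon) tagging position (day-1 prior is a delta
#'   there).
#' @param coas optional 12-h COA table for the same animal; days with a COA
#'   become fixed cells.
#' @param speed_mps,sigma_lon,sigma_sst,sst_fun model parameters.
#' @return list: `track` (with dates), `posterior`, `grid`, `kernel`,
#'   `log_evidence`, `fixed_days`.
#' @export
geolocate <- function(geosensor, grid, start, coas = NULL,
                      speed_mps = 2.0, sigma_lon = 1.0, sigma_sst = 0.5,
                      sst_fun = sst_field) {
  kernel <- build_movement_kernel(grid, speed_mps)
  T_ <- nrow(geosensor)
  fixed <- rep(NA_integer_, T_)
  if (!is.null(coas) && nrow(coas)) {
    cday <- to_calendar_day(coas$bin_start, 0)
    agg <- aggregate(cbind(lat, lon) ~ cday, data =
                       data.frame(cday = cday, lat = coas$lat,
                                  lon = coas$lon), FUN = mean)
    i <- match(geosensor$date, agg$cday)
    for (t in which(!is.na(i))) {
      fixed[t] <- nearest_state(grid, agg$lat[i[t]], agg$lon[i[t]])
    }
  }
  L <- matrix(0, T_, grid$n_states)
  for (t in seq_len(T_)) {
    L[t, ] <- daily_likelihood(grid,
                               lon_est = geosensor$lon_est[t],
                               sigma_lon = sigma_lon,
                               sst_tag = geosensor$sst_tag[t],
                               sigma_sst = sigma_sst,
                               date = geosensor$date[t], sst_fun = sst_fun,
                               fixed_state = if (!is.na(fixed[t]))
                                 fixed[t] else NULL)
  }
  prior <- rep(0, grid$n_states)
  start_state <- if (!is.na(fixed[1])) fixed[1] else
    nearest_state(grid, start[1], start[2])
  prior[start_state] <- 1
  fb <- forward_backward(L, kernel, prior, fixed = fixed)
  track <- most_probable_track(fb$posterior, L, kernel, grid, prior)
  track$date <- geosensor$date
  list(track = track, posterior = fb$posterior, grid = grid,
       kernel = kernel, log_evidence = fb$log_evidence,
       fixed_days = which(!is.na(fixed)))
}
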