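test_that("movement kernel is row-stochastic with hard speed truncation", {
  g <- geo_grid(lat_range = c(19, 22), lon_range = c(36.5, 38.5), cell = 0.25)
  kern <- build_movement_kernel(g, speed_mps = 2)
  expect_equal(unname(rowSums(kern$K)), rep(1, g$n_states), tolerance = 1e-12)
  expect_equal(kern$max_km, 172.8)
  expect_true(all(kern$K[kern$dist_km > 172.8] == 0))
  # vanishing speed leaves the identity operator
  k0 <- build_movement_kernel(g, speed_mps = 1e-9)
  expect_equal(k0$K, diag(g$n_states), tolerance = 1e-12)
  expect_error(build_movement_kernel(g, speed_mps = 0), "positive")
})

test_that("masked cells never receive likelihood or posterior mass", {
  g <- synthetic_red_sea_grid(coast_lon = 37.25, lat_range = c(19, 22),
                              lon_range = c(36.5, 38.5), cell = 0.25)
  expect_true(all(g$state_lon >= 37.25))
  L <- daily_likelihood(g, lon_est = 38, sst_tag = 29.5,
                        date = as.Date("2013-01-15"))
  expect_equal(length(L), g$n_states)
  kern <- build_movement_kernel(g)
  prior <- rep(1 / g$n_states, g$n_states)
  fb <- forward_backward(rbind(L, L, L), kern, prior)
  expect_equal(unname(rowSums(fb$posterior)), rep(1, 3), tolerance = 1e-10)
})

test_that("daily likelihood handles missing sensors, fixes and conflicts", {
  g <- geo_grid(lat_range = c(19, 22), lon_range = c(36.5, 38.5), cell = 0.25)
  # no sensors: uniform over water
  L <- daily_likelihood(g)
  expect_equal(L, rep(1, g$n_states))
  # fixed acoustic day: delta at the fixed cell
  f <- nearest_state(g, 20.85, 37.25)
  Lf <- daily_likelihood(g, lon_est = 38, fixed_state = f)
  expect_equal(which(Lf > 0), f)
  # zero-noise sensors peak at the true cell
  true_lat <- 20.62; true_lon <- 37.88
  s <- nearest_state(g, true_lat, true_lon)
  Lz <- daily_likelihood(g, lon_est = g$state_lon[s], sigma_lon = 0.05,
                         sst_tag = sst_field(g$state_lat[s],
                                             as.Date("2013-03-01")),
                         sigma_sst = 0.05, date = as.Date("2013-03-01"))
  expect_equal(which.max(Lz), s)
  # inconsistent observation: informative error
  expect_error(daily_likelihood(g, lon_est = 120, sigma_lon = 0.01,
                                date = as.Date("2013-03-01")),
               "inconsistent")
})

test_that("forward-backward matches the dense oracle on a 15x15 grid", {
  g <- geo_grid(lat_range = c(19, 22.75), lon_range = c(36.5, 40.25),
                cell = 0.25)
  expect_equal(g$n_states, 225)
  kern <- build_movement_kernel(g)
  set.seed(71)
  T_ <- 8
  L <- matrix(runif(T_ * g$n_states, 0.01, 1), T_, g$n_states)
  prior <- rep(0, g$n_states); prior[nearest_state(g, 20.8, 37.2)] <- 1
  fb <- forward_backward(L, kern, prior)
  orc <- fb_oracle(L, kern$K, prior)
  expect_lt(max(abs(fb$posterior - orc)), 1e-8)
  expect_equal(unname(rowSums(fb$posterior)), rep(1, T_), tolerance = 1e-10)
})

test_that("uniform likelihoods diffuse the prior; deltas pin the posterior", {
  g <- geo_grid(lat_range = c(19, 21), lon_range = c(36.5, 38.5), cell = 0.25)
  kern <- build_movement_kernel(g)
  n <- g$n_states
  prior <- rep(0, n); prior[nearest_state(g, 20, 37.5)] <- 1
  # all-uniform: smoothed posterior equals the prior diffused by the kernel
  L <- matrix(1, 5, n)
  fb <- forward_backward(L, kern, prior)
  p <- prior
  for (t in 1:5) {
    expect_equal(fb$posterior[t, ], p, tolerance = 1e-12)
    ent_t <- entropy(fb$posterior[t, ])
    if (t > 1) expect_gte(ent_t, entropy(fb$posterior[t - 1, ]) - 1e-10)
    p <- as.numeric(crossprod(kern$K, p))
  }
  # delta likelihood every day: posterior equals those deltas
  cells <- c(10, 12, 15, 15, 18)
  Ld <- matrix(0, 5, n)
  for (t in 1:5) Ld[t, cells[t]] <- 1
  fbd <- forward_backward(Ld, kern, rep(1 / n, n))
  for (t in 1:5) expect_equal(which(fbd$posterior[t, ] > 1e-12), cells[t])
})

test_that("time reversal symmetry holds for a doubly stochastic kernel", {
  # circulant kernel on a ring: symmetric, doubly stochastic, so the
  # reversed problem has the same transition matrix
  n <- 30
  base <- dnorm(0:(n - 1), 0, 2) + dnorm(n:1, 0, 2)
  K <- matrix(0, n, n)
  for (i in 1:n) K[i, ] <- base[((seq_len(n) - i) %% n) + 1]
  K <- K / rowSums(K)
  set.seed(72)
  T_ <- 6
  L <- matrix(runif(T_ * n, 0.05, 1), T_, n)
  prior <- rep(1 / n, n)
  fwd <- forward_backward(L, list(K = K), prior)
  rev_ <- forward_backward(L[T_:1, ], list(K = K), prior)
  expect_equal(fwd$posterior, rev_$posterior[T_:1, ], tolerance = 1e-10)
})

test_that("fixed acoustic days clamp the filtered state and sharpen neighbours", {
  g <- geo_grid(lat_range = c(19, 21), lon_range = c(36.5, 38.5), cell = 0.25)
  kern <- build_movement_kernel(g)
  n <- g$n_states
  set.seed(73)
  L <- matrix(1, 7, n)   # uninformative sensors
  prior <- rep(1 / n, n)
  free <- forward_backward(L, kern, prior)
  fixed <- rep(NA_integer_, 7); fixed[4] <- nearest_state(g, 20, 37.5)
  clamped <- forward_backward(L, kern, prior, fixed = fixed)
  expect_equal(which(clamped$posterior[4, ] > 0), fixed[4])
  # the acoustic fix never increases entropy on adjacent days
  for (t in c(3, 5)) {
    expect_lte(entropy(clamped$posterior[t, ]),
               entropy(free$posterior[t, ]) + 1e-10)
  }
})

test_that("most probable track respects the speed bound and single-cell days", {
  g <- geo_grid(lat_range = c(19, 21.5), lon_range = c(36.5, 38.5),
                cell = 0.25)
  kern <- build_movement_kernel(g)
  n <- g$n_states
  cells <- c(5, 5, 20, 20, 25)
  # consecutive target cells must be mutually reachable within a day
  for (t in 2:5) expect_lte(kern$dist_km[cells[t - 1], cells[t]], 172.8)
  L <- matrix(0, 5, n)
  for (t in 1:5) L[t, cells[t]] <- 1
  prior <- rep(1 / n, n)
  fb <- forward_backward(L, kern, prior)
  tr <- most_probable_track(fb$posterior, L, kern, g, prior)
  expect_equal(nearest_state(g, tr$lat[1], tr$lon[1]), cells[1])
  expect_equal(nearest_state(g, tr$lat[5], tr$lon[5]), cells[5])
  step <- haversine_m(head(tr$lat, -1), head(tr$lon, -1),
                      tail(tr$lat, -1), tail(tr$lon, -1)) / 1000
  expect_true(all(step <= kern$max_km + 1e-9))
})

test_that("synthetic tracks are recovered within sensor-limited error", {
  cfg <- sim_config(n_animals = 2, study_start = as.Date("2012-11-02"),
                    study_end = as.Date("2012-12-31"), seed = 74)
  mov <- simulate_movement(cfg)
  gs <- simulate_geosensor(mov, "M1", cfg, sigma_lon = 1, sigma_sst = 0.5)
  g <- geo_grid(lat_range = c(19, 22.5), lon_range = c(36.5, 39), cell = 0.25)
  # fix every 7th day from the true position (acoustic COA analogue)
  coas <- data.frame(animal_id = "M1",
                     bin_start = as.POSIXct(gs$date[seq(1, nrow(gs), 7)],
                                            tz = "UTC"),
                     lat = gs$true_lat[seq(1, nrow(gs), 7)],
                     lon = gs$true_lon[seq(1, nrow(gs), 7)],
                     n_detections = 5L)
  res <- geolocate(gs, g, start = c(gs$true_lat[1], gs$true_lon[1]),
                   coas = coas)
  err_km <- haversine_m(res$track$lat, res$track$lon,
                        gs$true_lat, gs$true_lon) / 1000
  fixed <- seq_len(nrow(gs)) %in% res$fixed_days
  cell_km <- 111.195 * g$cell
  expect_lt(median(err_km[fixed]), cell_km)        # within one grid cell
  expect_lt(median(err_km[!fixed]), 150)           # sensor-limited elsewhere
  expect_equal(unname(rowSums(res$posterior)), rep(1, nrow(gs)),
               tolerance = 1e-10)
})
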