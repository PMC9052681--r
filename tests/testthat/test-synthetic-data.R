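test_that("same seed gives byte-identical synthetic datasets", {
  a <- small_dataset(seed = 9, n_animals = 3, end = "2012-12-01")
  b <- small_dataset(seed = 9, n_animals = 3, end = "2012-12-01")
  expect_identical(a$data$detections, b$data$detections)
  expect_identical(a$data$labels, b$data$labels)
  expect_identical(a$data$environment, b$data$environment)
  expect_identical(a$data$truth$daily, b$data$truth$daily)
  c_ <- small_dataset(seed = 10, n_animals = 3, end = "2012-12-01")
  expect_false(identical(a$data$detections, c_$data$detections))
})

test_that("detection probability is ~50% at the 540 m range", {
  # animal pinned at exactly 540 m from a single receiver for 40 days
  cfg <- sim_config(n_animals = 1, study_start = as.Date("2013-01-01"),
                    study_end = as.Date("2013-02-09"), seed = 5)
  st <- line_stations(1, start = utc("2012-12-01"), end = utc("2014-01-01"))
  cfg$array <- st
  dep <- data.frame(animal_id = "M1", tag_id = "T1",
                    release_time = utc("2012-12-20"), sex = "F",
                    wingspan_cm = 300, maturity = "mature",
                    satellite_tag = "none")
  times <- seq(utc("2013-01-01"), utc("2013-02-09 23:50:00"), by = 600)
  # 540 m due north of the receiver
  lat <- st$lat[1] + 540 / 111195
  stopifnot(abs(haversine_m(lat, 37, st$lat[1], 37) - 540) < 0.5)
  movement <- list(positions = data.frame(animal_id = "M1", time = times,
                                          lat = lat, lon = 37,
                                          present = TRUE),
                   daily = data.frame(animal_id = "M1",
                                      date = seq(as.Date("2013-01-01"),
                                                 as.Date("2013-02-09"), 1),
                                      p_present = 1, present = TRUE))
  cfg$echo_rate <- 0; cfg$false_single_rate <- 0
  det <- suppressMessages(simulate_detections(movement, cfg, dep))
  n_tx <- (40 * 86400) / 360   # expected transmissions at mean delay 360 s
  frac <- nrow(det$detections) / n_tx
  # binomial error around 0.5 with ~9600 trials, and delay-mean slack
  expect_gt(frac, 0.46)
  expect_lt(frac, 0.54)
})

test_that("inter-detection gaps reflect uniform(310, 410) transmission delays", {
  # at near-zero range p = p_max, so observed mean gap ~ 360 / 0.95
  cfg <- sim_config(n_animals = 1, study_start = as.Date("2013-01-01"),
                    study_end = as.Date("2013-01-31"), seed = 6,
                    echo_rate = 0, false_single_rate = 0)
  st <- line_stations(1, start = utc("2012-12-01"), end = utc("2014-01-01"))
  cfg$array <- st
  dep <- data.frame(animal_id = "M1", tag_id = "T1",
                    release_time = utc("2012-12-20"), sex = "F",
                    wingspan_cm = 300, maturity = "mature",
                    satellite_tag = "none")
  times <- seq(utc("2013-01-01"), utc("2013-01-31 23:50:00"), by = 600)
  movement <- list(positions = data.frame(animal_id = "M1", time = times,
                                          lat = st$lat[1], lon = 37,
                                          present = TRUE),
                   daily = data.frame(animal_id = "M1",
                                      date = seq(as.Date("2013-01-01"),
                                                 as.Date("2013-01-31"), 1),
                                      p_present = 1, present = TRUE))
  det <- suppressMessages(simulate_detections(movement, cfg, dep))$detections
  gaps <- diff(as.numeric(det$timestamp))
  expect_equal(mean(gaps), 360 / 0.95, tolerance = 0.02)
  expect_gte(min(gaps), 310 - 1)   # rounding to whole seconds
})

test_that("environmental series has lunar cycle and positive seasonal chla", {
  cfg <- sim_config(seed = 3)
  env <- simulate_environment(cfg)
  expect_true(all(env$chla > 0))
  expect_true(all(env$moon_frac >= 0 & env$moon_frac <= 1))
  expect_gt(max(env$moon_frac), 0.995)
  expect_lt(min(env$moon_frac), 0.005)
  # successive full moons ~29.5 days apart (peak finding)
  m <- env$moon_frac
  peaks <- which(diff(sign(diff(m))) == -2) + 1
  peaks <- peaks[m[peaks] > 0.9]
  expect_equal(mean(diff(peaks)), 29.53, tolerance = 0.02)
  # seasonality: mean summer chla exceeds mean winter chla
  mon <- as.integer(format(env$date, "%m"))
  expect_gt(mean(env$chla[mon %in% 6:8]), mean(env$chla[mon %in% c(12, 1, 2)]))
})

test_that("movement respects the hard speed cap and anchors at stations", {
  cfg <- sim_config(n_animals = 3, study_start = as.Date("2012-11-02"),
                    study_end = as.Date("2012-12-31"), seed = 8)
  mov <- simulate_movement(cfg)
  for (a in unique(mov$positions$animal_id)) {
    p <- mov$positions[mov$positions$animal_id == a, ]
    step <- haversine_m(head(p$lat, -1), head(p$lon, -1),
                        tail(p$lat, -1), tail(p$lon, -1))
    expect_lte(max(step), cfg$speed_cap_mps * cfg$step_minutes * 60 + 1e-6)
  }
  # zero step noise: the walk converges onto the anchor station
  cfg0 <- sim_config(n_animals = 1, study_start = as.Date("2012-11-02"),
                     study_end = as.Date("2012-11-20"), seed = 8,
                     step_sd_m = 0, anchor_switch_prob = 0,
                     presence = list(intercept = 50, day_amp = 0,
                                     day_peak_doy = 288, chla_coef = 0,
                                     moon_coef = 0))
  mov0 <- simulate_movement(cfg0)
  last <- tail(mov0$positions, 1)
  pos <- station_positions(cfg0$array)
  dmin <- min(haversine_m(last$lat, last$lon, pos$lat, pos$lon))
  expect_lt(dmin, 1)
})

test_that("realized daily presence is calibrated to the configured model", {
  # persistence 0 isolates the marginal mechanism for a clean MC bound
  cfg <- sim_config(n_animals = 15, study_start = as.Date("2012-11-02"),
                    study_end = as.Date("2013-10-31"), seed = 12,
                    presence_persistence = 0)
  dep <- simulate_deployments(cfg)
  env <- simulate_environment(cfg)
  mov <- simulate_movement(cfg, dep, env)
  d <- mov$daily
  n <- nrow(d)
  se <- sqrt(sum(d$p_present * (1 - d$p_present))) / n
  expect_lt(abs(mean(d$present) - mean(d$p_present)), 4 * se)
  # calibration within probability bins
  bin <- cut(d$p_present, quantile(d$p_present, 0:4 / 4), include.lowest = TRUE)
  obs <- tapply(d$present, bin, mean)
  exp_ <- tapply(d$p_present, bin, mean)
  expect_lt(max(abs(obs - exp_)), 0.05)
})

test_that("default presence persistence yields multi-day absence runs", {
  cfg <- sim_config(n_animals = 10, study_start = as.Date("2012-11-02"),
                    study_end = as.Date("2013-10-31"), seed = 13)
  mov <- simulate_movement(cfg)
  d <- mov$daily
  # marginal calibration still holds (generous bound for autocorrelation)
  expect_lt(abs(mean(d$present) - mean(d$p_present)), 0.1)
  runs <- unlist(lapply(split(d$present, d$animal_id), function(p) {
    r <- rle(!p)
    r$lengths[r$values]
  }))
  expect_gt(mean(runs), 3)     # absences last days-to-weeks, not single days
  expect_gt(max(runs), 14)
})

test_that("geosensor errors match their configured scales", {
  cfg <- sim_config(n_animals = 1, study_start = as.Date("2012-11-02"),
                    study_end = as.Date("2013-10-31"), seed = 4)
  mov <- simulate_movement(cfg)
  gs <- simulate_geosensor(mov, "M1", cfg, sigma_lon = 1, sigma_sst = 0.5)
  err <- gs$lon_est - gs$true_lon
  expect_equal(mean(abs(err) <= 1), 0.683, tolerance = 0.1)
  expect_equal(sd(err), 1, tolerance = 0.15)
  serr <- gs$sst_tag - sst_field(gs$true_lat, gs$date)
  expect_equal(sd(serr), 0.5, tolerance = 0.15)
  # zero-noise degenerate case pins the sensor to the truth
  gs0 <- simulate_geosensor(mov, "M1", cfg, sigma_lon = 0, sigma_sst = 0)
  expect_equal(gs0$lon_est, gs0$true_lon)
})

test_that("deployments honour the maturity size rule and tag uniqueness", {
  cfg <- sim_config(n_animals = 12, seed = 2)
  dep <- simulate_deployments(cfg)
  expect_equal(dep$maturity, ifelse(dep$wingspan_cm >= 320,
                                    "mature", "immature"))
  expect_false(anyDuplicated(dep$tag_id) > 0)
  expect_true(all(dep$release_time <
                    as.POSIXct(cfg$study_start, tz = "UTC")))
})

test_that("dataset writer emits the canonical schemas and round-trips", {
  x <- small_dataset(seed = 21, n_animals = 2, end = "2012-11-20")
  dir <- withr::local_tempdir()
  write_dataset(x$data, dir)
  st <- read_receivers(file.path(dir, "receivers.csv"))
  det <- suppressMessages(read_detections(file.path(dir, "detections.csv"), st))
  expect_identical(det[, 1:3], x$data$detections[, 1:3])
  dep <- read_deployments(file.path(dir, "deployments.csv"))
  expect_equal(dep$animal_id, x$data$deployments$animal_id)
  env <- read_environment(file.path(dir, "environment.csv"))
  expect_equal(nrow(env), nrow(x$data$environment))
})
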