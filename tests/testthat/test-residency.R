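test_that("residence index reproduces published per-animal ratios", {
  expect_equal(round(residence_index(352, 702), 2), 0.50)
  expect_equal(round(residence_index(21, 122), 2), 0.17)
  expect_equal(residence_index(122, 122), 1)
  expect_error(residence_index(1, 0), "track_days")
  # every printed Table-2 RI equals detection_days / track_days at 2 dp
  t2 <- dmnp_table2()
  expect_equal(round(residence_index(t2$detection_days, t2$track_days), 2),
               t2$ri)
})

test_that("residency events follow the two-detection trigger and 1-h timeout", {
  # two detections then 2 h silence: one event [t, t+10], n = 2
  det <- make_det("T1", "R1", c("2012-11-02 09:00:00", "2012-11-02 09:10:00",
                                "2012-11-02 12:00:00", "2012-11-02 12:05:00"))
  ev <- segment_residency_events(det)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$n_detections, c(2L, 2L))
  expect_equal(ev$end[1], utc("2012-11-02 09:10:00"))

  # receiver switch closes the event; the lone R2 detection opens nothing
  det2 <- rbind(make_det("T1", "R1", c("2012-11-02 09:00:00",
                                       "2012-11-02 09:10:00")),
                make_det("T1", "R2", "2012-11-02 09:20:00"))
  ev2 <- segment_residency_events(det2)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$receiver_id, "R1")
  expect_equal(ev2$end, utc("2012-11-02 09:10:00"))

  # single detections never form events
  det3 <- make_det("T1", c("R1", "R2", "R1"),
                   c("2012-11-02 09:00:00", "2012-11-02 09:20:00",
                     "2012-11-02 09:40:00"))
  expect_equal(nrow(segment_residency_events(det3)), 0)

  # 67 detections over 9 h with sub-hour gaps form one long event
  times <- utc("2013-06-10 06:00:00") + round(seq(0, 9 * 3600, length.out = 67))
  det4 <- make_det("T1", "R1", format(times, "%Y-%m-%d %H:%M:%S"))
  ev4 <- segment_residency_events(det4)
  expect_equal(nrow(ev4), 1)
  expect_equal(ev4$n_detections, 67L)
  expect_equal(ev4$duration_min, 540, tolerance = 0.01)
})

test_that("event segmentation agrees with the state-machine oracle", {
  set.seed(91)
  st <- line_stations(3)
  for (trial in 1:80) {
    n <- sample(2:50, 1)
    det <- make_det("T1", sample(st$receiver_id, n, replace = TRUE),
                    "2012-11-02 00:00:00")
    det$timestamp <- utc("2012-11-02 00:00:00") +
      cumsum(sample(c(30, 300, 1800, 4000), n, replace = TRUE))
    ev <- segment_residency_events(det)
    orc <- event_oracle(det)
    if (is.null(orc)) {
      expect_equal(nrow(ev), 0)
    } else {
      expect_equal(nrow(ev), nrow(orc))
      expect_equal(ev$receiver_id, orc$receiver_id)
      expect_equal(ev$start, orc$start)
      expect_equal(ev$end, orc$end)
      expect_equal(ev$n_detections, orc$n_detections)
    }
  }
})

test_that("events of one animal never overlap and cover retained detections", {
  x <- small_dataset(seed = 19, n_animals = 3, end = "2012-12-15")
  qc <- suppressMessages(filter_detections(x$data$detections, x$data$stations,
                                           x$data$deployments))
  ev <- segment_residency_events(qc$retained)
  for (tag in unique(ev$tag_id)) {
    e <- ev[ev$tag_id == tag, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1) {
      expect_true(all(head(e$end, -1) <= tail(e$start, -1)))
    }
  }
  expect_true(all(ev$end >= ev$start))
  expect_true(all(ev$n_detections >= 2))
})

test_that("maximum non-residence gap counts absent days between presences", {
  det <- rbind(make_det("T1", "R1", c("2012-11-01 09:00:00",
                                      "2012-11-01 10:00:00",
                                      "2012-11-11 09:00:00",
                                      "2012-11-11 10:00:00")),
               make_det("T2", "R1", c("2012-11-01 09:00:00",
                                      "2012-11-01 10:00:00",
                                      "2012-11-02 09:00:00",
                                      "2012-11-02 10:00:00")))
  dp <- daily_presence(det, tz_offset = 0)
  g <- max_nonresidence(dp)
  expect_equal(unname(g["T1"]), 9L)    # present day 1 and day 11 only
  expect_equal(unname(g["T2"]), 0L)    # present every tracked day
})

test_that("minimum distance sums distinct-receiver hops only", {
  st <- line_stations(2, spacing_km = 1)
  det <- make_det("T1", c("R1", "R1", "R1"),
                  c("2012-11-02 09:00:00", "2012-11-02 10:00:00",
                    "2012-11-02 11:00:00"))
  expect_equal(min_distance_travelled(det, st)$total_km, 0)
  det2 <- make_det("T1", c("R1", "R2", "R1"),
                   c("2012-11-02 09:00:00", "2012-11-02 12:00:00",
                     "2012-11-02 15:00:00"))
  expect_equal(min_distance_travelled(det2, st)$total_km, 2,
               tolerance = 1e-4)
  # array-geometry fixture: a single N1 -> S3 hop spans ~29 km
  arr <- dungonab_array()
  det3 <- make_det("T1", c("N1", "S3"),
                   c("2013-01-10 09:00:00", "2013-01-11 09:00:00"))
  expect_equal(min_distance_travelled(det3, arr)$total_km, 29,
               tolerance = 0.01)
})

test_that("movement network counts nodes, edges and isolated receivers", {
  st <- line_stations(3)
  det <- make_det("T1", c("R1", "R1", "R2"),
                  c("2012-11-02 09:00:00", "2012-11-02 09:10:00",
                    "2012-11-02 09:20:00"))
  net <- build_network(det, st)
  expect_equal(net$nodes$n_detections[net$nodes$receiver_id == "R1"], 2L)
  expect_equal(net$nodes$n_detections[net$nodes$receiver_id == "R2"], 1L)
  expect_equal(net$edges$weight, 1L)
  expect_equal(net$edges$from, "R1")
  expect_equal(net$edges$to, "R2")
  # zero-detection receiver is carried as an isolated node
  expect_true("R3" %in% net$nodes$receiver_id)
  expect_equal(net$nodes$n_detections[net$nodes$receiver_id == "R3"], 0L)
  # node weights conserve the total detection count
  expect_equal(sum(net$nodes$n_detections), nrow(det))
  # no switches -> no edges
  net2 <- build_network(make_det("T1", "R1", "2012-11-02 09:00:00"), st)
  expect_equal(nrow(net2$edges), 0)
})

test_that("group comparisons behave under symmetry and degeneracy", {
  # two identical groups: t ~ 0, p ~ 1
  summ <- data.frame(tag_id = paste0("T", 1:8),
                     ri = rep(c(0.2, 0.3, 0.4, 0.5), 2),
                     total_detections = rep(c(100, 200, 300, 400), 2))
  dep <- data.frame(tag_id = paste0("T", 1:8),
                    sex = rep(c("F", "M"), each = 4),
                    wingspan_cm = rep(c(250, 280, 310, 340), 2))
  gs <- group_stats(summ, dep)
  expect_equal(unname(gs$welch_ri_sex$statistic), 0, tolerance = 1e-10)
  expect_equal(gs$welch_ri_sex$p.value, 1, tolerance = 1e-10)
  # degenerate group is flagged, not an error
  summ2 <- summ[1:5, ]; dep2 <- dep[1:5, ]
  gs2 <- group_stats(summ2, dep2)
  expect_s3_class(gs2$welch_ri_sex, "skipped_test")
})

test_that("estimated RI approaches configured occupancy as detection improves", {
  base <- list(n_animals = 6, study_start = as.Date("2012-11-02"),
               study_end = as.Date("2013-02-28"), seed = 33)
  run <- function(r50) {
    cfg <- do.call(sim_config, c(base, list(detect_r50_m = r50)))
    d <- suppressMessages(simulate_dataset(cfg))
    qc <- suppressMessages(filter_detections(d$detections, d$stations,
                                             d$deployments))
    rs <- residency_summary(qc$retained, d$stations)
    tr <- d$truth$daily
    dep <- d$deployments
    # true occupancy over the same first-to-last detection span as RI
    day <- to_calendar_day(qc$retained$timestamp)
    occ <- vapply(seq_len(nrow(rs)), function(i) {
      a <- dep$animal_id[match(rs$tag_id[i], dep$tag_id)]
      dd <- day[qc$retained$tag_id == rs$tag_id[i]]
      w <- tr$animal_id == a & tr$date >= min(dd) & tr$date <= max(dd)
      mean(tr$present[w])
    }, numeric(1))
    list(ri = rs$ri, occ = occ)
  }
  hi <- run(5000)   # near-perfect detection over the whole bay
  expect_lt(mean(abs(hi$ri - hi$occ)), 0.06)
  lo <- run(200)    # weak detection can only lower detection days
  expect_lte(mean(lo$ri), mean(hi$ri) + 0.02)
})
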