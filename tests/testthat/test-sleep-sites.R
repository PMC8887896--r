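test_that("sleep location is the median of the first pre-dawn fixes", {
  date <- as.Date("2012-08-02")
  t0 <- t_at("2012-08-02 05:40:00")
  mk_gps <- function(n, lon, lat) {
    data.frame(individual_id = "a", timestamp = t0 + (seq_len(n) - 1) * 30,
               lon = lon, lat = lat)
  }
  # identical fixes: exactly that point
  g <- mk_gps(10, 36.87, 0.29)
  loc <- infer_sleep_location(g, date)
  expect_equal(unname(loc$location), c(36.87, 0.29))

  # 9 fixes before the cutoff: excluded
  loc9 <- infer_sleep_location(mk_gps(9, 36.87, 0.29), date)
  expect_true(loc9$excluded)
  expect_equal(loc9$reason, "lt_10_fixes")

  # fixes after 06:15 do not count
  g_late <- mk_gps(9, 36.87, 0.29)
  g_late <- rbind(g_late,
                  data.frame(individual_id = "a",
                             timestamp = t_at("2012-08-02 06:20:00"),
                             lon = 36.87, lat = 0.29))
  expect_true(infer_sleep_location(g_late, date)$excluded)

  # median is robust to one 50 m outlier
  set.seed(2)
  p <- accsleep:::local_unproject(rnorm(10, 0, 1), rnorm(10, 0, 1),
                                  36.87, 0.29)
  p$lon[10] <- accsleep:::local_unproject(50, 0, 36.87, 0.29)$lon
  g_out <- data.frame(individual_id = "a",
                      timestamp = t0 + (0:9) * 30,
                      lon = p$lon, lat = p$lat)
  loc_o <- infer_sleep_location(g_out, date)
  xy <- accsleep:::local_project(loc_o$location[1], loc_o$location[2],
                                 36.87, 0.29)
  ctr <- c(mean(accsleep:::local_project(p$lon[1:9], p$lat[1:9],
                                         36.87, 0.29)$x),
           mean(accsleep:::local_project(p$lon[1:9], p$lat[1:9],
                                         36.87, 0.29)$y))
  expect_lt(sqrt((xy$x - ctr[1])^2 + (xy$y - ctr[2])^2), 1.5)
})

test_that("tree assignment uses containment, nearest crown, and the 10 m rule", {
  tm <- make_tree_map(5, seed = 8)
  # inside a crown: that tree
  ctr <- tm$centroids[3, ]
  ll <- accsleep:::local_unproject(ctr[1], ctr[2], tm$site_lon, tm$site_lat)
  a <- assign_sleep_tree(c(ll$lon, ll$lat), tm)
  expect_equal(a$tree_id, names(tm$trees)[3])
  expect_equal(a$distance, 0)

  # 7 m outside the nearest crown: still assigned, distance recorded
  poly <- tm$trees[[1]]
  vx <- poly[1, ]
  dir <- vx - accsleep:::polygon_centroid(poly)
  dir <- dir / sqrt(sum(dir^2))
  pt <- vx + 7 * dir
  ll7 <- accsleep:::local_unproject(pt[1], pt[2], tm$site_lon, tm$site_lat)
  a7 <- assign_sleep_tree(c(ll7$lon, ll7$lat), tm)
  expect_false(a7$excluded)
  expect_equal(a7$distance, 7, tolerance = 0.05)

  # far from every crown: excluded
  llf <- accsleep:::local_unproject(500, 500, tm$site_lon, tm$site_lat)
  af <- assign_sleep_tree(c(llf$lon, llf$lat), tm)
  expect_true(af$excluded)
  expect_equal(af$reason, "gt_10m_from_crown")

  expect_error(assign_sleep_tree(c(36.87, 0.29),
                                 list(trees = list(), site_lon = 36.87,
                                      site_lat = 0.29)), "empty")
})

test_that("travel distance discretizes to 5 m and applies coverage rules", {
  date <- as.Date("2012-08-02")
  mk_track <- function(x, y, t_start = "07:00:00", dt = 10) {
    t0 <- t_at(paste("2012-08-02", t_start))
    ll <- accsleep:::local_unproject(x, y, 36.87, 0.29)
    data.frame(individual_id = "a",
               timestamp = t0 + (seq_along(x) - 1) * dt,
               lon = ll$lon, lat = ll$lat)
  }
  # stationary with jitter bounded by 2 m: no step can reach 5 m
  set.seed(5)
  n <- 3700  # covers 07:00 -> 17:16 at 10 s
  r <- 2 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  g <- mk_track(r * cos(th), r * sin(th))
  d <- discretized_travel_distance(g, date)
  expect_false(d$excluded)
  expect_equal(d$distance_m, 0)

  # straight 100 m walk with 1 m steps: distance within 100 +/- 5
  xs <- seq(0, 100, by = 1)
  xs <- c(xs, rep(100, 3700 - length(xs)))
  g2 <- mk_track(xs, rep(0, length(xs)))
  d2 <- discretized_travel_distance(g2, date)
  expect_lt(abs(d2$distance_m - 100), 5)

  # discretized distance never exceeds the raw cumulative distance
  set.seed(6)
  xr <- cumsum(rnorm(3700, 0, 3)); yr <- cumsum(rnorm(3700, 0, 3))
  g3 <- mk_track(xr, yr)
  d3 <- discretized_travel_distance(g3, date)
  raw <- sum(sqrt(diff(xr)^2 + diff(yr)^2))
  expect_lte(d3$distance_m, raw)

  # first fix later than 07:30: excluded
  g4 <- mk_track(xs, rep(0, length(xs)), t_start = "07:45:00")
  d4 <- discretized_travel_distance(g4, date)
  expect_true(d4$excluded)
  expect_equal(d4$reason, "first_fix_late")
})

test_that("rendered daytime loop recovers its nominal length", {
  cfg <- sim_config(n_individuals = 1, n_nights = 1, seed = 44)
  tm <- make_tree_map(cfg$n_trees, seed = 44)
  tr <- generate_group_truth(cfg, tm)
  # fix spacing ~10 m: with 1 m jitter the 5 m discretization keeps the
  # measured distance near the nominal loop length
  gps <- render_gps_fixes(tr, cfg, day_track = TRUE,
                          day_track_length = 3000, fix_jitter = 1,
                          day_track_interval = 120)
  d <- discretized_travel_distance(gps, cfg$start_date + 1,
                                   ref = c(cfg$site_lon, cfg$site_lat))
  expect_false(d$excluded)
  expect_lt(abs(d$distance_m - 3000) / 3000, 0.05)
  # on dense 1 Hz-like tracks, jitter inflates the discretized distance:
  # it stays an upper bound on the nominal length
  gps_d <- render_gps_fixes(tr, cfg, day_track = TRUE,
                            day_track_length = 3000, fix_jitter = 1,
                            day_track_interval = 10)
  dd <- discretized_travel_distance(gps_d, cfg$start_date + 1,
                                    ref = c(cfg$site_lon, cfg$site_lat))
  expect_gt(dd$distance_m, 3000 * 0.97)
})

test_that("twilight times match closed-form solar geometry", {
  # equator at equinox: astronomical twilight begins ~72 min before
  # sunrise (exact hour-angle arithmetic gives 68.7 min)
  tw <- compute_twilight(as.Date("2012-03-20"), 0, 0)
  sr <- compute_twilight(as.Date("2012-03-20"), 0, 0, depression = 0.833)
  gap <- as.numeric(difftime(sr$morning_astro_start,
                             tw$morning_astro_start, units = "mins"))
  expect_lt(abs(gap - 72), 5)

  # determinism
  tw2 <- compute_twilight(as.Date("2012-03-20"), 0, 0)
  expect_identical(tw, tw2)

  # study site: evening end after sunset, morning start before sunrise
  site <- c(36.87, 0.29)
  twm <- compute_twilight(as.Date("2012-08-15"), site[1], site[2])
  srm <- compute_twilight(as.Date("2012-08-15"), site[1], site[2],
                          depression = 0.833)
  expect_gt(as.numeric(twm$evening_astro_end),
            as.numeric(srm$evening_astro_end))
  expect_lt(as.numeric(twm$morning_astro_start),
            as.numeric(srm$morning_astro_start))

  # the sun never gets 18 degrees below the horizon in midsummer at 60N
  expect_error(compute_twilight(as.Date("2012-06-21"), 0, 60),
               "undefined")
})
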