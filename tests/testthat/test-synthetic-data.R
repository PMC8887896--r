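test_that("tree map produces disjoint convex crowns, deterministically", {
  tm1 <- make_tree_map(10, seed = 1)
  tm2 <- make_tree_map(10, seed = 1)
  expect_identical(tm1$trees, tm2$trees)
  expect_length(tm1$trees, 10)

  # single tree contains its own centroid
  tm <- make_tree_map(1, seed = 3)
  ctr <- tm$centroids[1, ]
  expect_true(bf_in_convex(ctr[1], ctr[2], tm$trees[[1]]))

  # pairwise disjointness by brute force: no sampled point in two crowns
  set.seed(99)
  polys <- tm1$trees
  for (a in 1:9) {
    for (b in (a + 1):10) {
      xs <- runif(400, min(polys[[a]][, 1], polys[[b]][, 1]),
                  max(polys[[a]][, 1], polys[[b]][, 1]))
      ys <- runif(400, min(polys[[a]][, 2], polys[[b]][, 2]),
                  max(polys[[a]][, 2], polys[[b]][, 2]))
      both <- mapply(function(x, y) {
        bf_in_convex(x, y, polys[[a]]) && bf_in_convex(x, y, polys[[b]])
      }, xs, ys)
      expect_false(any(both))
    }
  }

  expect_error(make_tree_map(0), "positive")
})

test_that("ground truth respects the configured sleep architecture", {
  cfg <- sim_config(n_individuals = 4, n_nights = 5, seed = 21)
  tm <- make_tree_map(cfg$n_trees, seed = 21)
  tr <- generate_group_truth(cfg, tm)

  # conservation: every epoch of the sleep window is sleep or wake
  for (i in 1:4) {
    for (n in 1:5) {
      o <- tr$onset_epoch[i, n]; w <- tr$waking_epoch[i, n]
      st <- tr$state[i, o:(w - 1), n]
      expect_equal(sum(st == 1) + sum(st != 1), unname(w - o))
      # no wake bouts within 40 min of onset or waking
      expect_true(all(tr$state[i, o:(o + 39), n] == 1))
      expect_true(all(tr$state[i, (w - 40):(w - 1), n] == 1))
    }
  }

  # no wake inside the sleep window when bouts and coupling are off
  cfg0 <- sim_config(n_individuals = 3, n_nights = 4, wake_bout_rate = 0,
                     coupling_prob = 0, seed = 5)
  tr0 <- generate_group_truth(cfg0, tm)
  for (i in 1:3) {
    for (n in 1:4) {
      o <- tr0$onset_epoch[i, n]; w <- tr0$waking_epoch[i, n]
      expect_true(all(tr0$state[i, o:(w - 1), n] == 1))
    }
  }

  # degenerate preference: every individual uses exactly one tree
  cfg_inf <- sim_config(n_individuals = 5, n_nights = 8,
                        tree_preference_concentration = Inf, seed = 9)
  tr_inf <- generate_group_truth(cfg_inf, tm)
  expect_true(all(apply(tr_inf$tree, 1,
                        function(x) length(unique(x)) == 1)))

  # determinism
  tr_b <- generate_group_truth(cfg, tm)
  expect_identical(tr$state, tr_b$state)
  expect_identical(tr$tree, tr_b$tree)
})

test_that("wake onsets are cross-individually independent without coupling", {
  # two individuals, one tree, many nights: lagged co-occurrence of wake
  # onsets should show no association
  cfg <- sim_config(n_individuals = 2, n_nights = 200, n_trees = 1,
                    coupling_prob = 0, seed = 31)
  tm <- make_tree_map(1, seed = 31)
  tr <- generate_group_truth(cfg, tm)
  arr <- truth_epoch_array(tr)
  onset <- function(v) c(FALSE, v[-1] == 1 & v[-length(v)] == 0)
  a_prev <- c(); b_now <- c()
  for (n in seq_len(200)) {
    oa <- onset(arr[1, , n]); ob <- onset(arr[2, , n])
    a_prev <- c(a_prev, oa[-length(oa)])
    b_now <- c(b_now, ob[-1])
  }
  p <- suppressWarnings(stats::chisq.test(table(a_prev, b_now))$p.value)
  expect_gt(p, 0.01)
})

test_that("rendered bursts hit the configured emission distributions", {
  cfg <- sim_config(n_individuals = 1, n_nights = 2, seed = 7,
                    missing_burst_prob = 0)
  tm <- make_tree_map(cfg$n_trees, seed = 7)
  tr <- generate_group_truth(cfg, tm)
  b <- render_accel_bursts(tr, cfg)
  lv <- log(compute_vedba(b)$mean + 1e-6)
  st <- as.vector(tr$state[1, , ])
  sleep_lv <- lv[st == 1]
  se <- cfg$sleep_logvedba_sd / sqrt(length(sleep_lv))
  expect_lt(abs(mean(sleep_lv) - cfg$sleep_logvedba_mean), 3 * se)

  # deterministic emissions: every sleep burst yields identical log VeDBA
  cfg0 <- sim_config(n_individuals = 1, n_nights = 1, seed = 7,
                     sleep_logvedba_sd = 0, day_logvedba_sd = 0,
                     restingwake_logvedba_sd = 0)
  tr0 <- generate_group_truth(cfg0, tm)
  b0 <- render_accel_bursts(tr0, cfg0)
  lv0 <- log(compute_vedba(b0)$mean + 1e-6)
  sl <- lv0[as.vector(tr0$state[1, , ]) == 1]
  expect_lt(diff(range(sl)), 1e-9)
  expect_lt(abs(sl[1] - cfg0$sleep_logvedba_mean), 1e-6)

  # byte-identical re-render under the same seed
  b2 <- render_accel_bursts(tr, cfg)
  expect_identical(b$samples, b2$samples)
})

test_that("missingness injection drops the expected bursts", {
  cfg <- sim_config(n_individuals = 2, n_nights = 5, seed = 13)
  tm <- make_tree_map(cfg$n_trees, seed = 13)
  tr <- generate_group_truth(cfg, tm)
  b <- render_accel_bursts(tr, cfg)

  # probability zero, no runs: identity
  m0 <- inject_missingness(b, 0)
  expect_identical(m0$bursts$samples, b$samples)
  expect_equal(nrow(m0$dropped), 0)

  # i.i.d. dropout at 8.3%: observed count near the binomial mean
  m <- inject_missingness(b, 0.083, seed = 2)
  n_total <- length(b$individual_id)
  expected <- 0.083 * n_total
  expect_lt(abs(nrow(m$dropped) - expected),
            4 * sqrt(n_total * 0.083 * 0.917))

  # forced consecutive gap is dropped exactly
  run <- data.frame(individual_id = "ind_01",
                    start = t_at("2012-08-01 23:00:00"), length = 25)
  mr <- inject_missingness(b, 0, consecutive_runs = run)
  expect_equal(nrow(mr$dropped), 25)
  expect_true(all(mr$dropped$individual_id == "ind_01"))

  expect_error(inject_missingness(b, 1.5), "0, 1")
})

test_that("GPS rendering places fixes on the true sleep tree", {
  cfg <- sim_config(n_individuals = 3, n_nights = 2, n_trees = 4, seed = 17)
  tm <- make_tree_map(4, seed = 17)
  tr <- generate_group_truth(cfg, tm)
  gps0 <- render_gps_fixes(tr, cfg, fix_jitter = 0)
  # zero jitter: inferred location is exactly the tree centroid
  g <- gps0[gps0$individual_id == "ind_01", ]
  loc <- infer_sleep_location(g, cfg$start_date + 1)
  expect_false(loc$excluded)
  p <- accsleep:::local_project(loc$location[1], loc$location[2],
                                tm$site_lon, tm$site_lat)
  ctr <- tm$centroids[tr$tree[1, 1], ]
  expect_lt(sqrt((p$x - ctr[1])^2 + (p$y - ctr[2])^2), 0.01)

  gps_a <- render_gps_fixes(tr, cfg)
  gps_b <- render_gps_fixes(tr, cfg)
  expect_identical(gps_a, gps_b)
})
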