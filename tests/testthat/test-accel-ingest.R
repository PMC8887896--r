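make_burst <- function(m, rate = 10, id = "a",
                       t0 = t_at("2012-08-01 18:00:00")) {
  accel_bursts(id, t0, array(m, c(1, nrow(m), 3)), rate = rate)
}

test_that("VeDBA vanishes for constant signals and scales linearly", {
  m <- matrix(rep(c(0, 0, 1), each = 25), 25)
  b <- make_burst(m)
  v <- compute_vedba(b)
  expect_equal(v$mean, 0)
  expect_true(all(v$per_sample == 0))

  # homogeneity of degree 1 under axis scaling
  set.seed(4)
  m2 <- matrix(rnorm(75), 25)
  v1 <- compute_vedba(make_burst(m2))$mean
  v2 <- compute_vedba(make_burst(2 * m2))$mean
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
  expect_gte(min(compute_vedba(make_burst(m2))$per_sample), 0)
})

test_that("VeDBA matches a brute-force running-mean oracle", {
  # spike burst: x = [0,0,0,1,0,0,0] at 10 Hz with the 0.7 s window
  m <- cbind(c(0, 0, 0, 1, 0, 0, 0), 0, 0)
  b <- make_burst(m)
  v <- compute_vedba(b, smoothing_window = 0.7)
  expect_equal(as.vector(v$per_sample), bf_vedba(m, 10, 0.7),
               tolerance = 1e-12)
  expect_equal(v$mean, mean(bf_vedba(m, 10, 0.7)), tolerance = 1e-12)

  # random bursts
  set.seed(11)
  for (k in 1:50) {
    m <- matrix(rnorm(75, sd = runif(1, 0.1, 5)), 25)
    v <- compute_vedba(make_burst(m))
    expect_equal(as.vector(v$per_sample), bf_vedba(m, 10, 0.7),
                 tolerance = 1e-12)
  }

  # burst shorter than the smoothing window errors
  short <- make_burst(matrix(rnorm(15), 5))
  expect_error(compute_vedba(short, smoothing_window = 0.7), "shorter")
})

test_that("daytime harmonization interpolates onto the burst schedule", {
  t0 <- t_at("2012-08-01 10:00:00")
  tt <- seq(0, 180, by = 1 / 12)
  const <- data.frame(individual_id = "a", time = t0 + tt,
                      acc_x = 1, acc_y = 2, acc_z = 3)
  hb <- harmonize_daytime(const)
  expect_equal(hb$rate, 10)
  expect_equal(dim(hb$samples)[2], 25)
  expect_true(all(abs(hb$samples[, , 1] - 1) < 1e-12))

  # linear ramp is reproduced exactly by linear interpolation
  ramp <- data.frame(individual_id = "a", time = t0 + tt,
                     acc_x = 0.5 * tt, acc_y = 0, acc_z = 0)
  hr <- harmonize_daytime(ramp)
  for (i in seq_along(hr$epoch_start)) {
    rel <- as.numeric(hr$epoch_start[i]) - as.numeric(t0) + (0:24) / 10
    expect_lt(max(abs(hr$samples[i, , 1] - 0.5 * rel)), 1e-6)
  }

  # 0.5 Hz sinusoid matches the closed form within the linear-
  # interpolation error bound amp * (w * dt)^2 / 8 (~0.86% of amplitude
  # for a 12 Hz source)
  amp <- 2
  sine <- data.frame(individual_id = "a", time = t0 + tt,
                     acc_x = amp * sin(2 * pi * 0.5 * tt),
                     acc_y = 0, acc_z = 0)
  hs <- harmonize_daytime(sine)
  bound <- amp * (2 * pi * 0.5 / 12)^2 / 8
  for (i in seq_along(hs$epoch_start)) {
    rel <- as.numeric(hs$epoch_start[i]) - as.numeric(t0) + (0:24) / 10
    expect_lt(max(abs(hs$samples[i, , 1] - amp * sin(2 * pi * 0.5 * rel))),
              bound + 1e-9)
  }

  expect_error(harmonize_daytime(const[0, ]), "empty")
})

test_that("minute series uses ln(mean + 1e-6) and flags gaps explicitly", {
  t0 <- t_at("2012-08-01 18:00:00")
  b <- accel_bursts(rep("a", 3), t0 + c(0, 60, 180),
                    array(rnorm(225), c(3, 25, 3)))
  ser <- assemble_minute_series(b, vedba_means = c(1, 0, 2))
  expect_equal(nrow(ser), 4)  # spans the 120 s gap with an explicit row
  expect_equal(ser$log_vedba[1], log(1 + 1e-6))
  expect_lt(abs(ser$log_vedba[1]), 1e-5)     # ln(1) ~ 0
  expect_equal(ser$log_vedba[2], log(1e-6))  # zero-VeDBA floor
  expect_true(is.na(ser$log_vedba[3]))
  expect_error(assemble_minute_series(b, vedba_means = c(1, -1, 2)),
               "negative")
})

test_that("cumulative daytime VeDBA sums per-minute means", {
  t0 <- t_at("2012-08-01 09:00:00")
  tt <- seq(0, 600 - 1 / 12, by = 1 / 12)
  const <- data.frame(individual_id = "a", time = t0 + tt,
                      acc_x = 0, acc_y = 0, acc_z = 1)
  out <- cumulative_daytime_vedba(const)
  expect_equal(out$total, 0)
  expect_equal(out$n_minutes, 10)
  expect_equal(out$n_missing, 710)

  # oracle: total equals the brute-force per-minute tally
  set.seed(8)
  sig <- data.frame(individual_id = "a", time = t0 + tt,
                    acc_x = rnorm(length(tt)), acc_y = 0, acc_z = 1)
  out2 <- cumulative_daytime_vedba(sig)
  ved <- bf_vedba(cbind(sig$acc_x, sig$acc_y, sig$acc_z), 12, 0.5)
  minute <- floor(tt / 60)
  expect_equal(out2$total, sum(tapply(ved, minute, mean)),
               tolerance = 1e-10)
})

test_that("accelerometry CSV round-trips in both dialects", {
  cfg <- sim_config(n_individuals = 2, n_nights = 1, seed = 3)
  tm <- make_tree_map(cfg$n_trees, seed = 3)
  tr <- generate_group_truth(cfg, tm)
  b <- render_accel_bursts(tr, cfg)
  b <- b[seq_len(120)]

  for (dialect in c("packed", "long")) {
    path <- tempfile(fileext = ".csv")
    write_accel_csv(b, path, dialect = dialect)
    rb <- read_accel_records(path, dialect = dialect)
    expect_equal(length(rb), length(b))
    expect_equal(rb$individual_id, b$individual_id)
    expect_equal(as.numeric(rb$epoch_start), as.numeric(b$epoch_start))
    expect_equal(rb$samples, b$samples, tolerance = 1e-4)
    unlink(path)
  }

  # shuffled rows come back in time order
  path <- tempfile(fileext = ".csv")
  write_accel_csv(b, path, dialect = "packed")
  dt <- data.table::fread(path)
  data.table::fwrite(dt[sample(nrow(dt)), ], path)
  rb <- read_accel_records(path, dialect = "packed")
  expect_true(!is.unsorted(as.numeric(rb$epoch_start[
    rb$individual_id == rb$individual_id[1]])))

  # duplicated epoch row is rejected, naming individual and epoch
  data.table::fwrite(rbind(dt, dt[1, ]), path)
  expect_error(read_accel_records(path, dialect = "packed"),
               "duplicate.*ind_01")
  unlink(path)
})

test_that("round trip from rendered truth preserves burst counts", {
  cfg <- sim_config(n_individuals = 2, n_nights = 2, seed = 19,
                    missing_burst_prob = 0)
  tm <- make_tree_map(cfg$n_trees, seed = 19)
  tr <- generate_group_truth(cfg, tm)
  b <- render_accel_bursts(tr, cfg)
  expect_equal(length(b), 2 * 2 * 1440)
  ser <- assemble_minute_series(b)
  expect_equal(sum(!is.na(ser$log_vedba)), 2 * 2 * 1440)

  # missingness conservation: dropped bursts = missing epochs
  mis <- inject_missingness(b, 0.05, seed = 4)
  ser2 <- assemble_minute_series(mis$bursts)
  interior <- nrow(mis$dropped) -
    sum(!mis$dropped$epoch_start %in% ser2$time)
  expect_equal(sum(is.na(ser2$log_vedba)), interior)
})
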