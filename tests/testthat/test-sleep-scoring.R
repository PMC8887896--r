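test_that("threshold uses the linear-interpolation percentile times 1.125", {
  expect_equal(compute_threshold(rep(2, 1440)), 2.25)

  # percentile definition: Q10 of 1..100 is 10.9 by linear interpolation
  p <- scoring_params(min_valid_epochs = 50)
  expect_equal(compute_threshold(as.numeric(1:100), p), 12.2625)

  # scorability boundary: 1319 valid epochs is unscorable
  x <- rep(2, 1440); x[1:121] <- NA
  thr <- compute_threshold(x)
  expect_true(is.na(thr))
  expect_equal(attr(thr, "unscorable"), "insufficient_epochs")
  x2 <- rep(2, 1440); x2[1:120] <- NA
  expect_equal(as.numeric(compute_threshold(x2)), 2.25)

  # negative log VeDBA: the multiplier is applied literally, which
  # *lowers* the threshold below the percentile (regression-guarded)
  xn <- rep(-5, 1440)
  expect_equal(compute_threshold(xn), -5.625)
  expect_lt(compute_threshold(xn), stats::quantile(xn, 0.1))
})

test_that("rolling median matches a sort-based oracle", {
  expect_equal(rolling_median(rep(3, 20)), rep(3, 20))
  x <- c(5, 5, 5, 5, 50, 5, 5, 5, 5)
  expect_equal(rolling_median(x)[5], 5)

  set.seed(23)
  x <- rnorm(1000)
  x[sample(1000, 50)] <- NA
  expect_equal(rolling_median(x), bf_rolling_median(x))
})

test_that("sleep-period detection applies the block and merge rules", {
  thr <- 0.5
  mk <- function(spans, n = 300) {
    s <- rep(1, n)
    for (sp in spans) s[sp[1]:sp[2]] <- 0
    s
  }
  # no run of >= 30 below threshold: no sleep period
  expect_null(detect_spt_window(mk(list(c(10, 35))), thr))

  # 35-min and 60-min blocks, 40-min gap: merged into one 135-min period
  s <- mk(list(c(21, 55), c(96, 155)))
  spt <- detect_spt_window(s, thr)
  expect_equal(spt$onset_epoch, 21)
  expect_equal(spt$end_epoch, 155)
  expect_equal(spt$duration, 135)

  # 46-min gap exceeds the merge limit: the longer block wins
  s2 <- mk(list(c(21, 55), c(102, 161)))
  spt2 <- detect_spt_window(s2, thr)
  expect_equal(spt2$onset_epoch, 102)
  expect_equal(spt2$duration, 60)

  # tie on length: earliest onset wins
  s3 <- mk(list(c(21, 50), c(101, 130)))
  expect_equal(detect_spt_window(s3, thr)$onset_epoch, 21)
})

test_that("merge step is idempotent and order-independent", {
  # alternative merger: shortest gap first, iterated to fixed point
  alt_spt <- function(s, thr, min_block = 30, gap_max = 45) {
    below <- !is.na(s) & s < thr
    r <- rle(below)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    bl <- data.frame(start = starts[r$values], end = ends[r$values])
    bl <- bl[bl$end - bl$start + 1 >= min_block, ]
    if (!nrow(bl)) return(NULL)
    repeat {
      if (nrow(bl) < 2) break
      gaps <- bl$start[-1] - bl$end[-nrow(bl)] - 1
      if (min(gaps) > gap_max) break
      k <- which.min(gaps)
      bl$end[k] <- bl$end[k + 1]
      bl <- bl[-(k + 1), ]
    }
    len <- bl$end - bl$start + 1
    b <- which(len == max(len))[1]
    list(onset_epoch = bl$start[b], end_epoch = bl$end[b],
         duration = len[b])
  }
  set.seed(41)
  for (k in 1:200) {
    s <- as.numeric(runif(400) < 0.45)  # 0 = below-threshold activity
    got <- detect_spt_window(s, 0.5)
    want <- alt_spt(s, 0.5)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got[c("onset_epoch", "end_epoch", "duration")],
                   want[c("onset_epoch", "end_epoch", "duration")])
    }
  }
})

test_that("epoch classification enforces the 3-epoch run rule", {
  thr <- 1
  # below-threshold run of length 2 stays wake
  x <- c(2, 0, 0, 2, 2)
  expect_equal(classify_epochs(x, thr),
               c("wake", "wake", "wake", "wake", "wake"))

  # W B B B W B B: epochs 2-4 sleep, rest wake
  x2 <- c(2, 0, 0, 0, 2, 0, 0)
  expect_equal(classify_epochs(x2, thr),
               c("wake", "sleep", "sleep", "sleep", "wake", "wake",
                 "wake"))

  expect_equal(classify_epochs(rep(0, 5), thr), rep("sleep", 5))

  # missing epochs break runs and stay missing
  x3 <- c(0, 0, NA, 0, 0, 0)
  expect_equal(classify_epochs(x3, thr),
               c("wake", "wake", NA, "sleep", "sleep", "sleep"))
})

test_that("night metrics follow the stated definitions", {
  noon <- t_at("2012-08-01 12:00:00")
  # 600-min sleep period, all asleep
  labels <- rep("wake", 1440)
  labels[301:900] <- "sleep"
  spt <- list(onset_epoch = 301, end_epoch = 900, duration = 600)
  m <- compute_night_metrics(spt, labels, noon)
  expect_equal(m$tst_min, 600)
  expect_equal(m$efficiency, 1)
  expect_equal(m$fragmentation, 0)

  # 18 qualifying bouts with TST 540 -> fragmentation 2.0 bouts/hr
  lab2 <- rep("wake", 1440)
  blocks <- c()
  for (k in 1:18) blocks <- c(blocks, rep("sleep", 30), rep("wake", 2))
  lab2[301:(300 + length(blocks))] <- blocks
  spt2 <- list(onset_epoch = 301, end_epoch = 300 + length(blocks),
               duration = length(blocks))
  m2 <- compute_night_metrics(spt2, lab2, noon)
  expect_equal(m2$tst_min, 540)
  expect_equal(m2$n_wake_bouts, 18)
  expect_equal(m2$fragmentation, 2.0)

  # bout separation rule: S10 W2 S3 W1 S2 W3 S10 -> 2 bouts
  pat <- c(rep("sleep", 10), rep("wake", 2), rep("sleep", 3), "wake",
           rep("sleep", 2), rep("wake", 3), rep("sleep", 10))
  expect_equal(accsleep:::count_wake_bouts(pat), 2)
  expect_equal(bf_wake_bouts(pat), 2)
})

test_that("wake-bout counting matches the brute-force rule scan", {
  set.seed(57)
  for (k in 1:300) {
    lab <- rand_labels(120, p_sleep = runif(1, 0.5, 0.95), p_na = 0.03)
    expect_equal(accsleep:::count_wake_bouts(lab), bf_wake_bouts(lab))
  }
})

test_that("napping minutes respect the fixed 07:30-17:30 window", {
  d0 <- t_at("2012-08-01 00:00:00")
  mk_labels <- function(sleep_spans) {
    tt <- d0 + (0:1439) * 60
    lab <- rep("wake", 1440)
    for (sp in sleep_spans) lab[sp] <- "sleep"
    data.frame(time = tt, label = lab)
  }
  expect_equal(compute_nap_minutes(mk_labels(list()))$nap_min, 0)
  # 25-min nap at 13:00
  expect_equal(compute_nap_minutes(mk_labels(list(781:805)))$nap_min, 25)
  # run straddling the 17:30 boundary (17:20-17:40): 10 min counted
  expect_equal(compute_nap_minutes(mk_labels(list(1041:1060)))$nap_min, 10)
})

test_that("QC flags apply the 120-missing and 20-consecutive rules", {
  miss <- rep(FALSE, 1440)
  miss[seq(1, by = 12, length.out = 119)] <- TRUE
  qc <- apply_qc_filters(miss)
  expect_false(qc$missing_ge_total)
  expect_false(qc$consecutive_ge)

  miss[seq(2, by = 12, length.out = 1)] <- TRUE  # 120th missing burst
  qc2 <- apply_qc_filters(miss)
  expect_true(qc2$missing_ge_total)

  # 19-epoch gap plus 101 scattered: flag A but not B
  miss3 <- rep(FALSE, 1440)
  miss3[100:118] <- TRUE
  miss3[seq(200, by = 12, length.out = 101)] <- TRUE
  qc3 <- apply_qc_filters(miss3)
  expect_true(qc3$missing_ge_total)
  expect_false(qc3$consecutive_ge)
  expect_equal(qc3$n_missing, 120L)
  expect_equal(qc3$max_consecutive, 19L)
})

test_that("lowering the threshold never increases total sleep time", {
  set.seed(71)
  for (k in 1:50) {
    x <- rnorm(500)
    thr_hi <- stats::quantile(x, 0.5)
    thr_lo <- stats::quantile(x, 0.2)
    tst <- function(thr) {
      sum(classify_epochs(x, thr) == "sleep", na.rm = TRUE)
    }
    expect_lte(tst(thr_lo), tst(thr_hi))
  }
})

test_that("missing-epoch bridging recovers sleep periods across short gaps", {
  thr <- 0.5
  s <- rep(1, 300)
  s[51:200] <- 0
  s[60] <- NA  # dropped burst early in the sleep period
  spt <- detect_spt_window(s, thr)
  expect_equal(spt$onset_epoch, 51)
  expect_equal(spt$end_epoch, 200)
  # with bridging disabled the leading 9-min fragment is lost
  spt2 <- detect_spt_window(s, thr,
                            scoring_params(missing_bridge_blocks = FALSE))
  expect_equal(spt2$onset_epoch, 61)
})
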