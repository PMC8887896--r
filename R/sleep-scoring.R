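# Sleep-period detection and per-epoch sleep/wake classification from
# per-minute log VeDBA, with night-level metrics and QC filters.

#' Scoring parameters
#'
#' All tunable constants of the sleep-scoring stage, surfaced in one
#' place. Defaults follow the adapted human actigraphy heuristic: the
#' classification threshold is the 10th percentile (linear-interpolation
#' definition) of the day's log VeDBA times 1.125; candidate sleep blocks
#' are runs of at least 30 min of below-threshold rolling median (9-min
#' window); blocks separated by at most 45 min merge into sleep periods;
#' sleep epochs require at least 3 consecutive below-threshold minutes;
#' wake bouts inside the sleep period count when at least 2 min long and
#' separated by at least 3 sleep epochs; napping is scored 07:30-17:30;
#' days missing at least 120 bursts (or at least 20 consecutive bursts)
#' are flagged by QC.
#'
#' @param threshold_quantile Quantile of the day's log VeDBA used for the
#'   threshold (default 0.1).
#' @param threshold_multiplier Multiplier applied to that quantile
#'   (default 1.125).
#' @param median_window Rolling-median window in minutes (odd; default 9).
#' @param min_block Minimum sleep-block length in minutes (default 30).
#' @param merge_gap Maximum gap between blocks that still merges, minutes
#'   (default 45).
#' @param min_sleep_run Minimum consecutive below-threshold epochs for a
#'   sleep classification (default 3).
#' @param bout_min_duration Minimum wake-bout duration in minutes counted
#'   by the fragmentation metric (default 2).
#' @param bout_separation Minimum number of intervening sleep epochs for
#'   two wake runs to count as distinct bouts (default 3).
#' @param nap_window Clock window for napping minutes (default
#'   07:30-17:30).
#' @param min_valid_epochs Minimum non-missing epochs required to compute
#'   a threshold (default 1320 = 1440 - 120).
#' @param qc_missing_total Missing-burst count flagging a day (default
#'   120).
#' @param qc_missing_consecutive Consecutive missing-burst count flagging
#'   a day (default 20).
#' @param missing_bridge_blocks If `TRUE` (default), missing epochs
#'   flanked by below-threshold epochs are bridged during sleep-period
#'   block detection (they join and count toward the run), mirroring the
#'   short-gap imputation of canonical actigraphy toolchains; long gaps
#'   are guarded by the consecutive-missing QC rule. If `FALSE`, any
#'   missing epoch breaks a block. Epoch *classification* always treats
#'   missing epochs as breaking runs.
#' @return A named list of class `scoring_params`.
#' @export
scoring_params <- function(threshold_quantile = 0.1,
                           threshold_multiplier = 1.125,
                           median_window = 9,
                           min_block = 30,
                           merge_gap = 45,
                           min_sleep_run = 3,
                           bout_min_duration = 2,
                           bout_separation = 3,
                           nap_window = c("07:30", "17:30"),
                           min_valid_epochs = 1320,
                           qc_missing_total = 120,
                           qc_missing_consecutive = 20,
                           missing_bridge_blocks = TRUE) {
  p <- as.list(environment())
  stopifnot(p$median_window %% 2 == 1)
  class(p) <- "scoring_params"
  p
}

#' Classification threshold for one noon-to-noon day
#'
#' `threshold = Q(q) * multiplier`, where `Q(q)` is the
#' linear-interpolation (type 7) quantile of the day's non-missing log
#' VeDBA. Requires at least `min_valid_epochs` non-missing epochs;
#' otherwise the day is unscorable and `NA` is returned with an
#' `"unscorable"` attribute.
#'
#' Note the multiplier is only a *raised* threshold for positive log
#' VeDBA; applied to a negative percentile it lowers the threshold. The
#' formula is applied literally in either case.
#'
#' @param log_vedba Numeric vector of the day's 1440 per-minute log VeDBA
#'   values (`NA` = missing).
#' @param params A [scoring_params()].
#' @return The threshold (log-VeDBA units), or `NA` if unscorable.
#' @export
#' @examples
#' compute_threshold(rep(2, 1440))  # degenerate day: 1.125 * 2
compute_threshold <- function(log_vedba, params = scoring_params()) {
  ok <- sum(!is.na(log_vedba))
  if (ok < params$min_valid_epochs) {
    return(structure(NA_real_, unscorable = "insufficient_epochs"))
  }
  unname(stats::quantile(log_vedba, params$threshold_quantile,
                         na.rm = TRUE, type = 7)) *
    params$threshold_multiplier
}

#' Rolling median of a log-VeDBA series
#'
#' Centered rolling median; at the series edges the window shrinks
#' symmetrically to the available epochs; missing values are excluded
#' from the window, and the output is missing wherever the input epoch is
#' missing.
#'
#' @param x Numeric vector (`NA` = missing).
#' @param window Odd window length in epochs (default 9).
#' @return Numeric vector of the same length.
#' @export
rolling_median <- function(x, window = 9) {
  stopifnot(window %% 2 == 1)
  h <- (window - 1) %/% 2
  n <- length(x)
  out <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    if (is.na(x[j])) next
    he <- min(h, j - 1L, n - j)
    v <- x[(j - he):(j + he)]
    out[j] <- stats::median(v, na.rm = TRUE)
  }
  out
}

#' Detect the sleep-period (SPT) window of a noon-to-noon day
#'
#' (1) Finds maximal runs of at least `min_block` consecutive epochs with
#' rolling-median log VeDBA strictly below the threshold (interior
#' missing epochs are bridged when `missing_bridge_blocks` is set,
#' otherwise they break runs); (2) merges blocks whose gap is at most
#' `merge_gap`
#' minutes, iterating to a fixed point; (3) returns the longest merged
#' period, ties broken by earliest onset. Absence of any qualifying block
#' is a valid outcome (`NULL`).
#'
#' @param smoothed Rolling-median log VeDBA for the day (length 1440).
#' @param threshold The day's classification threshold.
#' @param params A [scoring_params()].
#' @return `NULL`, or a list with `onset_epoch`, `end_epoch` (1-based
#'   epoch indices into the day, inclusive) and `duration` (minutes).
#' @export
detect_spt_window <- function(smoothed, threshold,
                              params = scoring_params()) {
  if (is.na(threshold)) return(NULL)
  below <- !is.na(smoothed) & smoothed < threshold
  if (isTRUE(params$missing_bridge_blocks)) {
    # bridge missing epochs whose nearest observed neighbours on both
    # sides are below threshold (interior gaps of a sleep block)
    na_pos <- which(is.na(smoothed))
    if (length(na_pos)) {
      obs <- which(!is.na(smoothed))
      if (length(obs)) {
        prev_obs <- findInterval(na_pos, obs)
        next_obs <- prev_obs + 1L
        okp <- prev_obs >= 1 & prev_obs <= length(obs)
        okn <- next_obs >= 1 & next_obs <= length(obs)
        bridge <- okp & okn
        bridge[bridge] <- below[obs[prev_obs[bridge]]] &
          below[obs[next_obs[bridge]]]
        below[na_pos[bridge]] <- TRUE
      }
    }
  }
  runs <- true_runs(below)
  blocks <- runs[runs$length >= params$min_block, , drop = FALSE]
  if (nrow(blocks) == 0) return(NULL)
  # adjacent blocks with gap <= merge_gap coalesce; gaps between surviving
  # groups exceed merge_gap, so one grouping pass reaches the fixed point
  gap_prev <- c(Inf, blocks$start[-1] - blocks$end[-nrow(blocks)] - 1L)
  grp <- cumsum(gap_prev > params$merge_gap)
  merged <- data.frame(
    start = tapply(blocks$start, grp, min),
    end = tapply(blocks$end, grp, max)
  )
  merged$length <- merged$end - merged$start + 1L
  best <- which(merged$length == max(merged$length))[1]  # earliest tie
  list(onset_epoch = as.integer(merged$start[best]),
       end_epoch = as.integer(merged$end[best]),
       duration = as.integer(merged$length[best]))
}

#' Classify every epoch of a day as sleep, wake, or missing
#'
#' Epochs belong to runs of raw (unsmoothed) log VeDBA strictly below the
#' threshold; runs of at least `min_sleep_run` epochs are labelled sleep,
#' all other non-missing epochs wake. Missing epochs break runs and stay
#' missing. Applies to the whole noon-to-noon day, inside and outside the
#' sleep period (daytime sleep runs are naps).
#'
#' @param log_vedba Raw per-minute log VeDBA (length 1440, `NA` missing).
#' @param threshold The day's classification threshold.
#' @param params A [scoring_params()].
#' @return Character vector `"sleep"`/`"wake"`/`NA` per epoch.
#' @export
classify_epochs <- function(log_vedba, threshold,
                            params = scoring_params()) {
  n <- length(log_vedba)
  out <- rep(NA_character_, n)
  if (is.na(threshold)) return(out)
  out[!is.na(log_vedba)] <- "wake"
  below <- !is.na(log_vedba) & log_vedba < threshold
  runs <- true_runs(below)
  runs <- runs[runs$length >= params$min_sleep_run, , drop = FALSE]
  for (r in seq_len(nrow(runs))) {
    out[runs$start[r]:runs$end[r]] <- "sleep"
  }
  out
}

# Count qualifying wake bouts inside the SPT window. Wake runs separated
# by fewer than `bout_separation` sleep epochs coalesce into one bout;
# a bout counts when its summed wake length reaches `bout_min_duration`.
count_wake_bouts <- function(labels_spt, params = scoring_params()) {
  wruns <- true_runs(labels_spt == "wake")
  if (nrow(wruns) == 0) return(0L)
  n_bouts <- 0L
  cur_len <- wruns$length[1]
  if (nrow(wruns) > 1) {
    for (r in 2:nrow(wruns)) {
      sep <- sum(labels_spt[(wruns$end[r - 1] + 1):(wruns$start[r] - 1)] ==
                   "sleep", na.rm = TRUE)
      if (sep < params$bout_separation) {
        cur_len <- cur_len + wruns$length[r]
      } else {
        if (cur_len >= params$bout_min_duration) n_bouts <- n_bouts + 1L
        cur_len <- wruns$length[r]
      }
    }
  }
  if (cur_len >= params$bout_min_duration) n_bouts <- n_bouts + 1L
  n_bouts
}

#' Night-level sleep metrics for one scored day
#'
#' Total sleep time is the number of sleep epochs inside the sleep
#' period; efficiency is total sleep time over sleep-period duration;
#' fragmentation is the number of qualifying wake bouts (at least 2 min,
#' separated by at least 3 sleep epochs) per hour of sleep. Onset and
#' awakening are also expressed relative to astronomical twilight when
#' twilight times are supplied.
#'
#' @param spt A [detect_spt_window()] result (non-NULL).
#' @param labels [classify_epochs()] output for the day.
#' @param day_noon POSIXct of the day's starting noon.
#' @param twilight Optional list with `evening_astro_end` (that evening)
#'   and `morning_astro_start` (next morning), e.g. from
#'   [compute_twilight()].
#' @param params A [scoring_params()].
#' @return One-row data frame of night metrics.
#' @export
compute_night_metrics <- function(spt, labels, day_noon, twilight = NULL,
                                  params = scoring_params()) {
  stopifnot(!is.null(spt))
  lab_spt <- labels[spt$onset_epoch:spt$end_epoch]
  tst <- sum(lab_spt == "sleep", na.rm = TRUE)
  n_bouts <- count_wake_bouts(lab_spt, params)
  onset_time <- day_noon + (spt$onset_epoch - 1) * 60
  waking_time <- day_noon + spt$end_epoch * 60  # exclusive end of SPT
  data.frame(
    onset_time = onset_time,
    waking_time = waking_time,
    spt_duration_min = spt$duration,
    tst_min = tst,
    efficiency = tst / spt$duration,
    n_wake_bouts = n_bouts,
    fragmentation = if (tst > 0) n_bouts / (tst / 60) else NA_real_,
    onset_rel_twilight_min = if (!is.null(twilight)) {
      as.numeric(difftime(onset_time, twilight$evening_astro_end,
                          units = "mins"))
    } else NA_real_,
    awakening_rel_twilight_min = if (!is.null(twilight)) {
      as.numeric(difftime(waking_time, twilight$morning_astro_start,
                          units = "mins"))
    } else NA_real_
  )
}

#' Napping minutes within the fixed daytime window
#'
#' Counts sleep-classified epochs between 07:30 and 17:30 (by default) on
#' each calendar date covered by a label series.
#'
#' @param labels Data frame with columns `time` (POSIXct) and `label`.
#' @param params A [scoring_params()].
#' @return Data frame `date`, `nap_min`.
#' @export
compute_nap_minutes <- function(labels, params = scoring_params()) {
  mod <- minute_of_day(labels$time)
  w0 <- hm_to_min(params$nap_window[1]); w1 <- hm_to_min(params$nap_window[2])
  in_win <- mod >= w0 & mod < w1
  date <- as.Date(format(labels$time, tz = ACC_TZ))
  keep <- in_win
  agg <- tapply(labels$label[keep] == "sleep", date[keep],
                function(z) sum(z, na.rm = TRUE))
  data.frame(date = as.Date(names(agg)), nap_min = as.integer(agg),
             row.names = NULL)
}

#' Quality-control flags for one noon-to-noon day
#'
#' Flag `missing_ge_total`: at least `qc_missing_total` missing bursts in
#' the day, invalidating all sleep metrics including napping. Flag
#' `consecutive_ge`: at least `qc_missing_consecutive` consecutive missing
#' bursts, invalidating sleep-period-derived metrics but not napping.
#'
#' @param missing Logical vector (length 1440), TRUE where the burst is
#'   missing.
#' @param params A [scoring_params()].
#' @return List `missing_ge_total`, `consecutive_ge`, `n_missing`,
#'   `max_consecutive`.
#' @export
apply_qc_filters <- function(missing, params = scoring_params()) {
  n_missing <- sum(missing)
  runs <- true_runs(missing)
  max_consec <- if (nrow(runs)) max(runs$length) else 0L
  list(missing_ge_total = n_missing >= params$qc_missing_total,
       consecutive_ge = max_consec >= params$qc_missing_consecutive,
       n_missing = as.integer(n_missing),
       max_consecutive = as.integer(max_consec))
}

#' Score sleep for every individual and noon-to-noon day of a series
#'
#' Runs the full scoring stack - per-day threshold, rolling median,
#' sleep-period detection, epoch classification, night metrics, napping,
#' QC - over a per-minute log-VeDBA series.
#'
#' @param series A [assemble_minute_series()] data frame (or any data
#'   frame with `individual_id`, `time`, `log_vedba` at 1-min spacing).
#' @param site Optional `c(lon, lat)` for twilight-relative onset/waking.
#' @param params A [scoring_params()].
#' @return List with `nights` (one row per individual-day: metrics, QC
#'   flags, threshold, exclusion reason), `labels` (one row per epoch:
#'   `individual_id`, `night`, `time`, `label`), and `naps` (per
#'   individual and calendar date).
#' @export
score_sleep <- function(series, site = NULL, params = scoring_params()) {
  nights_out <- list(); labels_out <- list(); naps_out <- list()
  twi_cache <- new.env()
  get_twilight <- function(date) {
    if (is.null(site)) return(NULL)
    key <- format(date)
    if (is.null(twi_cache[[key]])) {
      ev <- compute_twilight(date, site[1], site[2])
      mo <- compute_twilight(date + 1, site[1], site[2])
      twi_cache[[key]] <- list(evening_astro_end = ev$evening_astro_end,
                               morning_astro_start = mo$morning_astro_start)
    }
    twi_cache[[key]]
  }
  # global night numbering: night 1 starts at the first noon boundary at
  # or before the earliest observation in the whole series
  g_first_date <- as.Date(format(min(series$time), tz = ACC_TZ))
  g_noon1 <- as.numeric(local_midnight(g_first_date)) + 12 * 3600
  if (g_noon1 > as.numeric(min(series$time))) g_noon1 <- g_noon1 - 86400
  for (id in unique(series$individual_id)) {
    s <- series[series$individual_id == id, ]
    tt <- as.numeric(s$time)
    # candidate days: noon-to-noon windows overlapping the series span by
    # at least the scorability minimum (shorter overlaps could never pass)
    noons <- seq(g_noon1, max(tt), by = 86400)
    overlap <- (pmin(max(tt), noons + 1439 * 60) -
                  pmax(min(tt), noons)) / 60 + 1
    noons <- noons[overlap >= params$min_valid_epochs]
    for (noon in noons) {
      night_idx <- as.integer((noon - g_noon1) / 86400) + 1L
      day_noon <- as.POSIXct(noon, origin = "1970-01-01", tz = ACC_TZ)
      idx <- match(noon + (0:1439) * 60, tt)
      lv <- rep(NA_real_, 1440)
      lv[!is.na(idx)] <- s$log_vedba[idx[!is.na(idx)]]
      qc <- apply_qc_filters(is.na(lv), params)
      thr <- compute_threshold(lv, params)
      labels <- classify_epochs(lv, thr, params)
      spt <- if (!is.na(thr)) {
        detect_spt_window(rolling_median(lv, params$median_window), thr,
                          params)
      } else NULL
      exclusion <- if (!is.na(attr(thr, "unscorable") %||% NA)) {
        "insufficient_epochs"
      } else if (qc$missing_ge_total) {
        "missing_ge_total"
      } else if (qc$consecutive_ge) {
        "consecutive_missing"
      } else if (is.null(spt)) {
        "no_sleep_period"
      } else {
        "none"
      }
      met <- if (!is.null(spt)) {
        compute_night_metrics(spt, labels, day_noon,
                              get_twilight(as.Date(format(day_noon,
                                                          tz = ACC_TZ))),
                              params)
      } else {
        data.frame(onset_time = as.POSIXct(NA), waking_time = as.POSIXct(NA),
                   spt_duration_min = NA_integer_, tst_min = NA_integer_,
                   efficiency = NA_real_, n_wake_bouts = NA_integer_,
                   fragmentation = NA_real_,
                   onset_rel_twilight_min = NA_real_,
                   awakening_rel_twilight_min = NA_real_)
      }
      nights_out[[length(nights_out) + 1L]] <- cbind(
        data.frame(individual_id = id, night = night_idx,
                   day_date = as.Date(format(day_noon, tz = ACC_TZ)),
                   threshold = as.numeric(thr)),
        met,
        data.frame(n_missing = qc$n_missing,
                   max_consecutive_missing = qc$max_consecutive,
                   qc_missing_ge_total = qc$missing_ge_total,
                   qc_consecutive_ge = qc$consecutive_ge,
                   exclusion_reason = exclusion)
      )
      labels_out[[length(labels_out) + 1L]] <- data.frame(
        individual_id = id, night = night_idx,
        time = day_noon + (0:1439) * 60,
        label = labels
      )
    }
  }
  nights <- do.call(rbind, nights_out)
  labels <- do.call(rbind, labels_out)
  naps <- do.call(rbind, lapply(unique(labels$individual_id), function(id) {
    li <- labels[labels$individual_id == id, ]
    # napping is kept on days flagged only for consecutive gaps, dropped
    # on days missing too many bursts overall
    flagged <- nights$day_date[nights$individual_id == id &
                                 nights$qc_missing_ge_total]
    bad_dates <- unique(c(flagged, flagged + 1))  # both calendar dates
    nm <- compute_nap_minutes(li, params)
    nm$individual_id <- id
    nm[!(nm$date %in% bad_dates), c("individual_id", "date", "nap_min")]
  }))
  list(nights = nights, labels = labels, naps = naps)
}
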