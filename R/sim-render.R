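# Render ground truth into sensor records (accelerometry and GPS).

# Deterministic triaxial base waveform for rendered bursts: a mix of
# sinusoids per axis, evaluated at time t (seconds). The rendered burst is
# gravity + c * pattern; because the VeDBA computation is linear in the
# dynamic component, the burst-mean VeDBA scales exactly with c, letting
# the renderer hit a target log VeDBA exactly.
burst_pattern <- function(t) {
  cbind(sin(2 * pi * 1.1 * t),
        sin(2 * pi * 1.7 * t + 1),
        sin(2 * pi * 2.3 * t + 2))
}

GRAVITY_COUNTS <- c(0, 0, 2000)  # collar at rest reads ~2000 counts on z

# burst-mean VeDBA of the unit pattern under the pipeline's own VeDBA
# definition (rate Hz, k samples, 0.7 s window)
pattern_mean_vedba <- function(rate = 10, k = 25) {
  t <- (seq_len(k) - 1) / rate
  p <- burst_pattern(t)
  b <- accel_bursts("pattern",
                    as.POSIXct("2000-01-01 00:00:00", tz = ACC_TZ),
                    array(p, c(1, k, 3)), rate = rate)
  compute_vedba(b)$mean
}

state_emission <- function(config) {
  list(
    mean = c(config$sleep_logvedba_mean, config$restingwake_logvedba_mean,
             config$day_logvedba_mean),
    sd = c(config$sleep_logvedba_sd, config$restingwake_logvedba_sd,
           config$day_logvedba_sd)
  )
}

#' Render ground-truth states as minute-aligned accelerometry bursts
#'
#' Emits, for every epoch, one 2.5 s burst of 10 Hz triaxial samples whose
#' burst-mean log VeDBA (as later computed by [compute_vedba()]) is
#' Gaussian around the latent state's emission mean. Samples are in raw
#' sensor-count units with a constant gravity offset on the z axis.
#'
#' @param truth A [generate_group_truth()] result.
#' @param config The [sim_config()] used to generate `truth`.
#' @param individuals Optional character vector restricting rendering to a
#'   subset of individuals (each individual's stream is seeded
#'   independently, so per-individual rendering matches a full rendering).
#' @param epochs `"all"` renders bursts for all 1440 epochs/day; `"night"`
#'   renders only the 18:00-06:00 burst schedule (daytime then comes from
#'   a continuous stream, see [render_day_continuous()]).
#' @return An [accel_bursts()] object sorted by individual and time.
#' @export
render_accel_bursts <- function(truth, config, individuals = NULL,
                                epochs = c("all", "night")) {
  epochs <- match.arg(epochs)
  individuals <- individuals %||% truth$individuals
  k <- 25L; rate <- 10
  t_rel <- (seq_len(k) - 1) / rate
  pat <- burst_pattern(t_rel)
  mv <- pattern_mean_vedba(rate, k)
  em <- state_emission(config)
  n_nights <- dim(truth$state)[3]
  ep_keep <- if (epochs == "all") seq_len(1440L) else 361:1080
  noons <- as.numeric(local_midnight(config$start_date +
                                       seq_len(n_nights) - 1)) + 12 * 3600
  out <- vector("list", length(individuals))
  for (ii in seq_along(individuals)) {
    id <- individuals[ii]
    st <- truth$state[id, ep_keep, , drop = FALSE]
    dim(st) <- c(length(ep_keep), n_nights)
    v <- with_seed(derive_seed(config$seed, paste0("render:", id)), {
      matrix(stats::rnorm(length(st), em$mean[st], em$sd[st]),
             nrow(st), ncol(st))
    })
    cc <- exp(as.vector(v)) / mv
    n <- length(cc)
    samples <- array(0, c(n, k, 3))
    for (ax in 1:3) {
      samples[, , ax] <- GRAVITY_COUNTS[ax] + cc %o% pat[, ax]
    }
    tt <- as.POSIXct(rep(noons, each = length(ep_keep)) +
                       (rep(ep_keep, n_nights) - 1) * 60,
                     origin = "1970-01-01", tz = ACC_TZ)
    out[[ii]] <- list(id = rep(id, n), tt = tt, samples = samples)
  }
  all_samples <- array(0, c(sum(vapply(out, function(o) length(o$id),
                                       integer(1))), k, 3))
  pos <- 0L
  for (o in out) {
    idx <- pos + seq_along(o$id)
    all_samples[idx, , ] <- o$samples
    pos <- pos + length(o$id)
  }
  accel_bursts(unlist(lapply(out, `[[`, "id")),
               as.POSIXct(unlist(lapply(out, function(o) as.numeric(o$tt))),
                          origin = "1970-01-01", tz = ACC_TZ),
               all_samples, rate = rate)
}

#' Render a continuous daytime accelerometry stream
#'
#' Produces the 06:00-18:00 continuous 12 Hz stream for one individual and
#' one calendar day, with the same per-minute emission model as the burst
#' renderer.
#'
#' @param truth A [generate_group_truth()] result.
#' @param config The matching [sim_config()].
#' @param individual Individual id.
#' @param day Calendar day index (1 = `config$start_date`).
#' @param rate Stream rate in Hz (default 12).
#' @return Data frame `individual_id`, `time`, `acc_x`, `acc_y`, `acc_z`.
#' @export
render_day_continuous <- function(truth, config, individual, day,
                                  rate = 12) {
  em <- state_emission(config)
  n_nights <- dim(truth$state)[3]
  mv <- pattern_mean_vedba()  # target the burst-schedule VeDBA scale
  minutes <- 360:1079  # 06:00 .. 17:59
  # state of each minute: morning belongs to night day-1, afternoon to day
  get_state <- function(m) {
    if (m < 720) {
      n <- day - 1L
      if (n < 1) return(ST_ACTIVE)
    } else {
      n <- day
      if (n > n_nights) return(ST_ACTIVE)
    }
    truth$state[individual, epoch_of_minute(m), n]
  }
  st <- vapply(minutes, get_state, integer(1))
  v <- with_seed(derive_seed(config$seed,
                             paste0("day:", individual, ":", day)), {
    stats::rnorm(length(st), em$mean[st], em$sd[st])
  })
  cc <- exp(v) / mv
  per_min <- as.integer(60 * rate)
  t0 <- as.numeric(local_midnight(config$start_date + day - 1))
  t_rel <- (seq_len(per_min) - 1) / rate
  n_min <- length(minutes)
  tt <- rep(t0 + minutes * 60, each = per_min) + rep(t_rel, n_min)
  pat <- burst_pattern(tt - t0)
  c_all <- rep(cc, each = per_min)
  data.frame(
    individual_id = individual,
    time = as.POSIXct(tt, origin = "1970-01-01", tz = ACC_TZ),
    acc_x = GRAVITY_COUNTS[1] + c_all * pat[, 1],
    acc_y = GRAVITY_COUNTS[2] + c_all * pat[, 2],
    acc_z = GRAVITY_COUNTS[3] + c_all * pat[, 3]
  )
}

#' Render GPS fixes around sleep trees (plus an optional day track)
#'
#' For each individual-night, emits pre-dawn fixes jittered around the
#' centroid of the true sleep tree (so the downstream median-location rule
#' recovers the tree), and optionally a daytime loop track of configurable
#' length used by the travel-distance computation.
#'
#' @param truth A [generate_group_truth()] result.
#' @param config The matching [sim_config()].
#' @param n_fixes Pre-dawn fixes per individual-night (default 12, all
#'   before 06:15).
#' @param fix_jitter GPS noise sd in meters (default 2).
#' @param day_track If `TRUE`, also render a daytime loop track.
#' @param day_track_length Nominal loop length in meters.
#' @param day_track_interval Seconds between day-track fixes.
#' @return Data frame `individual_id`, `timestamp` (POSIXct), `lon`,
#'   `lat`, sorted by individual then time.
#' @export
render_gps_fixes <- function(truth, config, n_fixes = 12, fix_jitter = 2,
                             day_track = FALSE, day_track_length = 3000,
                             day_track_interval = 10) {
  tm <- truth$tree_map
  n_nights <- dim(truth$state)[3]
  rows <- list()
  with_seed(derive_seed(config$seed, "gps"), {
    for (i in seq_along(truth$individuals)) {
      id <- truth$individuals[i]
      for (n in seq_len(n_nights)) {
        ctr <- tm$centroids[truth$tree[i, n], ]
        # fixes on the morning ending night n: 05:40 onwards, 30 s apart
        t0 <- as.numeric(local_midnight(config$start_date + n)) +
          5 * 3600 + 40 * 60
        tt <- t0 + (seq_len(n_fixes) - 1) * 30
        x <- ctr[1] + stats::rnorm(n_fixes, 0, fix_jitter)
        y <- ctr[2] + stats::rnorm(n_fixes, 0, fix_jitter)
        ll <- local_unproject(x, y, tm$site_lon, tm$site_lat)
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = id, timestamp = tt, lon = ll$lon, lat = ll$lat)
        if (day_track && n <= n_nights) {
          # loop walk on the day following the morning fixes
          r <- day_track_length / (2 * pi)
          td0 <- as.numeric(local_midnight(config$start_date + n)) +
            7 * 3600 + 15 * 60
          td1 <- as.numeric(local_midnight(config$start_date + n)) +
            17 * 3600 + 10 * 60
          tt_d <- seq(td0, td1, by = day_track_interval)
          th <- seq(0, 2 * pi, length.out = length(tt_d))
          # loop passes through the sleep site (circle centred at (-r, 0))
          xd <- r * cos(th) - r + stats::rnorm(length(th), 0, fix_jitter)
          yd <- r * sin(th) + stats::rnorm(length(th), 0, fix_jitter)
          lld <- local_unproject(xd, yd, tm$site_lon, tm$site_lat)
          rows[[length(rows) + 1L]] <- data.frame(
            individual_id = id, timestamp = tt_d,
            lon = lld$lon, lat = lld$lat)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$individual_id, out$timestamp), ]
  out$timestamp <- as.POSIXct(out$timestamp, origin = "1970-01-01",
                              tz = ACC_TZ)
  rownames(out) <- NULL
  out
}

#' Drop accelerometry bursts to emulate sensor dropout
#'
#' Removes bursts independently with probability `missing_burst_prob` and
#' optionally inserts specified consecutive gaps, returning both the
#' thinned record set and the provenance of dropped epochs.
#'
#' @param bursts An [accel_bursts()] object (sorted).
#' @param missing_burst_prob Per-burst drop probability in \[0, 1\].
#' @param consecutive_runs Optional data frame with columns
#'   `individual_id`, `start` (POSIXct), `length` (minutes) of gaps to
#'   force.
#' @param seed Integer seed.
#' @return List with `bursts` (thinned) and `dropped` (data frame
#'   `individual_id`, `epoch_start`, `reason`).
#' @export
inject_missingness <- function(bursts, missing_burst_prob,
                               consecutive_runs = NULL, seed = 1L) {
  if (is.na(missing_burst_prob) || missing_burst_prob < 0 ||
      missing_burst_prob > 1) {
    stop("missing_burst_prob must be in [0, 1]", call. = FALSE)
  }
  n <- length(bursts$individual_id)
  drop <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  if (missing_burst_prob > 0) {
    iid <- with_seed(seed, stats::runif(n) < missing_burst_prob)
    drop <- drop | iid
    reason[iid] <- "iid"
  }
  if (!is.null(consecutive_runs) && nrow(consecutive_runs)) {
    for (r in seq_len(nrow(consecutive_runs))) {
      t0 <- as.numeric(consecutive_runs$start[r])
      tt <- t0 + (seq_len(consecutive_runs$length[r]) - 1) * 60
      hit <- bursts$individual_id == consecutive_runs$individual_id[r] &
        as.numeric(bursts$epoch_start) %in% tt
      drop <- drop | hit
      reason[hit] <- "run"
    }
  }
  dropped <- data.frame(
    individual_id = bursts$individual_id[drop],
    epoch_start = bursts$epoch_start[drop],
    reason = reason[drop]
  )
  list(bursts = bursts[!drop], dropped = dropped)
}

#' Write a complete synthetic dataset to disk
#'
#' Renders and writes every file the analysis pipeline ingests:
#' accelerometry CSV (packed burst dialect, with missingness applied), GPS
#' CSV, tree-crown GeoJSON, ground-truth epoch and night tables, and the
#' generator configuration.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param day_track Render daytime GPS loop tracks (default FALSE; the
#'   night fixes alone support sleep-location inference).
#' @return Invisibly, a named list of written paths plus the `truth`
#'   object.
#' @export
simulate_dataset <- function(config, dir, day_track = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tm <- make_tree_map(config$n_trees,
                      site_center = c(config$site_lon, config$site_lat),
                      seed = derive_seed(config$seed, "trees"))
  truth <- generate_group_truth(config, tm)
  bursts <- render_accel_bursts(truth, config)
  mis <- inject_missingness(bursts, config$missing_burst_prob,
                            seed = derive_seed(config$seed, "missing"))
  gps <- render_gps_fixes(truth, config, day_track = day_track)
  paths <- list(
    accel = file.path(dir, "accel.csv"),
    gps = file.path(dir, "gps.csv"),
    trees = file.path(dir, "trees.geojson"),
    truth_epochs = file.path(dir, "truth_epochs.csv"),
    truth_nights = file.path(dir, "truth_nights.csv"),
    config = file.path(dir, "sim_config.yaml")
  )
  write_accel_csv(mis$bursts, paths$accel, dialect = "packed")
  gps_out <- data.frame(
    individual_id = gps$individual_id,
    timestamp = format(gps$timestamp, "%Y-%m-%dT%H:%M:%S", tz = ACC_TZ),
    lon = gps$lon, lat = gps$lat)
  data.table::fwrite(gps_out, paths$gps)
  write_tree_geojson(tm, paths$trees)
  n_nights <- dim(truth$state)[3]
  te <- data.table::data.table(
    individual_id = rep(truth$individuals, times = 1440 * n_nights),
    night = rep(seq_len(n_nights),
                each = length(truth$individuals) * 1440),
    epoch = rep(rep(seq_len(1440), each = length(truth$individuals)),
                times = n_nights),
    state = c("sleep", "resting_wake", "active_wake")[as.vector(truth$state)]
  )
  data.table::fwrite(te, paths$truth_epochs)
  data.table::fwrite(truth_nights(truth), paths$truth_nights)
  cfg_out <- unclass(config)
  cfg_out$start_date <- format(cfg_out$start_date)
  yaml::write_yaml(cfg_out, paths$config)
  invisible(c(paths, list(truth = truth)))
}
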