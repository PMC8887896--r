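# Accelerometry containers, VeDBA computation, and burst/stream ingest.

#' Construct an accelerometry burst set
#'
#' A compact container for minute-aligned triaxial bursts: parallel vectors
#' of individual id and epoch start time plus a samples array
#' (bursts x samples x 3 axes). Bursts are stored sorted by individual,
#' then time.
#'
#' @param individual_id Character vector, one per burst.
#' @param epoch_start POSIXct vector of burst (= minute epoch) start times.
#' @param samples Numeric array `n x k x 3` of acceleration samples.
#' @param rate Sampling rate within the burst (Hz).
#' @return An `accel_bursts` object.
#' @export
accel_bursts <- function(individual_id, epoch_start, samples, rate = 10) {
  n <- length(individual_id)
  stopifnot(length(epoch_start) == n, dim(samples)[1] == n,
            dim(samples)[3] == 3, rate > 0)
  if (any(!is.finite(samples))) {
    stop("burst samples must be finite", call. = FALSE)
  }
  ord <- order(individual_id, epoch_start)
  dup <- duplicated(data.frame(individual_id, epoch_start)[ord, ])
  if (any(dup)) {
    k <- ord[which(dup)[1]]
    stop(sprintf("duplicate burst for individual '%s' at epoch %s",
                 individual_id[k],
                 format(epoch_start[k], tz = ACC_TZ)), call. = FALSE)
  }
  structure(
    list(individual_id = individual_id[ord],
         epoch_start = epoch_start[ord],
         samples = samples[ord, , , drop = FALSE],
         rate = rate),
    class = "accel_bursts"
  )
}

#' @export
print.accel_bursts <- function(x, ...) {
  cat("<accel_bursts>", length(x$individual_id), "bursts,",
      dim(x$samples)[2], "samples/burst at", x$rate, "Hz;",
      length(unique(x$individual_id)), "individuals\n")
  invisible(x)
}

#' @export
length.accel_bursts <- function(x) length(x$individual_id)

#' Subset an accelerometry burst set
#' @param x An `accel_bursts`.
#' @param i Index vector of bursts to keep.
#' @param ... Unused.
#' @export
`[.accel_bursts` <- function(x, i, ...) {
  structure(
    list(individual_id = x$individual_id[i],
         epoch_start = x$epoch_start[i],
         samples = x$samples[i, , , drop = FALSE],
         rate = x$rate),
    class = "accel_bursts"
  )
}

# Centered running mean along rows of matrix M (n bursts x k samples),
# half-width h, truncated at the edges. Row-wise cumulative sums via a
# single triangular matrix product (k is small).
running_mean_rows <- function(M, h) {
  k <- ncol(M)
  U <- matrix(0, k, k)
  U[upper.tri(U, diag = TRUE)] <- 1
  cs <- cbind(0, M %*% U)
  lo <- pmax(seq_len(k) - h, 1L)
  hi <- pmin(seq_len(k) + h, k)
  out <- matrix(0, nrow(M), k)
  for (j in seq_len(k)) {
    out[, j] <- (cs[, hi[j] + 1L] - cs[, lo[j]]) / (hi[j] - lo[j] + 1L)
  }
  out
}

# Centered running mean of a long vector, half-width h, edge-truncated.
running_mean_vec <- function(x, h) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Compute per-sample and burst-mean VeDBA
#'
#' The static (gravitational) component of each axis is estimated by a
#' centered running mean over `smoothing_window` seconds (window truncated
#' at burst edges); the dynamic component is the raw signal minus the
#' static estimate, and VeDBA is the Euclidean norm of the three dynamic
#' components at each sample. The burst-level summary is the mean over all
#' samples of the burst.
#'
#' @param bursts An [accel_bursts()] object.
#' @param smoothing_window Static-estimation window in seconds (default
#'   0.7). The symmetric window half-width is
#'   `floor(rate * smoothing_window / 2)` samples (7 samples at 10 Hz).
#' @return List with `per_sample` (matrix bursts x samples) and `mean`
#'   (numeric vector, one burst-mean VeDBA per burst).
#' @export
#' @examples
#' b <- accel_bursts("a", as.POSIXct("2012-08-01 18:00:00", tz = "Etc/GMT-3"),
#'                   array(rep(c(0, 0, 1), each = 25), c(1, 25, 3)))
#' compute_vedba(b)$mean  # constant signal: VeDBA 0
compute_vedba <- function(bursts, smoothing_window = 0.7) {
  k <- dim(bursts$samples)[2]
  if (k / bursts$rate < smoothing_window) {
    stop("burst shorter than the smoothing window", call. = FALSE)
  }
  h <- floor(bursts$rate * smoothing_window / 2)
  v2 <- 0
  for (ax in 1:3) {
    M <- bursts$samples[, , ax, drop = FALSE]
    dim(M) <- dim(bursts$samples)[1:2]
    dyn <- M - running_mean_rows(M, h)
    v2 <- v2 + dyn^2
  }
  per_sample <- sqrt(v2)
  list(per_sample = per_sample, mean = rowMeans(per_sample))
}

#' Assemble per-minute log-VeDBA series
#'
#' Builds the pipeline's central time series: for each individual, one row
#' per minute epoch spanning the first to the last observed epoch, with
#' `log_vedba = log(mean VeDBA + 1e-6)` (natural log; the small offset
#' guards against log(0) on perfectly still bursts) and `NA` where the
#' burst is missing. Missing epochs are explicit rows, never interpolated.
#'
#' @param bursts An [accel_bursts()] object.
#' @param vedba_means Optional precomputed burst-mean VeDBA (from
#'   [compute_vedba()]); computed if omitted.
#' @return A data frame of class `minute_vedba` with columns
#'   `individual_id`, `time` (POSIXct, minute resolution), `log_vedba`.
#' @export
assemble_minute_series <- function(bursts, vedba_means = NULL) {
  if (is.null(vedba_means)) vedba_means <- compute_vedba(bursts)$mean
  if (any(vedba_means < 0, na.rm = TRUE)) {
    stop("negative mean VeDBA is impossible", call. = FALSE)
  }
  eps <- 1e-6
  out <- lapply(unique(bursts$individual_id), function(id) {
    sel <- bursts$individual_id == id
    tt <- bursts$epoch_start[sel]
    lv <- log(vedba_means[sel] + eps)
    grid <- seq(min(tt), max(tt), by = 60)
    m <- match(as.numeric(grid), as.numeric(tt))
    data.frame(individual_id = id, time = grid, log_vedba = lv[m])
  })
  res <- do.call(rbind, out)
  class(res) <- c("minute_vedba", "data.frame")
  res
}

#' Resample a continuous daytime stream onto the nocturnal burst schedule
#'
#' Continuous daytime accelerometry (e.g. 12 Hz) is downsampled and
#' interpolated so that it matches the nighttime burst schedule: for every
#' minute covered by the stream, the first `burst_duration` seconds are
#' linearly interpolated onto a `rate`-Hz sample grid starting at the
#' minute. Minutes whose burst window is not fully covered by the stream
#' are flagged missing (omitted from the output).
#'
#' @param stream Data frame with columns `individual_id`, `time`
#'   (POSIXct), `acc_x`, `acc_y`, `acc_z`, time-sorted within individual.
#' @param rate Target burst sampling rate (Hz), default 10.
#' @param burst_duration Target burst duration (seconds), default 2.5.
#' @return An [accel_bursts()] object; minutes without coverage carry no
#'   burst.
#' @export
harmonize_daytime <- function(stream, rate = 10, burst_duration = 2.5) {
  if (nrow(stream) == 0) stop("empty input stream", call. = FALSE)
  k <- as.integer(round(rate * burst_duration))
  rel <- (seq_len(k) - 1) / rate
  ids <- character(0); starts <- numeric(0)
  sample_list <- list()
  for (id in unique(stream$individual_id)) {
    s <- stream[stream$individual_id == id, ]
    tt <- as.numeric(s$time)
    minutes <- seq(floor(min(tt) / 60) * 60, floor(max(tt) / 60) * 60, by = 60)
    for (m0 in minutes) {
      tgt <- m0 + rel
      if (min(tt) > tgt[1] || max(tt) < tgt[k]) next  # window not covered
      xyz <- vapply(c("acc_x", "acc_y", "acc_z"), function(ax) {
        stats::approx(tt, s[[ax]], xout = tgt)$y
      }, numeric(k))
      ids <- c(ids, id); starts <- c(starts, m0)
      sample_list[[length(sample_list) + 1L]] <- xyz
    }
  }
  if (!length(ids)) stop("stream covers no complete burst window",
                         call. = FALSE)
  samples <- array(0, c(length(ids), k, 3))
  for (i in seq_along(sample_list)) samples[i, , ] <- sample_list[[i]]
  accel_bursts(ids, as.POSIXct(starts, origin = "1970-01-01", tz = ACC_TZ),
               samples, rate = rate)
}

#' Cumulative daytime activity from a continuous stream
#'
#' Computes VeDBA over a continuous daytime stream with a short smoothing
#' window, averages it within each minute, and sums the per-minute means
#' over the 06:00-18:00 day to a single cumulative activity value.
#' Missing minutes contribute nothing and are reported.
#'
#' @param stream Data frame with columns `individual_id`, `time`,
#'   `acc_x`, `acc_y`, `acc_z` for one individual-day.
#' @param smoothing_window VeDBA static-estimation window in seconds
#'   (default 0.5).
#' @param day_start,day_end Local clock bounds of the daytime window.
#' @return List with `total` (sum of per-minute mean VeDBA), `n_minutes`
#'   (minutes contributing), `n_missing` (window minutes without data).
#' @export
cumulative_daytime_vedba <- function(stream, smoothing_window = 0.5,
                                     day_start = "06:00", day_end = "18:00") {
  if (nrow(stream) == 0) {
    return(list(total = 0, n_minutes = 0L,
                n_missing = length(window_minutes(c(day_start, day_end)))))
  }
  tt <- as.numeric(stream$time)
  dt <- diff(sort(tt))
  rate <- 1 / stats::median(dt[dt > 0])
  h <- max(1L, floor(rate * smoothing_window / 2))
  M <- as.matrix(stream[, c("acc_x", "acc_y", "acc_z")])
  v2 <- 0
  for (ax in 1:3) {
    x <- M[, ax]
    dyn <- x - running_mean_vec(x, h)
    v2 <- v2 + dyn^2
  }
  ved <- sqrt(v2)
  mod <- minute_of_day(stream$time)
  in_day <- mod >= hm_to_min(day_start) & mod < hm_to_min(day_end)
  minute_key <- floor(tt / 60)
  means <- tapply(ved[in_day], minute_key[in_day], mean)
  n_window <- length(window_minutes(c(day_start, day_end)))
  list(total = sum(means), n_minutes = length(means),
       n_missing = n_window - length(means))
}

#' Write accelerometry bursts to CSV
#'
#' Uses a packed one-row-per-burst dialect (`samples` holds
#' space-separated x y z triples) or a long one-row-per-sample dialect.
#'
#' @param bursts An [accel_bursts()] object.
#' @param path Output path.
#' @param dialect `"packed"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(bursts, path, dialect = c("packed", "long")) {
  dialect <- match.arg(dialect)
  n <- length(bursts$individual_id)
  k <- dim(bursts$samples)[2]
  if (dialect == "packed") {
    packed <- vapply(seq_len(n), function(i) {
      paste(sprintf("%.6g", t(bursts$samples[i, , ])), collapse = " ")
    }, character(1))
    dt <- data.table::data.table(
      individual_id = bursts$individual_id,
      timestamp = format(bursts$epoch_start, "%Y-%m-%dT%H:%M:%S",
                         tz = ACC_TZ),
      rate = bursts$rate,
      samples = packed
    )
  } else {
    rel <- rep((seq_len(k) - 1) / bursts$rate, times = n)
    idx <- rep(seq_len(n), each = k)
    tt <- as.numeric(bursts$epoch_start)[idx] + rel
    dt <- data.table::data.table(
      individual_id = bursts$individual_id[idx],
      timestamp = format(as.POSIXct(tt, origin = "1970-01-01", tz = ACC_TZ),
                         "%Y-%m-%dT%H:%M:%OS1", tz = ACC_TZ),
      sample_index = rep(seq_len(k), times = n),
      acc_x = as.vector(t(bursts$samples[, , 1])),
      acc_y = as.vector(t(bursts$samples[, , 2])),
      acc_z = as.vector(t(bursts$samples[, , 3]))
    )
  }
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read accelerometry records from CSV
#'
#' Accepts the packed one-row-per-burst dialect or the long
#' one-row-per-sample dialect (column names remappable via `col_map`).
#' Rows may arrive out of order; duplicate (individual, epoch) bursts are
#' an error naming the individual and epoch.
#'
#' @param path CSV path.
#' @param dialect `"packed"` or `"long"`.
#' @param rate Burst sampling rate (Hz); for the long dialect, samples are
#'   grouped into minute epochs and each epoch must carry the same number
#'   of samples.
#' @param col_map Named list remapping the expected column names
#'   (`individual_id`, `timestamp`, `samples`, `acc_x`, `acc_y`, `acc_z`,
#'   `sample_index`).
#' @return An [accel_bursts()] object.
#' @export
read_accel_records <- function(path, dialect = c("packed", "long"),
                               rate = 10, col_map = list()) {
  dialect <- match.arg(dialect)
  cm <- function(nm) col_map[[nm]] %||% nm
  dt <- data.table::fread(path, showProgress = FALSE)
  parse_time <- parse_local_time
  if (dialect == "packed") {
    id <- as.character(dt[[cm("individual_id")]])
    tt <- parse_time(dt[[cm("timestamp")]])
    key <- paste(id, as.numeric(tt))
    if (anyDuplicated(key)) {
      k <- which(duplicated(key))[1]
      stop(sprintf("duplicate burst for individual '%s' at epoch %s",
                   id[k], format(tt[k], tz = ACC_TZ)), call. = FALSE)
    }
    vals <- strsplit(dt[[cm("samples")]], " ", fixed = TRUE)
    k_s <- length(vals[[1]]) / 3
    samples <- array(0, c(nrow(dt), k_s, 3))
    for (i in seq_len(nrow(dt))) {
      v <- as.numeric(vals[[i]])
      samples[i, , ] <- matrix(v, ncol = 3, byrow = TRUE)
    }
    r <- if ("rate" %in% names(dt)) dt$rate[1] else rate
    accel_bursts(id, tt, samples, rate = r)
  } else {
    id <- as.character(dt[[cm("individual_id")]])
    tt <- parse_time(dt[[cm("timestamp")]])
    epoch <- as.POSIXct(floor(as.numeric(tt) / 60) * 60,
                        origin = "1970-01-01", tz = ACC_TZ)
    ord <- order(id, tt)
    id <- id[ord]; tt <- tt[ord]; epoch <- epoch[ord]
    xyz <- cbind(dt[[cm("acc_x")]], dt[[cm("acc_y")]],
                 dt[[cm("acc_z")]])[ord, , drop = FALSE]
    key <- paste(id, as.numeric(epoch))
    counts <- table(key)
    k_s <- as.integer(names(sort(table(counts), decreasing = TRUE))[1])
    bad <- names(counts)[counts != k_s]
    if (length(bad)) {
      stop(sprintf(
        "inconsistent sample count (possible duplicate epoch) for '%s'",
        bad[1]), call. = FALSE)
    }
    ukey <- unique(key)
    n <- length(ukey)
    samples <- array(0, c(n, k_s, 3))
    grp <- match(key, ukey)
    for (ax in 1:3) {
      samples[cbind(grp, stats::ave(seq_along(grp), grp, FUN = seq_along),
                    ax)] <- xyz[, ax]
    }
    first <- !duplicated(key)
    accel_bursts(id[first], epoch[first], samples, rate = rate)
  }
}
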