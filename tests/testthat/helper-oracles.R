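# Independent brute-force oracles. These deliberately use naive
# algorithms (explicit loops, sort-based medians, literal rule scans) so
# they share no code path with the package implementations they check.

TZ3 <- "Etc/GMT-3"
t_at <- function(s) as.POSIXct(s, tz = TZ3)

# naive centered running mean with edge truncation
bf_running_mean <- function(x, h) {
  n <- length(x)
  sapply(seq_len(n), function(j) {
    mean(x[max(1, j - h):min(n, j + h)])
  })
}

# naive per-sample VeDBA for one burst (k x 3 matrix)
bf_vedba <- function(m, rate, window) {
  h <- floor(rate * window / 2)
  stat <- apply(m, 2, bf_running_mean, h = h)
  dyn <- m - stat
  sqrt(rowSums(dyn^2))
}

# naive rolling median: symmetric edge shrink, NAs excluded from the
# window, output NA where input NA
bf_rolling_median <- function(x, window = 9) {
  h <- (window - 1) / 2
  n <- length(x)
  sapply(seq_len(n), function(j) {
    if (is.na(x[j])) return(NA_real_)
    he <- min(h, j - 1, n - j)
    v <- sort(x[(j - he):(j + he)])  # sort drops NA
    k <- length(v)
    if (k == 0) return(NA_real_)
    if (k %% 2 == 1) v[(k + 1) / 2] else mean(v[k / 2 + 0:1])
  })
}

# naive run-length sleep classifier: scan runs of strictly-below epochs
bf_classify <- function(x, thr, min_run = 3) {
  n <- length(x)
  out <- ifelse(is.na(x), NA_character_, "wake")
  if (is.na(thr)) return(rep(NA_character_, n))
  i <- 1
  while (i <= n) {
    if (!is.na(x[i]) && x[i] < thr) {
      j <- i
      while (j < n && !is.na(x[j + 1]) && x[j + 1] < thr) j <- j + 1
      if (j - i + 1 >= min_run) out[i:j] <- "sleep"
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# naive wake-bout counter: literal reading of the separation rule
bf_wake_bouts <- function(labels, min_dur = 2, sep = 3) {
  n <- length(labels)
  # collect wake runs
  runs <- list()
  i <- 1
  while (i <= n) {
    if (!is.na(labels[i]) && labels[i] == "wake") {
      j <- i
      while (j < n && !is.na(labels[j + 1]) && labels[j + 1] == "wake") {
        j <- j + 1
      }
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(runs)) return(0L)
  # coalesce runs separated by < sep sleep epochs, then count long bouts
  bouts <- list(runs[[1]])
  for (r in runs[-1]) {
    prev <- bouts[[length(bouts)]]
    gap <- labels[(prev[length(prev)] + 1):(r[1] - 1)]
    if (sum(gap == "sleep", na.rm = TRUE) < sep) {
      bouts[[length(bouts)]] <- c(prev, r)
    } else {
      bouts[[length(bouts)]] <- prev
      bouts[[length(bouts) + 1]] <- r
    }
  }
  cnt <- 0L
  for (b in bouts) {
    wl <- sum(sapply(seq(1, length(b), by = 2), function(k) {
      b[k + 1] - b[k] + 1
    }))
    if (wl >= min_dur) cnt <- cnt + 1L
  }
  cnt
}

# naive group statistics tally
bf_group_stats <- function(arr) {
  d <- dim(arr)
  any_awake <- c(); sync <- c()
  for (n in seq_len(d[3])) {
    for (e in seq_len(d[2])) {
      v <- arr[, e, n]
      v <- v[!is.na(v)]
      if (!length(v)) next
      any_awake <- c(any_awake, any(v == 1))
      sync <- c(sync, max(sum(v == 1), sum(v == 0)) / length(v))
    }
  }
  list(prop_any_awake = mean(any_awake),
       mean_prop_synchronized = mean(sync))
}

# naive dyad score tally
bf_dyad_scores <- function(arr) {
  ids <- dimnames(arr)[[1]]
  nights <- as.integer(dimnames(arr)[[3]])
  rows <- list()
  for (n in seq_along(nights)) {
    for (a in 1:(length(ids) - 1)) {
      for (b in (a + 1):length(ids)) {
        agree <- 0; tot <- 0
        for (e in seq_len(dim(arr)[2])) {
          va <- arr[a, e, n]; vb <- arr[b, e, n]
          if (!is.na(va) && !is.na(vb)) {
            tot <- tot + 1
            if (va == vb) agree <- agree + 1
          }
        }
        if (tot > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            id_a = ids[a], id_b = ids[b], night = nights[n],
            sync_score = agree / tot, minutes_observed = tot)
        }
      }
    }
  }
  do.call(rbind, rows)
}

# naive arousal-table eligibility scan
bf_arousal_rows <- function(arr, trees_by_ind_night, first_n = 14) {
  ids <- dimnames(arr)[[1]]
  nights <- as.integer(dimnames(arr)[[3]])
  rows <- list()
  for (n in seq_along(nights)) {
    if (nights[n] > first_n) next
    for (f in seq_along(ids)) {
      tf <- trees_by_ind_night[[paste(ids[f], nights[n])]]
      if (is.null(tf) || is.na(tf)) next
      mates <- c()
      for (g in seq_along(ids)) {
        if (g == f) next
        tg <- trees_by_ind_night[[paste(ids[g], nights[n])]]
        if (!is.null(tg) && !is.na(tg) && tg == tf) mates <- c(mates, g)
      }
      if (!length(mates)) next
      for (t in 4:dim(arr)[2]) {
        v <- arr[f, , n]
        if (is.na(v[t])) next
        if (any(is.na(v[(t - 3):(t - 1)])) ||
            any(v[(t - 3):(t - 1)] != 0)) next
        mv <- arr[mates, t - 1, n]
        if (all(is.na(mv))) next
        rows[[length(rows) + 1]] <- data.frame(
          focal_id = ids[f], night = nights[n], epoch = t,
          awake = as.integer(v[t] == 1),
          groupmate_awake_prev = as.integer(any(mv == 1, na.rm = TRUE)))
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# independent convex-polygon containment (sign of cross products)
bf_in_convex <- function(px, py, poly) {
  n <- nrow(poly)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cr <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
      (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
    if (abs(cr) < 1e-12) next
    if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

# ground-truth assignment table from a simulation
truth_assignments <- function(truth) {
  n_nights <- dim(truth$state)[3]
  data.frame(
    individual_id = rep(truth$individuals, n_nights),
    night = rep(seq_len(n_nights), each = length(truth$individuals)),
    tree_id = as.vector(truth$tree)
  )
}

# small random label vector with sleep/wake/NA
rand_labels <- function(n, p_sleep = 0.7, p_na = 0.05) {
  l <- sample(c("sleep", "wake"), n, replace = TRUE,
              prob = c(p_sleep, 1 - p_sleep))
  l[runif(n) < p_na] <- NA
  l
}
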