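# Ground-truth simulation: latent sleep/wake states, tree choices, coupling.

# State codes in the truth array
ST_SLEEP <- 1L
ST_REST <- 2L    # resting wakefulness (sleep-like acceleration)
ST_ACTIVE <- 3L  # active wakefulness

# Epoch index within a noon-to-noon day: epoch 1 starts at local 12:00.
epoch_of_minute <- function(min_of_day) {
  ((min_of_day - 720) %% 1440) + 1L
}

minute_of_epoch <- function(epoch) {
  ((epoch - 1L) + 720L) %% 1440L
}

# truncated-normal draw (truncation at mean +/- 2 sd)
rtrunc2 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  mean + sd * stats::qnorm(stats::runif(n, lo, hi))
}

rgeom1 <- function(n, mean) {
  # geometric on {1, 2, ...} with the given mean
  stats::rgeom(n, prob = 1 / mean) + 1L
}

#' Simulate ground-truth sleep/wake states, tree choices, and coupling
#'
#' Generates the latent behaviour of a simulated group: per individual and
#' night, a consolidated sleep period between a sampled onset and waking
#' time, spontaneous wake bouts (Poisson arrivals, geometric durations)
#' confined to the interior of the sleep period, optional wake contagion
#' between tree-mates (a sleeping individual wakes at epoch t with
#' `coupling_prob` when any same-tree group-mate transitioned to
#' wakefulness at t-1, so cascades can propagate), and a nightly sleep-tree
#' choice drawn from fixed individual preference weights.
#'
#' Three latent states are tracked - sleep, resting wakefulness, and active
#' wakefulness - even though downstream scoring is binary, so the known
#' actigraphy bias (resting wakefulness misread as sleep) can be measured
#' against truth.
#'
#' @param config A [sim_config()].
#' @param tree_map A [make_tree_map()] result with at least
#'   `config$n_trees` trees (extra trees are ignored).
#' @return A `ground_truth` object: list with `state` (integer array
#'   individuals x 1440 epochs x nights; epoch 1 = local noon; codes
#'   1 sleep / 2 resting-wake / 3 active-wake), `onset_epoch` and
#'   `waking_epoch` matrices, `tree` matrix of nightly tree ids,
#'   `preferences` (individuals x trees weight matrix), `coupling_events`
#'   data frame, `individuals`, `config`, `tree_map`.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 3, n_nights = 2, seed = 7)
#' tm <- make_tree_map(cfg$n_trees, seed = 7)
#' tr <- generate_group_truth(cfg, tm)
#' dim(tr$state)
generate_group_truth <- function(config, tree_map) {
  validate_sim_config(config)
  if (length(tree_map$trees) < config$n_trees) {
    stop("tree_map has fewer trees than config$n_trees", call. = FALSE)
  }
  n_ind <- config$n_individuals
  n_nights <- config$n_nights
  ids <- sprintf("ind_%02d", seq_len(n_ind))
  tree_ids <- names(tree_map$trees)[seq_len(config$n_trees)]

  with_seed(derive_seed(config$seed, "truth"), {
    onset_min <- matrix(
      round(rtrunc2(n_ind * n_nights, config$night_sleep_start$mean,
                    config$night_sleep_start$sd)),
      n_ind, n_nights)
    waking_min <- matrix(
      round(rtrunc2(n_ind * n_nights, config$night_sleep_end$mean,
                    config$night_sleep_end$sd)),
      n_ind, n_nights)
    onset_ep <- epoch_of_minute(onset_min)
    waking_ep <- epoch_of_minute(waking_min)

    # fixed per-individual tree preferences
    gamma <- config$tree_preference_concentration
    base <- matrix(stats::runif(n_ind * config$n_trees), n_ind)
    pref <- if (is.infinite(gamma)) {
      p <- matrix(0, n_ind, config$n_trees)
      p[cbind(seq_len(n_ind), max.col(base))] <- 1
      p
    } else if (gamma == 0) {
      matrix(1 / config$n_trees, n_ind, config$n_trees)
    } else {
      w <- base^gamma
      w / rowSums(w)
    }
    colnames(pref) <- tree_ids

    tree <- matrix("", n_ind, n_nights)
    for (i in seq_len(n_ind)) {
      tree[i, ] <- tree_ids[sample.int(config$n_trees, n_nights,
                                       replace = TRUE, prob = pref[i, ])]
    }

    state <- array(ST_ACTIVE, dim = c(n_ind, 1440L, n_nights))
    # wake bouts confined to the interior (consolidated onset/waking);
    # the 40-min margin exceeds the scorer's 30-min block length plus
    # its 9-min median window, so sleep onset and waking stay crisp
    zone_lo <- onset_ep + 40L
    zone_hi <- waking_ep - 41L
    draw_bout_states <- function(len) {
      if (stats::runif(1) < config$resting_wake_fraction) {
        rep(ST_REST, len)
      } else {
        rep(ST_ACTIVE, len)
      }
    }
    draw_dur <- function() {
      min(rgeom1(1, config$wake_bout_duration),
          config$wake_bout_max_duration)
    }
    # renewal process of arousals: each wake bout is followed by at least
    # `wake_bout_min_sleep_gap` minutes of sleep plus an exponential
    # slack chosen so the long-run bout rate matches wake_bout_rate
    slack <- if (config$wake_bout_rate > 0) {
      max(0, 60 / config$wake_bout_rate - config$wake_bout_duration -
            config$wake_bout_min_sleep_gap)
    } else {
      0
    }
    for (n in seq_len(n_nights)) {
      for (i in seq_len(n_ind)) {
        o <- onset_ep[i, n]; w <- waking_ep[i, n]
        if (w <= o) next
        state[i, o:(w - 1L), n] <- ST_SLEEP
        lo <- zone_lo[i, n]; hi <- zone_hi[i, n]
        if (config$wake_bout_rate > 0 && hi >= lo) {
          t <- lo + if (slack > 0) round(stats::rexp(1, 1 / slack)) else 0L
          while (t <= hi) {
            dur <- draw_dur()
            eps <- t:min(t + dur - 1L, hi)
            state[i, eps, n] <- draw_bout_states(length(eps))
            gap <- config$wake_bout_min_sleep_gap +
              if (slack > 0) round(stats::rexp(1, 1 / slack)) else 0
            t <- t + dur + gap
          }
        }
      }
    }

    # wake contagion between tree-mates, with one-epoch lag
    events <- list()
    if (config$coupling_prob > 0 && n_ind > 1) {
      for (n in seq_len(n_nights)) {
        t_lo <- min(onset_ep[, n]) + 2L
        t_hi <- max(waking_ep[, n]) - 1L
        st <- state[, , n, drop = FALSE]
        dim(st) <- dim(state)[1:2]
        for (t in t_lo:t_hi) {
          awake_prev <- st[, t - 1L] != ST_SLEEP
          asleep_prev2 <- st[, t - 2L] == ST_SLEEP
          in_window_prev <- (t - 1L) >= onset_ep[, n] &
            (t - 1L) < waking_ep[, n]
          onset_now <- awake_prev & asleep_prev2 & in_window_prev
          if (!any(onset_now)) next
          trig_trees <- unique(tree[onset_now, n])
          cand <- which(st[, t] == ST_SLEEP &
                          tree[, n] %in% trig_trees &
                          t >= zone_lo[, n] & t <= zone_hi[, n] &
                          !onset_now)
          if (!length(cand)) next
          # refractory arousal: only individuals asleep for at least
          # 5 min can be woken by a group-mate (damps cascades)
          ok <- vapply(cand, function(i) {
            lo_chk <- max(onset_ep[i, n], t - 5L)
            all(st[i, lo_chk:(t - 1L)] == ST_SLEEP)
          }, logical(1))
          cand <- cand[ok]
          if (!length(cand)) next
          woken <- cand[stats::runif(length(cand)) < config$coupling_prob]
          for (i in woken) {
            # responsive arousals are brief; the 4-min cap keeps them
            # below the rolling-median majority, so they never fragment
            # sleep-period detection
            dur <- min(rgeom1(1, config$coupling_bout_duration), 4L)
            eps <- t:min(t + dur - 1L, zone_hi[i, n])
            st[i, eps] <- draw_bout_states(length(eps))
            events[[length(events) + 1L]] <-
              data.frame(night = n, epoch = t, individual = ids[i],
                         tree_id = tree[i, n])
          }
        }
        state[, , n] <- st
      }
    }
    coupling_events <- if (length(events)) {
      do.call(rbind, events)
    } else {
      data.frame(night = integer(), epoch = integer(),
                 individual = character(), tree_id = character())
    }

    dimnames(state) <- list(ids, NULL, NULL)
    rownames(tree) <- ids
    rownames(onset_ep) <- rownames(waking_ep) <- ids
    structure(
      list(state = state, onset_epoch = onset_ep, waking_epoch = waking_ep,
           tree = tree, preferences = pref,
           coupling_events = coupling_events,
           individuals = ids, config = config, tree_map = tree_map),
      class = "ground_truth"
    )
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", length(x$individuals), "individuals x",
      dim(x$state)[3], "nights;", nrow(x$coupling_events),
      "coupling events\n")
  invisible(x)
}

#' Extract a clock-aligned binary wake/sleep array from ground truth
#'
#' Subsets the truth state array to a fixed nightly clock window and
#' recodes it as binary wakefulness (resting and active wakefulness both
#' count as wake). This is the ground-truth analogue of the epoch matrix
#' built from scored labels, and is the natural input for the
#' synchronization null models when evaluating them against known truth.
#'
#' @param truth A `ground_truth`.
#' @param window Character `c(start, end)` local clock times; default the
#'   21:00-05:00 nocturnal analysis window.
#' @param missing_prob Probability that an epoch is `NA`, emulating the
#'   dropped accelerometry bursts that make scored labels missing;
#'   defaults to the generator's `missing_burst_prob`.
#' @param seed Seed for the missingness draw (derived from the
#'   generator's seed by default).
#' @return Integer array individuals x epochs x nights, 1 = wake,
#'   0 = sleep, NA = missing, with an `epoch_min` attribute giving each
#'   column's minute of day.
#' @export
truth_epoch_array <- function(truth, window = c("21:00", "05:00"),
                              missing_prob = NULL, seed = NULL) {
  mins <- window_minutes(window)
  eps <- epoch_of_minute(mins)
  arr <- truth$state[, eps, , drop = FALSE]
  out <- array(1L, dim = dim(arr),
               dimnames = list(truth$individuals, NULL,
                               seq_len(dim(arr)[3])))
  out[arr == ST_SLEEP] <- 0L
  missing_prob <- missing_prob %||% truth$config$missing_burst_prob
  if (missing_prob > 0) {
    seed <- seed %||% derive_seed(truth$config$seed, "epoch_missing")
    drop <- with_seed(seed, stats::runif(length(out)) < missing_prob)
    out[drop] <- NA_integer_
  }
  attr(out, "epoch_min") <- mins
  out
}

# minutes of day covered by a clock window, end-exclusive, possibly
# crossing midnight
window_minutes <- function(window) {
  a <- hm_to_min(window[1]); b <- hm_to_min(window[2])
  if (a < b) a:(b - 1L) else c(a:1439L, 0L:(b - 1L))
}

#' Per-night ground-truth summary table
#'
#' @param truth A `ground_truth`.
#' @return Data frame with one row per individual-night: true onset and
#'   waking times (POSIXct, site-local), true total sleep minutes, and the
#'   chosen tree.
#' @export
truth_nights <- function(truth) {
  n_ind <- length(truth$individuals)
  n_nights <- dim(truth$state)[3]
  grid <- expand.grid(i = seq_len(n_ind), night = seq_len(n_nights))
  noon <- local_midnight(truth$config$start_date + grid$night - 1) + 12 * 3600
  data.frame(
    individual_id = truth$individuals[grid$i],
    night = grid$night,
    onset_time = noon +
      (truth$onset_epoch[cbind(grid$i, grid$night)] - 1) * 60,
    waking_time = noon +
      (truth$waking_epoch[cbind(grid$i, grid$night)] - 1) * 60,
    tst_true = vapply(seq_len(nrow(grid)), function(k) {
      sum(truth$state[grid$i[k], , grid$night[k]] == ST_SLEEP)
    }, integer(1)),
    tree_id = truth$tree[cbind(grid$i, grid$night)]
  )
}
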