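# Group-level nocturnal wakefulness and synchronization, with time-shift
# and night-permutation null models and dyadic synchronization scores.

#' Build a clock-aligned epoch matrix from scored labels
#'
#' Arranges per-epoch sleep/wake labels into an array individuals x
#' epochs x nights restricted to a fixed nightly clock window (default
#' 21:00-05:00, 480 epochs, times that fall inside every sleep period).
#'
#' @param labels Data frame from [score_sleep()] (`individual_id`,
#'   `night`, `time`, `label`).
#' @param window Clock window `c(start, end)`.
#' @return Integer array (1 = wake, 0 = sleep, NA = missing) with an
#'   `epoch_min` attribute.
#' @export
epoch_matrix <- function(labels, window = c("21:00", "05:00")) {
  mins <- window_minutes(window)
  ids <- sort(unique(labels$individual_id))
  nights <- sort(unique(labels$night))
  arr <- array(NA_integer_,
               dim = c(length(ids), length(mins), length(nights)),
               dimnames = list(ids, NULL, nights))
  mod <- minute_of_day(labels$time)
  keep <- mod %in% mins
  l <- labels[keep, ]
  mpos <- match(mod[keep], mins)
  ipos <- match(l$individual_id, ids)
  npos <- match(l$night, nights)
  val <- ifelse(is.na(l$label), NA_integer_,
                ifelse(l$label == "wake", 1L, 0L))
  arr[cbind(ipos, mpos, npos)] <- val
  attr(arr, "epoch_min") <- mins
  arr
}

#' Collective wakefulness and synchronization statistics
#'
#' For a clock-aligned epoch array, computes (a) the proportion of minute
#' epochs (across all nights) in which at least one non-missing group
#' member was awake, and (b) the mean proportion of the group in the
#' modal state (asleep or awake) per epoch - the synchronization
#' statistic. Epochs with no non-missing individual are excluded from
#' both.
#'
#' @param arr Array individuals x epochs x nights (1 wake, 0 sleep, NA
#'   missing), e.g. from [epoch_matrix()] or [truth_epoch_array()].
#' @return List `prop_any_awake`, `mean_prop_synchronized`, `n_epochs`.
#' @export
group_wake_statistics <- function(arr) {
  d <- dim(arr)
  m <- arr
  dim(m) <- c(d[1], d[2] * d[3])
  n_obs <- colSums(!is.na(m))
  n_wake <- colSums(m == 1L, na.rm = TRUE)
  valid <- n_obs >= 1
  sync <- pmax(n_wake[valid], n_obs[valid] - n_wake[valid]) / n_obs[valid]
  list(prop_any_awake = mean(n_wake[valid] > 0),
       mean_prop_synchronized = mean(sync),
       n_epochs = sum(valid))
}

# circularly shift one individual-night state vector by k epochs
circ_shift <- function(v, k) {
  n <- length(v)
  v[((seq_len(n) - 1L - k) %% n) + 1L]
}

#' Time-shift null model for collective sleep statistics
#'
#' Each iteration applies an independent random circular shift (uniform
#' on 1..E-1 epochs) to every individual's state vector on every night,
#' then recomputes the group statistics. Shifting preserves each
#' individual-night's wake total and autocorrelation exactly while
#' destroying cross-individual alignment; missing epochs travel with the
#' vector.
#'
#' @param arr Epoch array (individuals x epochs x nights).
#' @param n_iter Iterations (default 1000).
#' @param seed Integer seed.
#' @param iteration_hook Optional function called with the resampled
#'   array at every iteration (used e.g. to verify conservation
#'   invariants).
#' @return List of class `null_report` per statistic: each has
#'   `empirical`, `nulls`, `p_value`, `direction`, `method`, `seed`. The
#'   p-values use the directions of interest: any-awake *less* than null
#'   (collective vigilance lower than chance), synchronization *greater*
#'   than null.
#' @export
time_shift_null <- function(arr, n_iter = 1000, seed = 1L,
                            iteration_hook = NULL) {
  emp <- group_wake_statistics(arr)
  d <- dim(arr)
  nulls_any <- numeric(n_iter)
  nulls_sync <- numeric(n_iter)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      shifted <- arr
      for (n in seq_len(d[3])) {
        ks <- sample.int(d[2] - 1L, d[1], replace = TRUE)
        for (i in seq_len(d[1])) {
          shifted[i, , n] <- circ_shift(arr[i, , n], ks[i])
        }
      }
      if (!is.null(iteration_hook)) iteration_hook(shifted)
      st <- group_wake_statistics(shifted)
      nulls_any[it] <- st$prop_any_awake
      nulls_sync[it] <- st$mean_prop_synchronized
    }
  })
  list(
    prop_any_awake = null_report("prop_any_awake", emp$prop_any_awake,
                                 nulls_any, "le", "time_shift", seed),
    mean_prop_synchronized = null_report(
      "mean_prop_synchronized", emp$mean_prop_synchronized, nulls_sync,
      "ge", "time_shift", seed)
  )
}

#' Night-permutation null model for collective sleep statistics
#'
#' Keeps the clock time of every state vector but permutes, independently
#' for each individual, which night each vector is attributed to, then
#' recomputes the group statistics. This controls for synchrony arising
#' from a stereotyped shared schedule.
#'
#' @inheritParams time_shift_null
#' @return As [time_shift_null()], with `method = "night_permutation"`.
#' @export
night_permutation_null <- function(arr, n_iter = 1000, seed = 1L,
                                   iteration_hook = NULL) {
  d <- dim(arr)
  if (d[3] < 2) stop("night permutation requires >= 2 nights",
                     call. = FALSE)
  emp <- group_wake_statistics(arr)
  nulls_any <- numeric(n_iter)
  nulls_sync <- numeric(n_iter)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      perm <- arr
      for (i in seq_len(d[1])) {
        perm[i, , ] <- arr[i, , sample.int(d[3])]
      }
      if (!is.null(iteration_hook)) iteration_hook(perm)
      st <- group_wake_statistics(perm)
      nulls_any[it] <- st$prop_any_awake
      nulls_sync[it] <- st$mean_prop_synchronized
    }
  })
  list(
    prop_any_awake = null_report("prop_any_awake", emp$prop_any_awake,
                                 nulls_any, "le", "night_permutation",
                                 seed),
    mean_prop_synchronized = null_report(
      "mean_prop_synchronized", emp$mean_prop_synchronized, nulls_sync,
      "ge", "night_permutation", seed)
  )
}

null_report <- function(statistic, empirical, nulls, direction, method,
                        seed) {
  structure(
    list(statistic = statistic, empirical = empirical, nulls = nulls,
         p_value = permutation_pvalue(empirical, nulls, direction),
         direction = direction, method = method, seed = seed,
         n_iter = length(nulls)),
    class = "null_report"
  )
}

#' @export
print.null_report <- function(x, ...) {
  p_str <- if (x$p_value == 0) {
    sprintf("< %.4g", 1 / x$n_iter)
  } else {
    sprintf("= %.4g", x$p_value)
  }
  cat(sprintf("<null_report> %s (%s): empirical %.4f, null %.4f [%.4f, %.4f], p %s (%s)\n",
              x$statistic, x$method, x$empirical, mean(x$nulls),
              stats::quantile(x$nulls, 0.025),
              stats::quantile(x$nulls, 0.975), p_str, x$direction))
  invisible(x)
}

#' Permutation p-value
#'
#' Proportion of null values as or more extreme than the empirical value
#' in the declared direction (`"le"`: null <= empirical; `"ge"`: null >=
#' empirical). The resolution floor is 1/n_iter; a zero count is reported
#' as 0 and printed as `< 1/n_iter`.
#'
#' @param empirical Empirical statistic.
#' @param nulls Numeric vector of null statistics.
#' @param direction `"le"` or `"ge"`.
#' @return Numeric p-value in \[0, 1\].
#' @export
permutation_pvalue <- function(empirical, nulls, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (!length(nulls)) stop("nulls must be non-empty", call. = FALSE)
  k <- switch(direction,
              ge = sum(nulls >= empirical),
              le = sum(nulls <= empirical))
  k / length(nulls)
}

#' Dyadic nightly synchronization scores
#'
#' For every pair of individuals and night, the synchronization score is
#' the number of epochs in which both exhibited the same state (sleep or
#' wake) divided by the number of epochs in which both had data. The
#' same-tree flag comes from the per-night sleep assignments; dyads with
#' an excluded assignment carry `NA`.
#'
#' @param arr Epoch array from [epoch_matrix()].
#' @param assignments Optional assignment table (from
#'   [assign_sleep_trees()] or truth) with `individual_id`, `night`,
#'   `tree_id`.
#' @return Data frame `id_a`, `id_b`, `night`, `sync_score`,
#'   `minutes_observed`, `same_tree`.
#' @export
dyad_sync_scores <- function(arr, assignments = NULL) {
  ids <- dimnames(arr)[[1]]
  nights <- as.integer(dimnames(arr)[[3]])
  tree_of <- function(id, n) {
    if (is.null(assignments)) return(NA_character_)
    r <- assignments$tree_id[assignments$individual_id == id &
                               assignments$night == n]
    if (length(r) != 1) NA_character_ else r
  }
  out <- list()
  for (ni in seq_along(nights)) {
    for (a in seq_along(ids)[-length(ids)]) {
      va <- arr[a, , ni]
      for (b in (a + 1):length(ids)) {
        vb <- arr[b, , ni]
        co <- !is.na(va) & !is.na(vb)
        n_co <- sum(co)
        if (n_co == 0) next
        ta <- tree_of(ids[a], nights[ni])
        tb <- tree_of(ids[b], nights[ni])
        out[[length(out) + 1L]] <- data.frame(
          id_a = ids[a], id_b = ids[b], night = nights[ni],
          sync_score = mean(va[co] == vb[co]),
          minutes_observed = n_co,
          same_tree = if (is.na(ta) || is.na(tb)) NA else ta == tb)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
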