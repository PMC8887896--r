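#' Configuration for the synthetic biologger-data generator
#'
#' Builds and validates the parameter set controlling a simulated group of
#' collared animals with known ground-truth sleep/wake behaviour, sleep-tree
#' choices, wake contagion between tree-mates, and sensor noise.
#'
#' Defaults emulate the field conditions of a tracked baboon group: a
#' consolidated nocturnal sleep period of about 11 h (sleep onset around
#' 19:00 local, waking around 06:05, both with 15-min night-to-night spread,
#' truncated at 2 sd so the 21:00-05:00 analysis window always falls inside
#' every sleep period), brief nocturnal wake bouts arriving as a renewal
#' process (1.3 arousals/h, geometric durations with mean 3 min, at least
#' 40 min of sleep between consecutive arousals) confined to the interior
#' of the sleep period (no bouts within 40 min of onset or waking), and a
#' small fraction of wake bouts spent in resting wakefulness, which is
#' emitted at sleep-like acceleration levels and so reproduces the known
#' actigraphy failure mode (resting wakefulness misread as sleep).
#'
#' Acceleration is emitted in raw sensor-count units (as recorded by field
#' biologging collars), for which log mean VeDBA per burst is positive;
#' `sleep_logvedba_mean` must be below `day_logvedba_mean`.
#'
#' @param n_individuals Number of tracked animals.
#' @param n_nights Number of simulated nights (noon-to-noon days).
#' @param epoch_length Epoch length in seconds; fixed at 60.
#' @param night_sleep_start,night_sleep_end Lists `list(mean=, sd=)` giving
#'   the local clock-time distribution of true sleep onset / waking; `mean`
#'   is `"HH:MM"` or minutes since midnight, `sd` in minutes. Draws are
#'   truncated at `mean +/- 2*sd`.
#' @param wake_bout_rate Spontaneous wake bouts per hour of the sleep period.
#' @param wake_bout_duration Mean wake-bout duration in minutes (geometric on
#'   1, 2, ... minutes, capped at `wake_bout_max_duration`).
#' @param wake_bout_min_sleep_gap Minimum minutes of sleep between
#'   consecutive wake bouts (default 40). Arousals in consolidated sleep
#'   arrive as a renewal process with this refractory sleep interval;
#'   setting 0 recovers a pure Poisson process.
#' @param wake_bout_max_duration Cap on wake-bout durations in minutes
#'   (default 15).
#' @param resting_wake_fraction Probability that a wake-bout epoch is resting
#'   wakefulness rather than active wakefulness.
#' @param coupling_prob Probability that a sleeping individual wakes at epoch
#'   t given that a same-tree group-mate transitioned to wakefulness at t-1.
#'   Responsive arousals require at least 5 min of preceding sleep (a
#'   refractory period that damps cascades).
#' @param coupling_bout_duration Mean duration (minutes) of responsive
#'   arousals; these are brief (capped at 4 min, shorter than the
#'   rolling-median majority) compared to spontaneous bouts.
#' @param n_trees Number of sleep trees at the site.
#' @param tree_preference_concentration Non-negative sharpness of individual
#'   tree preferences: 0 gives uniform random nightly choice, larger values
#'   concentrate each individual on its favourite trees, `Inf` pins every
#'   individual to a single tree.
#' @param day_logvedba_mean,day_logvedba_sd Emission parameters (natural log
#'   of burst-mean VeDBA, count units) for active wakefulness (day and
#'   nocturnal active wake bouts).
#' @param sleep_logvedba_mean,sleep_logvedba_sd Emission parameters for sleep.
#' @param restingwake_logvedba_mean,restingwake_logvedba_sd Emission
#'   parameters for resting wakefulness (sleep-like by design).
#' @param missing_burst_prob Probability that any given accelerometry burst
#'   is missing.
#' @param site_lon,site_lat Site centre (degrees); defaults to a riverine
#'   sleep site on the Laikipia plateau.
#' @param start_date First simulated day (`Date` or `"YYYY-MM-DD"`); day d
#'   covers local noon of `start_date + d - 1` to the next noon.
#' @param seed Integer seed controlling all generator randomness.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 4, n_nights = 3, seed = 1)
#' cfg$wake_bout_rate
sim_config <- function(n_individuals = 26,
                       n_nights = 35,
                       epoch_length = 60,
                       night_sleep_start = list(mean = "19:00", sd = 15),
                       night_sleep_end = list(mean = "06:05", sd = 15),
                       wake_bout_rate = 1.3,
                       wake_bout_duration = 3,
                       wake_bout_min_sleep_gap = 40,
                       wake_bout_max_duration = 15,
                       resting_wake_fraction = 0.05,
                       coupling_prob = 0.05,
                       coupling_bout_duration = 2,
                       n_trees = 10,
                       tree_preference_concentration = 2,
                       day_logvedba_mean = 5.5,
                       day_logvedba_sd = 0.5,
                       sleep_logvedba_mean = 2.2,
                       sleep_logvedba_sd = 0.06,
                       restingwake_logvedba_mean = 2.25,
                       restingwake_logvedba_sd = 0.06,
                       missing_burst_prob = 0.005,
                       site_lon = 36.87,
                       site_lat = 0.29,
                       start_date = "2012-08-01",
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_nights = as.integer(n_nights),
    epoch_length = as.integer(epoch_length),
    night_sleep_start = list(mean = hm_to_min(night_sleep_start$mean),
                             sd = as.numeric(night_sleep_start$sd)),
    night_sleep_end = list(mean = hm_to_min(night_sleep_end$mean),
                           sd = as.numeric(night_sleep_end$sd)),
    wake_bout_rate = as.numeric(wake_bout_rate),
    wake_bout_duration = as.numeric(wake_bout_duration),
    wake_bout_min_sleep_gap = as.numeric(wake_bout_min_sleep_gap),
    wake_bout_max_duration = as.numeric(wake_bout_max_duration),
    resting_wake_fraction = as.numeric(resting_wake_fraction),
    coupling_prob = as.numeric(coupling_prob),
    coupling_bout_duration = as.numeric(coupling_bout_duration),
    n_trees = as.integer(n_trees),
    tree_preference_concentration = as.numeric(tree_preference_concentration),
    day_logvedba_mean = as.numeric(day_logvedba_mean),
    day_logvedba_sd = as.numeric(day_logvedba_sd),
    sleep_logvedba_mean = as.numeric(sleep_logvedba_mean),
    sleep_logvedba_sd = as.numeric(sleep_logvedba_sd),
    restingwake_logvedba_mean = as.numeric(restingwake_logvedba_mean),
    restingwake_logvedba_sd = as.numeric(restingwake_logvedba_sd),
    missing_burst_prob = as.numeric(missing_burst_prob),
    site_lon = as.numeric(site_lon),
    site_lat = as.numeric(site_lat),
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid sim_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (cfg$n_individuals < 1) stop_field("n_individuals", "must be >= 1")
  if (cfg$n_nights < 1) stop_field("n_nights", "must be >= 1")
  if (cfg$epoch_length != 60) stop_field("epoch_length", "fixed at 60 s")
  if (86400 %% cfg$epoch_length != 0) {
    stop_field("epoch_length", "must divide one day")
  }
  for (f in c("coupling_prob", "missing_burst_prob",
              "resting_wake_fraction")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop_field(f, "must be a probability in [0, 1]")
    }
  }
  if (cfg$wake_bout_rate < 0) stop_field("wake_bout_rate", "must be >= 0")
  if (cfg$wake_bout_duration < 1) {
    stop_field("wake_bout_duration", "mean duration must be >= 1 minute")
  }
  if (cfg$wake_bout_min_sleep_gap < 0) {
    stop_field("wake_bout_min_sleep_gap", "must be >= 0")
  }
  if (cfg$coupling_bout_duration < 1) {
    stop_field("coupling_bout_duration", "mean duration must be >= 1")
  }
  if (cfg$wake_bout_max_duration < cfg$wake_bout_duration) {
    stop_field("wake_bout_max_duration",
               "cap must be at least the mean duration")
  }
  if (cfg$wake_bout_rate > 0) {
    cycle <- cfg$wake_bout_duration + cfg$wake_bout_min_sleep_gap
    if (60 / cfg$wake_bout_rate < cycle) {
      stop_field("wake_bout_rate",
                 "rate incompatible with the minimum sleep gap")
    }
  }
  if (cfg$n_trees < 1) stop_field("n_trees", "must be >= 1")
  if (cfg$tree_preference_concentration < 0) {
    stop_field("tree_preference_concentration", "must be >= 0")
  }
  if (!(cfg$sleep_logvedba_mean < cfg$day_logvedba_mean)) {
    stop_field("sleep_logvedba_mean",
               "sleep emission mean must be below day emission mean")
  }
  for (f in grep("_sd$", names(cfg), value = TRUE)) {
    if (is.list(cfg[[f]])) next
    if (cfg[[f]] < 0) stop_field(f, "must be >= 0")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_individuals, "individuals x", x$n_nights,
      "nights,", x$n_trees, "trees\n")
  cat("  sleep window ~", min_to_hm(x$night_sleep_start$mean), "-",
      min_to_hm(x$night_sleep_end$mean),
      sprintf("(sd %g/%g min)\n", x$night_sleep_start$sd,
              x$night_sleep_end$sd))
  cat(sprintf("  wake bouts %g/h, mean %g min; coupling %g; missing %g\n",
              x$wake_bout_rate, x$wake_bout_duration, x$coupling_prob,
              x$missing_burst_prob))
  invisible(x)
}
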