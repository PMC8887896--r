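# End-to-end orchestration: ingest -> score -> sites -> fidelity -> sync
# -> arousal, with a machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter in one serializable list. All analysis
#' constants are surfaced here (none hard-coded downstream): VeDBA
#' windows, the rolling-median window, the Q10 x 1.125 threshold, block
#' and merge durations, run lengths, bout rules, nap window, QC cutoffs,
#' the sleep-location rule, geometry thresholds, the nocturnal analysis
#' window, null-model iteration counts, night subsets, and seeds.
#'
#' @param accel,gps,trees Input file paths (accelerometry CSV, GPS CSV,
#'   tree-crown GeoJSON).
#' @param out_dir Output directory for all stage products.
#' @param accel_dialect `"packed"` or `"long"` (see
#'   [read_accel_records()]).
#' @param site `c(lon, lat)` of the sleep site (twilight computation).
#' @param scoring A [scoring_params()] list.
#' @param vedba_window Burst VeDBA smoothing window, seconds.
#' @param sync_window Nocturnal clock window for the collective analyses.
#' @param n_iter Null-model iterations.
#' @param n_perm Fidelity permutations.
#' @param first_n_nights Night subset for fidelity and arousal analyses.
#' @param fidelity_min_nights Minimum nights per individual for fidelity.
#' @param location_cutoff,location_n_fixes Sleep-location rule (clock
#'   cutoff and number of fixes).
#' @param max_tree_dist Maximum location-to-crown distance in meters.
#' @param seed Master seed; stage seeds derive from it.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(accel, gps, trees, out_dir,
                            accel_dialect = "packed",
                            site = c(36.87, 0.29),
                            scoring = scoring_params(),
                            vedba_window = 0.7,
                            sync_window = c("21:00", "05:00"),
                            n_iter = 1000,
                            n_perm = 1000,
                            first_n_nights = 14,
                            fidelity_min_nights = 4,
                            location_cutoff = "06:15",
                            location_n_fixes = 10,
                            max_tree_dist = 10,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [pipeline_config()] defaults; the
#' `scoring` block overrides individual [scoring_params()] entries.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc <- do.call(scoring_params, y$scoring %||% list())
  y$scoring <- NULL
  do.call(pipeline_config, c(y, list(scoring = sc)))
}

#' Run the full analysis pipeline
#'
#' Executes ingest, sleep scoring, sleep-site assignment, tree-fidelity
#' testing, collective-synchronization null models, and the
#' arousal-response table/fit, writing per-stage outputs and a run
#' manifest to `config$out_dir`. Re-running with the same configuration
#' and inputs reproduces all outputs.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @return Invisibly, a list with the main in-memory products (`series`,
#'   `scored`, `assignments`, `fidelity`, `sync`, `arousal`) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    stages[[name]] <<- list(
      status = "completed",
      seconds = round(as.numeric(difftime(Sys.time(), t0,
                                          units = "secs")), 2))
    res
  }
  outfile <- function(f) file.path(config$out_dir, f)

  # 1. ingest ---------------------------------------------------------
  series <- t_stage("ingest", {
    bursts <- read_accel_records(config$accel, dialect = config$accel_dialect)
    vm <- compute_vedba(bursts, smoothing_window = config$vedba_window)$mean
    assemble_minute_series(bursts, vm)
  })
  data.table::fwrite(series, outfile("minute_vedba.csv"))

  # 2. sleep scoring ----------------------------------------------------
  scored <- t_stage("score", {
    score_sleep(series, site = config$site, params = config$scoring)
  })
  data.table::fwrite(scored$nights, outfile("night_metrics.csv"))
  data.table::fwrite(scored$labels, outfile("epoch_labels.csv"))
  data.table::fwrite(scored$naps, outfile("naps.csv"))

  # 3. sleep sites ------------------------------------------------------
  assignments <- t_stage("sites", {
    tm <- read_tree_geojson(config$trees, site_center = config$site)
    gps <- data.table::fread(config$gps, showProgress = FALSE)
    gps <- as.data.frame(gps)
    gps$timestamp <- parse_local_time(gps$timestamp)
    night_dates <- sort(unique(scored$nights$day_date)) + 1
    assign_sleep_trees(gps, tm, night_dates,
                       cutoff = config$location_cutoff,
                       n_required = config$location_n_fixes,
                       max_dist = config$max_tree_dist)
  })
  data.table::fwrite(assignments, outfile("sleep_assignments.csv"))

  # 4. tree fidelity ----------------------------------------------------
  fidelity <- t_stage("fidelity", {
    tryCatch(
      fidelity_test(assignments[, c("individual_id", "night", "tree_id")],
                    n_perm = config$n_perm,
                    min_nights = config$fidelity_min_nights,
                    first_n_nights = config$first_n_nights,
                    seed = derive_seed(config$seed, "fidelity")),
      error = function(e) {
        warning("fidelity stage skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  })
  if (!is.null(fidelity)) {
    data.table::fwrite(fidelity$fidelity_index,
                       outfile("fidelity_index.csv"))
    jsonlite::write_json(
      list(ks_statistic = fidelity$ks_statistic,
           p_value = fidelity$p_value, n_perm = fidelity$n_perm,
           seed = fidelity$seed, eligible = fidelity$eligible,
           empirical_entropies = unname(fidelity$empirical_entropies)),
      outfile("fidelity_report.json"), auto_unbox = TRUE, digits = NA)
  }

  # 5. collective synchronization ---------------------------------------
  sync <- t_stage("sync", {
    arr <- epoch_matrix(scored$labels, window = config$sync_window)
    if (dim(arr)[1] < 2) {
      warning("single individual: group statistics skipped",
              call. = FALSE)
      NULL
    } else {
      list(
        time_shift = time_shift_null(arr, n_iter = config$n_iter,
                                     seed = derive_seed(config$seed,
                                                        "timeshift")),
        night_permutation = if (dim(arr)[3] >= 2) {
          night_permutation_null(arr, n_iter = config$n_iter,
                                 seed = derive_seed(config$seed,
                                                    "nightperm"))
        } else NULL,
        dyads = dyad_sync_scores(arr, assignments)
      )
    }
  })
  if (!is.null(sync)) {
    rep_json <- lapply(c(sync["time_shift"], sync["night_permutation"]),
                       function(m) {
                         if (is.null(m)) return(NULL)
                         lapply(m, function(r) {
                           list(statistic = r$statistic,
                                empirical = r$empirical,
                                p_value = r$p_value,
                                direction = r$direction,
                                method = r$method, seed = r$seed,
                                n_iter = r$n_iter,
                                null_mean = mean(r$nulls),
                                null_q025 = unname(stats::quantile(r$nulls,
                                                                   0.025)),
                                null_q975 = unname(stats::quantile(r$nulls,
                                                                   0.975)))
                         })
                       })
    jsonlite::write_json(rep_json, outfile("sync_reports.json"),
                         auto_unbox = TRUE, digits = NA)
    data.table::fwrite(sync$dyads, outfile("dyad_sync.csv"))
  }

  # 6. arousal response -------------------------------------------------
  arousal <- t_stage("arousal", {
    arr <- epoch_matrix(scored$labels, window = config$sync_window)
    tab <- build_arousal_table(arr, assignments, nights = scored$nights,
                               first_n_nights = config$first_n_nights)
    fit <- tryCatch(fit_response_standin(tab), error = function(e) {
      warning("arousal fit skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    list(table = tab, fit = fit)
  })
  data.table::fwrite(arousal$table, outfile("arousal_table.csv"))
  if (!is.null(arousal$fit)) {
    jsonlite::write_json(arousal$fit, outfile("arousal_fit.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  # manifest ------------------------------------------------------------
  cfg_serial <- config
  cfg_serial$scoring <- unclass(cfg_serial$scoring)
  cfg_path <- outfile("pipeline_config.yaml")
  yaml::write_yaml(lapply(unclass(cfg_serial), function(x) {
    if (inherits(x, "Date")) format(x) else x
  }), cfg_path)
  manifest <- list(
    package = "accsleep",
    version = as.character(utils::packageVersion("accsleep")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = stages
  )
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  summary_lines <- c(
    sprintf("accsleep pipeline run (%d stages completed)", length(stages)),
    sprintf("nights scored: %d (%d scorable)", nrow(scored$nights),
            sum(scored$nights$exclusion_reason == "none")),
    if (!is.null(fidelity)) {
      sprintf("tree fidelity: KS D = %.3f, p = %.3g", fidelity$ks_statistic,
              fidelity$p_value)
    },
    if (!is.null(sync)) {
      c(sprintf("prop any awake: %.3f (time-shift p = %.3g)",
                sync$time_shift$prop_any_awake$empirical,
                sync$time_shift$prop_any_awake$p_value),
        sprintf("mean prop synchronized: %.3f (time-shift p = %.3g)",
                sync$time_shift$mean_prop_synchronized$empirical,
                sync$time_shift$mean_prop_synchronized$p_value))
    }
  )
  writeLines(summary_lines, outfile("summary.txt"))
  invisible(list(series = series, scored = scored,
                 assignments = assignments, fidelity = fidelity,
                 sync = sync, arousal = arousal, manifest = manifest))
}
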