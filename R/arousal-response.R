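# Arousal-threshold (wake-contagion) design table and relative covariates.

#' Individual-mean-centered previous-night covariates
#'
#' For each individual-night, the relative value of a night metric is the
#' night's value minus the individual's mean over its valid nights,
#' controlling for stable among-individual differences. Also computes the
#' relative number of individuals in the sleep tree (tree occupancy over
#' the number assigned that night).
#'
#' @param nights Data frame with `individual_id`, `night`, and metric
#'   columns (`tst_min`, `fragmentation`).
#' @param assignments Optional assignment table with `individual_id`,
#'   `night`, `tree_id` used for relative tree occupancy.
#' @return `nights` with added columns `rel_tst`, `rel_frag` (NA when the
#'   individual has no valid nights) and, when assignments are given,
#'   `rel_tree_occupancy`.
#' @export
relative_covariates <- function(nights, assignments = NULL) {
  out <- nights
  center <- function(v, id) {
    mu <- tapply(v, id, mean, na.rm = TRUE)
    res <- v - as.numeric(mu[match(id, names(mu))])
    res[is.nan(res)] <- NA
    res
  }
  out$rel_tst <- center(nights$tst_min, nights$individual_id)
  out$rel_frag <- center(nights$fragmentation, nights$individual_id)
  if (!is.null(assignments)) {
    a <- assignments[!is.na(assignments$tree_id), ]
    key <- paste(a$night, a$tree_id)
    occ <- table(key)
    tot <- table(a$night)
    m <- match(paste(nights$night,
                     a$tree_id[match(paste(nights$individual_id,
                                           nights$night),
                                     paste(a$individual_id, a$night))]),
               names(occ))
    n_tree <- as.integer(occ[m])
    n_tot <- as.integer(tot[match(as.character(nights$night), names(tot))])
    out$rel_tree_occupancy <- n_tree / n_tot
  }
  out
}

#' Build the arousal-threshold design table
#'
#' One row per eligible focal epoch: the focal individual must have been
#' asleep for the three preceding epochs (epochs t-1, t-2, t-3 all
#' sleep), the epoch must lie in the nightly clock window (21:00-05:00),
#' and the night within the first `first_n_nights` nights. The outcome is
#' whether the focal is awake at t; the key predictor is whether any
#' same-tree group-mate (tracked, non-missing at t-1) was awake at t-1.
#' Rows where the predictor is undeterminable (focal alone in its tree,
#' or all tree-mates missing) are dropped.
#'
#' @param arr Epoch array (individuals x epochs x nights; 1 wake, 0
#'   sleep, NA missing) from [epoch_matrix()] or [truth_epoch_array()].
#'   The first three epochs of the window seed the eligibility filter
#'   only.
#' @param assignments Assignment table (`individual_id`, `night`,
#'   `tree_id`); NA-tree rows are ignored.
#' @param nights Optional night-metrics table; when given, previous-night
#'   relative covariates ([relative_covariates()]) are joined on.
#' @param first_n_nights Restrict to the first n nights (default 14).
#' @return Data frame `focal_id`, `night`, `epoch`, `awake`,
#'   `groupmate_awake_prev`, and when available `rel_tst_prev`,
#'   `rel_frag_prev`.
#' @export
build_arousal_table <- function(arr, assignments, nights = NULL,
                                first_n_nights = 14) {
  ids <- dimnames(arr)[[1]]
  night_ids <- as.integer(dimnames(arr)[[3]])
  keep_nights <- which(night_ids <= first_n_nights)
  rel <- NULL
  if (!is.null(nights)) rel <- relative_covariates(nights)
  out <- list()
  for (ni in keep_nights) {
    night <- night_ids[ni]
    tr <- assignments$tree_id[match(paste(ids, night),
                                    paste(assignments$individual_id,
                                          assignments$night))]
    for (f in seq_along(ids)) {
      if (is.na(tr[f])) next
      mates <- which(tr == tr[f] & seq_along(ids) != f)
      if (!length(mates)) next
      v <- arr[f, , ni]
      E <- length(v)
      t_cand <- 4:E
      elig <- v[t_cand - 1] == 0 & v[t_cand - 2] == 0 & v[t_cand - 3] == 0 &
        !is.na(v[t_cand])
      elig[is.na(elig)] <- FALSE
      tt <- t_cand[elig]
      if (!length(tt)) next
      mate_mat <- arr[mates, tt - 1, ni, drop = FALSE]
      dim(mate_mat) <- c(length(mates), length(tt))
      n_obs <- colSums(!is.na(mate_mat))
      any_awake <- colSums(mate_mat == 1L, na.rm = TRUE) > 0
      ok <- n_obs > 0
      if (!any(ok)) next
      df <- data.frame(
        focal_id = ids[f], night = night, epoch = tt[ok],
        awake = as.integer(v[tt[ok]] == 1L),
        groupmate_awake_prev = as.integer(any_awake[ok]))
      if (!is.null(rel)) {
        prev <- match(paste(ids[f], night - 1),
                      paste(rel$individual_id, rel$night))
        df$rel_tst_prev <- rel$rel_tst[prev]
        df$rel_frag_prev <- rel$rel_frag[prev]
      }
      out[[length(out) + 1L]] <- df
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(focal_id = character(), night = integer(),
                      epoch = integer(), awake = integer(),
                      groupmate_awake_prev = integer())
  }
  rownames(res) <- NULL
  res
}

#' Logistic stand-in model for the arousal-response analysis
#'
#' Fits an ordinary logistic regression of the focal's waking on the
#' group-mate-awake predictor and, when present, the previous-night
#' relative covariates and their interactions with the predictor, with
#' cluster-robust (by focal individual) standard errors. This is a fixed-
#' effects stand-in exposing the sign and significance surface of the
#' arousal-response analysis; it is not a mixed model.
#'
#' @param table An arousal table from [build_arousal_table()].
#' @return Data frame with `term`, `estimate`, `std_error`, `z`,
#'   `p_value`.
#' @export
fit_response_standin <- function(table) {
  if (!nrow(table) || length(unique(table$awake)) < 2) {
    stop("arousal table degenerate: both outcome classes required",
         call. = FALSE)
  }
  has_cov <- all(c("rel_tst_prev", "rel_frag_prev") %in% names(table)) &&
    any(!is.na(table$rel_tst_prev))
  fml <- if (has_cov) {
    awake ~ groupmate_awake_prev * rel_tst_prev +
      groupmate_awake_prev * rel_frag_prev
  } else {
    awake ~ groupmate_awake_prev
  }
  dat <- table[stats::complete.cases(table[, all.vars(fml)]), ]
  fit <- stats::glm(fml, family = stats::binomial(), data = dat)
  vc <- sandwich::vcovCL(fit, cluster = dat$focal_id)
  ct <- lmtest::coeftest(fit, vcov. = vc)
  data.frame(term = rownames(ct), estimate = ct[, 1], std_error = ct[, 2],
             z = ct[, 3], p_value = ct[, 4], row.names = NULL)
}
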