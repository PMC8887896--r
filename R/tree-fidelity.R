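# Sleep-tree fidelity: Shannon entropy of tree use against a within-night
# permutation null, one-tailed two-sample KS test, and fidelity indices.

#' Shannon entropy of sleep-tree usage
#'
#' `H = -sum(p * log(p))` in nats over trees with positive counts
#' (`0 * log(0)` taken as 0). Lower entropy means more concentrated (more
#' faithful) tree use.
#'
#' @param counts Non-negative integer vector of nights per tree (total
#'   > 0).
#' @return Entropy in nats.
#' @export
#' @examples
#' shannon_entropy(c(4, 0, 0, 0))      # 0: always the same tree
#' shannon_entropy(c(1, 1, 1, 1))      # log(4)
shannon_entropy <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- sum(counts)
  if (tot == 0) stop("total count must be positive", call. = FALSE)
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Permute nightly tree assignments within nights
#'
#' Generates permuted assignment sets by randomly exchanging the sleep
#' locations of the individuals present on each night: within every
#' night, the observed multiset of occupied tree slots is reassigned
#' uniformly at random among that night's individuals, so every
#' permutation preserves the empirical per-night tree occupancy exactly.
#'
#' @param assignments Data frame `individual_id`, `night`, `tree_id`
#'   (excluded/NA rows should be removed beforehand).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Character matrix `nrow(assignments) x n_perm` of permuted tree
#'   ids, rows aligned with `assignments`.
#' @export
permute_night_assignments <- function(assignments, n_perm = 1000,
                                      seed = 1L) {
  stopifnot(all(c("individual_id", "night", "tree_id") %in%
                  names(assignments)))
  if (anyNA(assignments$tree_id)) {
    stop("remove excluded (NA tree) rows before permuting", call. = FALSE)
  }
  n <- nrow(assignments)
  out <- matrix(NA_character_, n, n_perm)
  night_rows <- split(seq_len(n), assignments$night)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      for (rows in night_rows) {
        out[rows, p] <- assignments$tree_id[rows][
          sample.int(length(rows))]
      }
    }
  })
  out
}

#' One-tailed two-sample KS test for tree fidelity
#'
#' Compares empirical per-individual entropies to permuted entropies with
#' the alternative that empirical entropies are stochastically smaller
#' (lower entropy signals fidelity).
#'
#' @param empirical,permuted Numeric entropy samples (non-empty).
#' @return List `statistic`, `p_value`.
#' @export
fidelity_ks_test <- function(empirical, permuted) {
  if (!length(empirical) || !length(permuted)) {
    stop("both entropy samples must be non-empty", call. = FALSE)
  }
  ks <- suppressWarnings(
    stats::ks.test(empirical, permuted, alternative = "greater",
                   exact = FALSE))
  list(statistic = unname(ks$statistic), p_value = ks$p.value)
}

# entropy of each individual's tree usage for one assignment vector
entropies_by_individual <- function(ids, trees) {
  vapply(split(trees, ids), function(tr) {
    shannon_entropy(as.vector(table(tr)))
  }, numeric(1))
}

#' Sleep-tree fidelity test and fidelity indices
#'
#' Tests whether individuals reuse particular sleep trees more than
#' expected under random within-night reassignment. Each eligible
#' individual's empirical Shannon entropy of tree use is compared to the
#' pooled entropies from `n_perm` within-night permutations with a
#' one-tailed two-sample Kolmogorov-Smirnov test (alternative: empirical
#' entropies stochastically smaller, i.e. fidelity). Also returns the
#' fidelity index per individual and tree: observed nights in the tree
#' minus the mean permuted nights.
#'
#' @param assignments Data frame `individual_id`, `night`, `tree_id`;
#'   rows with `NA` tree are dropped.
#' @param n_perm Permutations (default 1000).
#' @param min_nights Minimum nights of data for an individual to enter
#'   the test or receive indices (default 4).
#' @param first_n_nights Restrict to the first n nights (default 14;
#'   `Inf` disables).
#' @param seed Integer seed (recorded in the report).
#' @param pooled If `TRUE` (default) the comparison sample pools permuted
#'   entropies over all individuals and permutation rounds; otherwise
#'   per-round group means are used.
#' @param compute_index If `FALSE`, skip the per-individual-per-tree
#'   fidelity indices (cheaper for bulk simulation runs).
#' @return List of class `fidelity_report`: `ks_statistic`, `p_value`,
#'   `empirical_entropies`, `permuted_entropies`, `fidelity_index` (data
#'   frame `individual_id`, `tree_id`, `observed_nights`,
#'   `expected_nights`, `index`), `eligible`, `n_perm`, `seed`.
#' @export
fidelity_test <- function(assignments, n_perm = 1000, min_nights = 4,
                          first_n_nights = 14, seed = 1L, pooled = TRUE,
                          compute_index = TRUE) {
  a <- assignments[!is.na(assignments$tree_id), ]
  a <- a[a$night <= first_n_nights, ]
  if (!nrow(a)) stop("no usable assignments", call. = FALSE)
  nights_per_ind <- table(a$individual_id)
  eligible <- names(nights_per_ind)[nights_per_ind >= min_nights]
  if (!length(eligible)) stop("no eligible individuals", call. = FALSE)
  perms <- permute_night_assignments(a, n_perm, seed)
  el <- a$individual_id %in% eligible
  emp <- entropies_by_individual(a$individual_id[el], a$tree_id[el])
  perm_ent <- matrix(NA_real_, length(eligible), n_perm,
                     dimnames = list(sort(eligible), NULL))
  for (p in seq_len(n_perm)) {
    perm_ent[, p] <- entropies_by_individual(a$individual_id[el],
                                             perms[el, p])
  }
  comparison <- if (pooled) as.vector(perm_ent) else colMeans(perm_ent)
  ks <- suppressWarnings(
    stats::ks.test(emp, comparison, alternative = "greater",
                   exact = FALSE))

  # fidelity index: observed minus permutation-mean nights per tree
  trees <- sort(unique(a$tree_id))
  idx_rows <- list()
  if (compute_index) for (id in sort(eligible)) {
    rows <- which(a$individual_id == id)
    obs <- table(factor(a$tree_id[rows], levels = trees))
    perm_counts <- matrix(0, length(trees), n_perm,
                          dimnames = list(trees, NULL))
    for (p in seq_len(n_perm)) {
      perm_counts[, p] <- table(factor(perms[rows, p], levels = trees))
    }
    expd <- rowMeans(perm_counts)
    idx_rows[[id]] <- data.frame(
      individual_id = id, tree_id = trees,
      observed_nights = as.integer(obs),
      expected_nights = as.numeric(expd),
      index = as.numeric(obs) - as.numeric(expd))
  }
  structure(
    list(ks_statistic = unname(ks$statistic), p_value = ks$p.value,
         empirical_entropies = emp, permuted_entropies = comparison,
         fidelity_index = if (length(idx_rows)) {
           do.call(rbind, c(idx_rows, make.row.names = FALSE))
         } else NULL,
         eligible = sort(eligible), n_perm = n_perm, seed = seed,
         pooled = pooled),
    class = "fidelity_report"
  )
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report>", length(x$eligible), "eligible individuals,",
      x$n_perm, "permutations\n")
  cat(sprintf("  one-tailed KS D = %.4f, p = %.4g\n", x$ks_statistic,
              x$p_value))
  invisible(x)
}
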