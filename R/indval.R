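#' Indicator value (IndVal) table: specificity x fidelity per taxon and group
#'
#' For taxon i and station group j,
#' \deqn{A_{ij} = Nindividuals_{ij} / Nindividuals_i, \quad
#'       B_{ij} = Nsite_{ij} / Nsite_j, \quad
#'       IndVal_{ij} = A_{ij} B_{ij} \times 100,}
#' where Nindividuals_ij is the mean abundance of taxon i over the sites of
#' group j (zero-abundance sites of the group included — the classical
#' Dufrene-Legendre mean), Nindividuals_i the sum of those group means over
#' all groups, Nsite_ij the number of group-j sites where the taxon is
#' present (abundance strictly > 0) and Nsite_j the group size.  A measures
#' site specificity (concentration of abundance in the group), B group
#' fidelity (how consistently the taxon occurs there).
#'
#' @param abund abundance matrix (stations x taxa).
#' @param partition named factor, station -> group; >= 2 non-empty groups
#'   covering all stations.
#' @return data.frame per (taxon, group): `n_individuals_ij`,
#'   `n_individuals_i`, `n_sites_ij`, `n_sites_j`, `A`, `B`, `indval`, and
#'   `all_zero` flagging taxa absent from every station (their IndVal is 0 in
#'   all groups by convention).
#' @export
indval_table <- function(abund, partition) {
  validate_abundance(abund)
  partition <- validate_partition(partition)
  validate_joint(abund, partition = partition)
  g <- droplevels(partition[rownames(abund)])
  if (nlevels(g) < 2L) stop("IndVal needs at least 2 groups")
  lv <- levels(g)
  nj <- table(g)
  # group means including zero-abundance sites, and presence counts
  mean_ij <- rowsum(abund, g) / as.vector(nj)           # groups x taxa
  pres_ij <- rowsum((abund > 0) + 0, g)                 # groups x taxa
  sum_i <- colSums(mean_ij)
  A <- sweep(mean_ij, 2L, ifelse(sum_i > 0, sum_i, 1), "/")
  A[, sum_i == 0] <- 0
  B <- sweep(pres_ij, 1L, as.vector(nj), "/")
  iv <- 100 * A * B
  out <- data.frame(
    taxon = rep(colnames(abund), each = length(lv)),
    group = rep(lv, times = ncol(abund)),
    n_individuals_ij = as.vector(mean_ij),
    n_individuals_i = rep(unname(sum_i), each = length(lv)),
    n_sites_ij = as.integer(pres_ij),
    n_sites_j = rep(as.integer(nj), times = ncol(abund)),
    A = as.vector(A), B = as.vector(B), indval = as.vector(iv),
    all_zero = rep(unname(sum_i) == 0, each = length(lv)),
    stringsAsFactors = FALSE)
  out
}

#' IndVal from group-mean abundances at stated fidelity
#'
#' Evaluates IndVal_ij = 100 * (m_j / sum(m)) * B_j directly from per-group
#' mean abundances.  This is the arithmetic needed to verify published IndVal
#' tables, where the per-group means are printed but the raw station data are
#' not: whenever a printed value implies presence at every site of the group,
#' fidelity is forced to 1 and IndVal follows from the means alone.
#'
#' @param means per-group mean abundances of one taxon (ind m^-3).
#' @param fidelity per-group fidelity B in [0, 1]; recycled (default 1).
#' @return per-group IndVal (%), same names as `means`.
#' @export
indval_from_means <- function(means, fidelity = 1) {
  if (any(!is.finite(means)) || any(means < 0))
    stop("group means must be finite and >= 0")
  if (any(fidelity < 0 | fidelity > 1)) stop("fidelity must lie in [0, 1]")
  tot <- sum(means)
  if (tot <= 0) return(setNames(rep(0, length(means)), names(means)))
  100 * (means / tot) * rep_len(fidelity, length(means))
}

#' Select indicator taxa above an IndVal threshold
#'
#' Strictly-greater-than comparison, following the convention that a taxon is
#' an indicator of a group when its IndVal there exceeds 50\%.
#'
#' @param iv IndVal table from [indval_table()].
#' @param threshold percent threshold in (0, 100); default 50.
#' @return data.frame of (group, taxon, indval) sorted by descending IndVal
#'   within group.
#' @export
select_indicators <- function(iv, threshold = 50) {
  if (!all(c("taxon", "group", "indval") %in% names(iv)))
    stop("iv must be an IndVal table")
  if (threshold <= 0 || threshold >= 100) stop("threshold must lie in (0, 100)")
  sel <- iv[iv$indval > threshold, c("group", "taxon", "indval")]
  sel <- sel[order(sel$group, -sel$indval), ]
  rownames(sel) <- NULL
  sel
}

max_indval_by_taxon <- function(abund, g, nj) {
  mean_ij <- rowsum(abund, g) / as.vector(nj)
  pres_ij <- rowsum((abund > 0) + 0, g)
  sum_i <- colSums(mean_ij)
  A <- sweep(mean_ij, 2L, ifelse(sum_i > 0, sum_i, 1), "/")
  A[, sum_i == 0] <- 0
  B <- sweep(pres_ij, 1L, as.vector(nj), "/")
  apply(100 * A * B, 2L, max)
}

#' Permutation p-values for IndVal
#'
#' Station group labels are permuted; for each (taxon, group) cell the
#' observed IndVal is compared against the permutation distribution of that
#' taxon's maximum IndVal over groups (the classical test statistic), with
#' the +1 conservative correction:
#' p = (1 + #\{permuted max >= observed\}) / (1 + n_perm).
#'
#' @inheritParams indval_table
#' @param n_perm number of label permutations (>= 99).
#' @param seed optional integer seed.
#' @return the IndVal table with an extra `p_value` column.
#' @export
indval_permutation_p <- function(abund, partition, n_perm = 999, seed = NULL) {
  if (n_perm < 99L) stop("use at least 99 permutations")
  if (!is.null(seed)) set.seed(seed)
  iv <- indval_table(abund, partition)
  g <- droplevels(validate_partition(partition)[rownames(abund)])
  nj <- table(g)
  null_max <- replicate(n_perm, max_indval_by_taxon(abund, sample(g), nj))
  if (is.null(dim(null_max))) null_max <- matrix(null_max, nrow = 1L)
  rownames(null_max) <- colnames(abund)
  obs <- iv$indval
  ge <- vapply(seq_len(nrow(iv)), function(r)
    sum(null_max[iv$taxon[r], ] >= obs[r]), numeric(1L))
  iv$p_value <- (1 + ge) / (1 + n_perm)
  iv
}

#' Consistency solver for published IndVal tables
#'
#' Published indicator tables print per-group mean abundances and IndVal but
#' rarely the group sizes or presence counts behind them.  Because fidelity
#' is a ratio of small integers, the printed values over-determine the
#' design: this solver brute-forces every composition of `total_stations`
#' into as many groups as the table has columns (each part >= `min_size`)
#' and, within each composition, the integer presence count 0..n_j that best
#' matches each printed IndVal.  The composition minimising the worst
#' absolute residual wins; residuals of a consistent table are bounded by
#' the rounding of the printed abundances.
#'
#' @param means matrix (taxa x groups) of printed per-group mean abundances;
#'   absent entries as 0.
#' @param printed matrix (taxa x groups) of printed IndVal; NA where the
#'   table prints none.
#' @param total_stations total number of stations behind the table.
#' @param min_size smallest admissible group size (default 2).
#' @param max_residual residual above which the table is declared
#'   inconsistent (default 1).
#' @return list: `sizes` (best composition), `presence` (taxa x groups
#'   integer counts under it), `max_residual`, `runner_up_residual`,
#'   `ambiguous` (TRUE when another composition ties to within 1e-9), and
#'   `recomputed` (taxa x groups IndVal under the solution).
#' @export
indval_consistency_solver <- function(means, printed, total_stations,
                                      min_size = 2L, max_residual = 1) {
  means <- as.matrix(means); printed <- as.matrix(printed)
  if (!all(dim(means) == dim(printed)))
    stop("means and printed must have matching dimensions")
  if (sum(!is.na(printed)) < 3L)
    stop("need at least 3 printed IndVal entries")
  G <- ncol(means)
  sums <- rowSums(means)
  A <- sweep(means, 1L, ifelse(sums > 0, sums, 1), "/")
  comps <- compositions_of(total_stations, G, min_size)
  score <- function(n) {
    worst <- 0
    for (i in seq_len(nrow(means))) for (j in seq_len(G)) {
      if (is.na(printed[i, j])) next
      r <- min(abs(100 * A[i, j] * (0:n[j]) / n[j] - printed[i, j]))
      worst <- max(worst, r)
    }
    worst
  }
  res <- vapply(comps, score, numeric(1L))
  ord <- order(res)
  best <- comps[[ord[1L]]]
  best_res <- res[ord[1L]]
  runner <- if (length(res) > 1L) res[ord[2L]] else NA_real_
  if (best_res >= max_residual)
    stop("no station composition reproduces the printed IndVal table ",
         "(best residual ", format(best_res, digits = 4), ")")
  presence <- matrix(NA_integer_, nrow(means), G,
                     dimnames = dimnames(means))
  recomputed <- matrix(NA_real_, nrow(means), G, dimnames = dimnames(means))
  for (i in seq_len(nrow(means))) for (j in seq_len(G)) {
    if (is.na(printed[i, j])) next
    k <- 0:best[j]
    vals <- 100 * A[i, j] * k / best[j]
    w <- which.min(abs(vals - printed[i, j]))
    presence[i, j] <- k[w]
    recomputed[i, j] <- vals[w]
  }
  list(sizes = best, presence = presence, max_residual = best_res,
       runner_up_residual = runner,
       ambiguous = is.finite(runner) && (runner - best_res) < 1e-9,
       recomputed = recomputed)
}

compositions_of <- function(total, parts, min_size) {
  if (parts == 1L) {
    if (total >= min_size) return(list(total)) else return(list())
  }
  out <- list()
  for (first in min_size:(total - min_size * (parts - 1L))) {
    for (rest in compositions_of(total - first, parts - 1L, min_size))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}
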