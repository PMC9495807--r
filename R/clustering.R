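env_numeric <- function(env) {
  m <- as.matrix(env[, c("temperature", "salinity", "dissolved_oxygen", "pH")])
  rownames(m) <- env$station
  m
}

#' Bray-Curtis dissimilarity between stations on hydrographic variables
#'
#' d(a, b) = sum_v |a_v - b_v| / sum_v (a_v + b_v) over temperature, salinity,
#' dissolved oxygen and pH in raw units.  Raw units are the default on
#' purpose: on sea-surface profiles the shared magnitudes (salinity ~34,
#' temperature ~20-27) compress dissimilarities to a few percent, which is
#' exactly the 97-99\% similarity scale reported for such surveys.  Set
#' `standardize = TRUE` to range-standardise each variable to [0, 1] first
#' (keeps values non-negative, weights variables equally) when the raw scale
#' is not meaningful.
#'
#' @param env environment table ([validate_env()]).
#' @param standardize range-standardise variables before the distance.
#' @return a `dist` object of Bray-Curtis dissimilarities in [0, 1], station
#'   ids as labels.
#' @export
env_dissimilarity <- function(env, standardize = FALSE) {
  validate_env(env)
  m <- env_numeric(env)
  if (any(m < 0))
    stop("Bray-Curtis needs non-negative variables; shift or standardize ",
         "explicitly (standardize = TRUE)")
  if (standardize) {
    rng <- apply(m, 2L, function(v) diff(range(v)))
    rng[rng == 0] <- 1
    m <- sweep(sweep(m, 2L, apply(m, 2L, min)), 2L, rng, "/")
  }
  vegan::vegdist(m, method = "bray")
}

#' Percent similarity from a dissimilarity
#' @param d `dist` of Bray-Curtis dissimilarities in [0, 1].
#' @return `dist` of similarities, percent scale: `100 * (1 - d)`.
#' @export
similarity_percent <- function(d) 100 * (1 - d)

#' Complete-linkage agglomerative clustering of stations
#'
#' @param d `dist` of station dissimilarities (from [env_dissimilarity()]).
#' @return an `hclust` tree; merge heights equal the maximum within-cluster
#'   pairwise dissimilarity at each merge.
#' @export
cluster_env <- function(d) {
  if (!inherits(d, "dist")) stop("d must be a dist object")
  if (attr(d, "Size") < 2L) stop("clustering needs at least 2 stations")
  hclust(d, method = "complete")
}

#' Cut a station dendrogram into labelled water-mass groups
#'
#' Cuts the complete-linkage tree at `k` groups and names them "A", "B",
#' ... in order of descending group-mean dissolved oxygen, so that "A" is
#' the coldest, most oxygenated (monsoon-derived) water and the last letter
#' the warmest, least oxygenated (oceanic intrusion) water.  Without an
#' environment table groups are named in dendrogram order.
#'
#' @param tree `hclust` tree from [cluster_env()].
#' @param k number of groups (1 <= k <= n stations).
#' @param env optional environment table used for the DO-based labelling.
#' @return named factor, station -> group label.
#' @export
cut_partition <- function(tree, k, env = NULL) {
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k must lie in 1..n stations")
  raw <- cutree(tree, k = k)
  if (!is.null(env)) {
    validate_env(env)
    do <- setNames(env$dissolved_oxygen, env$station)[names(raw)]
    mean_do <- tapply(do, raw, mean)
    ord <- order(-mean_do)
  } else {
    ord <- seq_len(k)
  }
  labels <- setNames(LETTERS[seq_len(k)], as.character(ord))
  validate_partition(setNames(labels[as.character(raw)], names(raw)))
}

#' Mean within-group percent similarity
#'
#' @param d `dist` of station dissimilarities.
#' @param partition named factor, station -> group.
#' @return data.frame per group: `n_stations`, `similarity` (mean of all
#'   within-group pairwise percent similarities), and `singleton` flagging
#'   groups of one station, whose similarity is reported as 100 by
#'   convention.
#' @export
group_similarity <- function(d, partition) {
  partition <- validate_partition(partition)
  s <- as.matrix(similarity_percent(d))
  miss <- setdiff(names(partition), rownames(s))
  if (length(miss)) stop("stations absent from distance: ",
                         paste(miss, collapse = ", "))
  grp <- levels(partition)
  res <- lapply(grp, function(g) {
    st <- names(partition)[partition == g]
    if (length(st) == 1L)
      return(data.frame(group = g, n_stations = 1L, similarity = 100,
                        singleton = TRUE))
    sub <- s[st, st]
    data.frame(group = g, n_stations = length(st),
               similarity = mean(sub[lower.tri(sub)]), singleton = FALSE)
  })
  do.call(rbind, res)
}

#' Similarity-profile (SIMPROF) permutation test of multivariate structure
#'
#' Tests whether a set of stations carries more internal structure than
#' expected if the hydrographic variables were independent of station
#' identity.  The statistic is Clarke's pi: the ordered observed pairwise
#' percent similarities are compared rank by rank with their mean profile
#' under permutations that shuffle each variable independently across
#' stations, and pi sums the absolute rank-wise departures.  Significance
#' comes from a second, independent set of permutations.
#'
#' @param env environment table.
#' @param stations subset of station ids to test (default: all); at least 3.
#' @param n_perm_expected permutations used to build the mean (expected)
#'   similarity profile.
#' @param n_perm_test permutations used for the null distribution of pi.
#' @param standardize passed to [env_dissimilarity()].
#' @param seed optional integer seed for reproducibility.
#' @return list with `pi` (observed statistic, percent-similarity scale),
#'   `p_value` (with +1 conservative correction), `n_stations`, and the
#'   permutation counts.
#' @export
simprof <- function(env, stations = NULL, n_perm_expected = 499,
                    n_perm_test = 499, standardize = FALSE, seed = NULL) {
  validate_env(env)
  if (is.null(stations)) stations <- env$station
  if (length(stations) < 3L) stop("SIMPROF needs at least 3 stations")
  sub <- env[match(stations, env$station), ]
  if (anyNA(sub$station)) stop("unknown station id in subset")
  if (!is.null(seed)) set.seed(seed)
  m <- env_numeric(sub)
  n <- nrow(m)
  profile_of <- function(mat) {
    d <- vegan::vegdist(mat, method = "bray")
    sort(as.numeric(similarity_percent(d)))
  }
  shuffle <- function(mat) apply(mat, 2L, sample)
  obs <- profile_of(m)
  exp_profiles <- replicate(n_perm_expected, profile_of(shuffle(m)))
  expected <- rowMeans(exp_profiles)
  pi_obs <- sum(abs(obs - expected))
  pi_null <- replicate(n_perm_test,
                       sum(abs(profile_of(shuffle(m)) - expected)))
  p <- (1 + sum(pi_null >= pi_obs)) / (1 + n_perm_test)
  list(pi = pi_obs, p_value = p, n_stations = n,
       n_perm_expected = n_perm_expected, n_perm_test = n_perm_test)
}

#' SIMPROF applied to every group of a partition
#'
#' Groups with fewer than 3 stations are reported with NA statistics (the
#' test is undefined there).
#'
#' @inheritParams simprof
#' @param partition named factor, station -> group.
#' @return data.frame per group: `n_stations`, `pi`, `p_value`.
#' @export
simprof_by_group <- function(env, partition, n_perm_expected = 499,
                             n_perm_test = 499, standardize = FALSE,
                             seed = NULL) {
  partition <- validate_partition(partition)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(levels(partition), function(g) {
    st <- names(partition)[partition == g]
    if (length(st) < 3L)
      return(data.frame(group = g, n_stations = length(st), pi = NA_real_,
                        p_value = NA_real_))
    r <- simprof(env, st, n_perm_expected, n_perm_test, standardize,
                 seed = NULL)
    data.frame(group = g, n_stations = r$n_stations, pi = r$pi,
               p_value = r$p_value)
  })
  do.call(rbind, out)
}
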