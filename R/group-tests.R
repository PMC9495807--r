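#' Per-station total abundance
#'
#' @param abund abundance matrix (stations x taxa).
#' @return named numeric vector, total ind m^-3 per station.
#' @export
station_totals <- function(abund) {
  validate_abundance(abund)
  rowSums(abund)
}

check_groups <- function(values, partition) {
  partition <- validate_partition(partition)
  if (is.null(names(values))) stop("values must be named by station id")
  miss <- setdiff(names(values), names(partition))
  if (length(miss)) stop("stations missing from partition: ",
                         paste(miss, collapse = ", "))
  g <- partition[names(values)]
  if (nlevels(droplevels(g)) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L))
    stop("every group needs at least 2 stations for the variance decomposition")
  droplevels(g)
}

#' One-way ANOVA of station values across water-mass groups
#'
#' Classical between/within sum-of-squares decomposition via [stats::aov()];
#' the p-value comes from the F distribution.
#'
#' @param values per-station numeric values (e.g. [station_totals()]), named
#'   by station id.
#' @param partition named factor, station -> group; each group needs >= 2
#'   stations.
#' @return list of class `anova_groups`: `F`, `df` (between, within),
#'   `p_value`, `ss_between`, `ss_within`, and per-group `means`/`sds`/`n`.
#' @export
oneway_anova <- function(values, partition) {
  g <- check_groups(values, partition)
  fit <- aov(values ~ g, data = data.frame(values = as.numeric(values), g = g))
  tab <- summary(fit)[[1L]]
  out <- list(F = tab[1L, "F value"],
              df = c(between = tab[1L, "Df"], within = tab[2L, "Df"]),
              p_value = tab[1L, "Pr(>F)"],
              ss_between = tab[1L, "Sum Sq"],
              ss_within = tab[2L, "Sum Sq"],
              means = tapply(as.numeric(values), g, mean),
              sds = tapply(as.numeric(values), g, sd),
              n = tapply(as.numeric(values), g, length))
  # identical group means give F = 0 whose upper-tail p is exactly 1
  if (out$ss_between == 0) { out$F <- 0; out$p_value <- 1 }
  class(out) <- "anova_groups"
  out
}

#' Tukey HSD pairwise contrasts (Tukey-Kramer for unequal group sizes)
#'
#' Adjusted p-values come from the studentized-range distribution
#' ([stats::ptukey()]); the q statistic uses the Tukey-Kramer standard error
#' sqrt(MSW * (1/n_j + 1/n_k) / 2), so unbalanced groups are handled.
#' Zero within-group variance with unequal means is a degenerate boundary:
#' q is infinite and the adjusted p is reported as 0 with `boundary = TRUE`.
#'
#' @inheritParams oneway_anova
#' @return data.frame per group pair: `diff` (mean difference), `q`,
#'   `p_adj`, `boundary`.
#' @export
tukey_hsd <- function(values, partition) {
  g <- check_groups(values, partition)
  v <- as.numeric(values)
  an <- oneway_anova(values, partition)
  msw <- an$ss_within / an$df[["within"]]
  # exact-replicate groups: SSW is zero up to rounding of the group means
  if (an$ss_within <= 1e-12 * (an$ss_within + an$ss_between)) msw <- 0
  lv <- levels(g)
  pairs <- utils::combn(lv, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    na <- an$n[[a]]; nb <- an$n[[b]]
    dif <- an$means[[b]] - an$means[[a]]
    se <- sqrt(msw * (1 / na + 1 / nb) / 2)
    if (se == 0) {
      q <- if (dif == 0) 0 else Inf
      p <- if (dif == 0) 1 else 0
      boundary <- dif != 0
    } else {
      q <- abs(dif) / se
      p <- ptukey(q, nmeans = length(lv), df = an$df[["within"]],
                  lower.tail = FALSE)
      boundary <- FALSE
    }
    data.frame(pair = paste(b, a, sep = "-"), diff = dif, q = q, p_adj = p,
               boundary = boundary, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
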