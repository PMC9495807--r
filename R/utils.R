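#' Rand index between two partitions of the same stations
#'
#' Fraction of station pairs on which the two partitions agree (same group in
#' both, or different groups in both).  1 means identical partitions up to
#' label names.
#'
#' @param p1,p2 named group assignments covering the same stations.
#' @return Rand index in [0, 1].
#' @export
rand_index <- function(p1, p2) {
  p1 <- validate_partition(p1)
  p2 <- validate_partition(p2)
  st <- names(p1)
  if (!setequal(st, names(p2))) stop("partitions cover different stations")
  a <- as.integer(p1[st]); b <- as.integer(p2[st])
  n <- length(st)
  agree <- 0L
  for (i in seq_len(n - 1L)) {
    same1 <- a[i] == a[(i + 1L):n]
    same2 <- b[i] == b[(i + 1L):n]
    agree <- agree + sum(same1 == same2)
  }
  agree / (n * (n - 1L) / 2)
}
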