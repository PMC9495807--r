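#' Relative abundance (percent of a total)
#'
#' The ratio convention used throughout: a mean abundance expressed as a
#' percentage of the summed mean abundances.  Exposed on its own because the
#' same arithmetic verifies published dominance tables, where the grand total
#' is printed with its own rounding.
#'
#' @param ma mean abundance(s), ind m^-3.
#' @param total total mean abundance; defaults to `sum(ma)`.
#' @return percentage(s), `100 * ma / total`.
#' @export
relative_abundance <- function(ma, total = sum(ma)) {
  if (!is.numeric(ma) || any(!is.finite(ma)) || any(ma < 0))
    stop("mean abundances must be finite and >= 0")
  if (!is.finite(total) || total <= 0)
    stop("total mean abundance must be > 0 (all-zero community has no ",
         "defined relative abundance)")
  100 * ma / total
}

#' Dominance table: mean abundance, relative abundance, occurrence rate
#'
#' Per taxon: MA = mean abundance over stations (ind m^-3); RA = 100 * MA /
#' sum of all MAs; OR = percentage of stations where the taxon is present
#' (abundance strictly > 0).  RA is defined from station-averaged abundances
#' (ratio of MAs), not as a per-station RA averaged over stations — the two
#' differ, and only the former matches the arithmetic of published dominance
#' tables.
#'
#' @param abund abundance matrix (stations x taxa).
#' @return data.frame with columns `taxon`, `MA`, `RA`, `OR`, ordered as the
#'   matrix columns; the total mean abundance is attached as attribute
#'   `total_mean_abundance`.
#' @export
dominance_table <- function(abund) {
  validate_abundance(abund)
  ma <- colMeans(abund)
  total <- sum(ma)
  ra <- relative_abundance(ma, total)
  or <- 100 * colSums(abund > 0) / nrow(abund)
  out <- data.frame(taxon = colnames(abund), MA = unname(ma), RA = unname(ra),
                    OR = unname(or), stringsAsFactors = FALSE)
  attr(out, "total_mean_abundance") <- total
  out
}

#' Order-level community composition
#'
#' Species counts exclude copepodite categories (juveniles are not identified
#' species); abundance sums include every taxon of the order, copepodites
#' counted within their order.
#'
#' @param abund abundance matrix (stations x taxa).
#' @param taxa taxon metadata mapping each column to an order and a
#'   copepodite flag.
#' @return data.frame per order: `n_species`, `species_share` (%),
#'   `mean_abundance` (summed MA, ind m^-3), `abundance_share` (%).
#' @export
order_composition <- function(abund, taxa) {
  validate_joint(abund, taxa = taxa)
  meta <- taxa[match(colnames(abund), taxa$taxon), ]
  ma <- colMeans(abund)
  ords <- intersect(copepod_orders(), unique(meta$order))
  n_sp <- vapply(ords, function(o)
    sum(meta$order == o & !meta$is_copepodite), integer(1L))
  ab <- vapply(ords, function(o) sum(ma[meta$order == o]), numeric(1L))
  if (sum(n_sp) == 0L) stop("no identified species (all taxa are copepodites)")
  total_ab <- sum(ab)
  if (total_ab <= 0) stop("all-zero community has no composition")
  data.frame(order = ords,
             n_species = n_sp,
             species_share = 100 * n_sp / sum(n_sp),
             mean_abundance = ab,
             abundance_share = relative_abundance(ab, total_ab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dominant taxa by relative abundance
#'
#' @param dom dominance table from [dominance_table()].
#' @param ra_threshold keep taxa with RA >= this percentage (default 2, the
#'   conventional dominance cut for these communities).
#' @param top_n if given, overrides the threshold and returns the `top_n`
#'   taxa by RA.
#' @return the selected rows, ordered by descending RA.
#' @export
dominant_taxa <- function(dom, ra_threshold = 2, top_n = NULL) {
  if (!all(c("taxon", "RA") %in% names(dom)))
    stop("dom must be a dominance table with columns taxon and RA")
  if (!is.null(top_n)) {
    ord <- order(-dom$RA)
    out <- dom[ord, ][seq_len(min(top_n, nrow(dom))), ]
  } else {
    if (!is.numeric(ra_threshold) || ra_threshold <= 0 || ra_threshold > 100)
      stop("ra_threshold must lie in (0, 100]")
    out <- dom[dom$RA >= ra_threshold, ]
    out <- out[order(-out$RA), ]
  }
  rownames(out) <- NULL
  out
}
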