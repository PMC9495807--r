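#' Validate a station-by-taxon abundance matrix
#'
#' The abundance matrix is the central community object: stations as rows,
#' taxa as columns, values in individuals per cubic metre.  Plain numeric
#' matrices are used throughout (vegan convention); this validator enforces
#' the invariants every downstream function assumes.
#'
#' @param x numeric matrix, stations in rows (rownames = station ids), taxa in
#'   columns (colnames = taxon ids), abundances in ind m^-3.
#' @return `x`, invisibly, after validation.
#' @export
validate_abundance <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("abundance must be a numeric matrix (stations x taxa)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance matrix needs station rownames and taxon colnames")
  if (nrow(x) < 2L) stop("abundance matrix needs at least 2 stations")
  if (ncol(x) < 1L) stop("abundance matrix needs at least 1 taxon")
  if (anyDuplicated(rownames(x)))
    stop("duplicate station ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("abundance must be finite and >= 0; first offending cell: station '",
         rownames(x)[bad[1L, 1L]], "', taxon '", colnames(x)[bad[1L, 2L]], "'")
  invisible(x)
}

#' Validate a station environment table
#'
#' @param env data.frame with columns `station`, `temperature` (deg C),
#'   `salinity` (PSU), `dissolved_oxygen` (mg/L), `pH`.
#' @return `env`, invisibly, after validation.
#' @export
validate_env <- function(env) {
  need <- c("station", "temperature", "salinity", "dissolved_oxygen", "pH")
  if (!is.data.frame(env) || !all(need %in% names(env)))
    stop("environment table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(env$station))
    stop("duplicate station ids in environment table: ",
         paste(unique(env$station[duplicated(env$station)]), collapse = ", "))
  num <- env[, need[-1L]]
  if (!all(vapply(num, is.numeric, logical(1L))) ||
      !all(vapply(num, function(v) all(is.finite(v)), logical(1L))))
    stop("environment values must be finite numerics (missing cells are an error)")
  if (any(env$temperature <= 0))
    stop("temperature must be > 0 degrees C in this domain")
  if (any(env$salinity <= 0)) stop("salinity must be > 0 PSU")
  if (any(env$dissolved_oxygen <= 0)) stop("dissolved oxygen must be > 0 mg/L")
  if (any(env$pH <= 0 | env$pH >= 14)) stop("pH must lie in (0, 14)")
  invisible(env)
}

#' Recognised copepod orders
#' @export
copepod_orders <- function() {
  c("Calanoida", "Cyclopoida", "Harpacticoida", "Poecilostomatoida")
}

#' Validate a taxon metadata table
#'
#' Maps every taxon to its copepod order and flags copepodite (juvenile)
#' categories, which count toward abundance but not toward species number.
#'
#' @param taxa data.frame with columns `taxon`, `order`, `is_copepodite`.
#' @return `taxa`, invisibly, after validation.
#' @export
validate_taxa <- function(taxa) {
  need <- c("taxon", "order", "is_copepodite")
  if (!is.data.frame(taxa) || !all(need %in% names(taxa)))
    stop("taxon table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(taxa$taxon))
    stop("duplicate taxon ids in taxon table: ",
         paste(unique(taxa$taxon[duplicated(taxa$taxon)]), collapse = ", "))
  bad <- setdiff(unique(taxa$order), copepod_orders())
  if (length(bad) > 0L)
    stop("unknown copepod order(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(copepod_orders(), collapse = ", "), ")")
  if (!is.logical(taxa$is_copepodite) || anyNA(taxa$is_copepodite))
    stop("is_copepodite must be TRUE/FALSE with no missing values")
  invisible(taxa)
}

#' Validate a station partition into groups
#'
#' @param partition factor (or character) of group labels named by station id.
#' @return the partition as a named factor, after validation.
#' @export
validate_partition <- function(partition) {
  if (is.null(names(partition)) || anyDuplicated(names(partition)))
    stop("partition must be named by unique station ids")
  nm <- names(partition)
  partition <- factor(as.character(partition), exclude = NULL)
  names(partition) <- nm
  if (anyNA(partition)) stop("every station must be assigned to a group")
  if (any(table(partition) == 0L)) stop("every group must be non-empty")
  partition
}

#' Stations per group
#'
#' @param partition named factor, station -> group label.
#' @return named integer vector of group sizes.
#' @export
group_sizes <- function(partition) {
  partition <- validate_partition(partition)
  tab <- table(partition)
  setNames(as.integer(tab), names(tab))
}

#' Check that paired tables describe the same stations / taxa
#'
#' Joint validation for an abundance matrix used together with an environment
#' table (same station set) or a taxon table (every column mapped).
#'
#' @param abund abundance matrix (stations x taxa).
#' @param env optional environment table.
#' @param taxa optional taxon metadata table.
#' @param partition optional named partition covering the stations.
#' @return TRUE invisibly, or an error naming the mismatch.
#' @export
validate_joint <- function(abund, env = NULL, taxa = NULL, partition = NULL) {
  validate_abundance(abund)
  st <- rownames(abund)
  if (!is.null(env)) {
    validate_env(env)
    miss <- setdiff(st, env$station)
    extra <- setdiff(env$station, st)
    if (length(miss) || length(extra))
      stop("station sets differ between abundance and environment tables",
           if (length(miss)) paste0("; missing from env: ",
                                    paste(miss, collapse = ", ")),
           if (length(extra)) paste0("; absent from abundance: ",
                                     paste(extra, collapse = ", ")))
  }
  if (!is.null(taxa)) {
    validate_taxa(taxa)
    um <- setdiff(colnames(abund), taxa$taxon)
    if (length(um))
      stop("taxa without metadata: ", paste(um, collapse = ", "))
  }
  if (!is.null(partition)) {
    partition <- validate_partition(partition)
    miss <- setdiff(st, names(partition))
    if (length(miss))
      stop("stations missing from partition: ", paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
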