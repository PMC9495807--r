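# CSV dialect: comma-separated, UTF-8, '.' decimal, mandatory header.
# Numbers are written with 17 significant digits so read(write(x)) == x
# exactly; missing cells are an error, never imputed.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  ints <- is.finite(x) & x == round(x) & abs(x) < 1e15
  out[ints] <- sprintf("%.0f", x[ints])
  out
}

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
           encoding = "UTF-8")
}

#' Read a station-by-taxon abundance CSV
#'
#' First column holds the station id, remaining columns one taxon each
#' (header row = taxon names), numeric body in ind m^-3.  Row and column
#' order are preserved as read.
#'
#' @param path path to a CSV file.
#' @return validated numeric abundance matrix (stations x taxa).
#' @export
read_abundance <- function(path) {
  df <- read_csv_strict(path)
  if (ncol(df) < 2L) stop("abundance CSV needs a station column plus taxa")
  stations <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("non-numeric abundance at station '", stations[bad],
           "', taxon '", names(body)[j], "'")
    }
  }
  x <- as.matrix(body)
  rownames(x) <- stations
  validate_abundance(x)
  x
}

#' Write a station-by-taxon abundance CSV
#'
#' @param x validated abundance matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path) {
  validate_abundance(x)
  header <- paste(c("station", colnames(x)), collapse = ",")
  rows <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], fmt_num(x[i, ])), collapse = ","), character(1L))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a station environment CSV
#'
#' Columns: station, temperature (deg C), salinity (PSU), dissolved_oxygen
#' (mg/L), pH.
#'
#' @param path path to a CSV file.
#' @return validated environment data.frame.
#' @export
read_env <- function(path) {
  df <- read_csv_strict(path)
  df$station <- as.character(df$station)
  validate_env(df)
  df
}

#' Write a station environment CSV
#' @param env validated environment table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_env <- function(env, path) {
  validate_env(env)
  cols <- c("temperature", "salinity", "dissolved_oxygen", "pH")
  header <- paste(c("station", cols), collapse = ",")
  rows <- vapply(seq_len(nrow(env)), function(i)
    paste(c(env$station[i], fmt_num(unlist(env[i, cols]))), collapse = ","),
    character(1L))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a taxon metadata CSV
#'
#' Columns: taxon, order (one of the four copepod orders), is_copepodite
#' (true/false).
#'
#' @param path path to a CSV file.
#' @return validated taxon metadata data.frame.
#' @export
read_taxa <- function(path) {
  df <- read_csv_strict(path)
  if (!all(c("taxon", "order", "is_copepodite") %in% names(df)))
    stop("taxon CSV needs columns: taxon, order, is_copepodite")
  df$taxon <- as.character(df$taxon)
  df$order <- as.character(df$order)
  if (is.character(df$is_copepodite))
    df$is_copepodite <- tolower(df$is_copepodite) %in% c("true", "t", "1") &
      !is.na(df$is_copepodite)
  if (is.numeric(df$is_copepodite)) df$is_copepodite <- df$is_copepodite != 0
  validate_taxa(df)
  df
}

#' Write a taxon metadata CSV
#' @param taxa validated taxon table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxa <- function(taxa, path) {
  validate_taxa(taxa)
  header <- "taxon,order,is_copepodite"
  rows <- paste(taxa$taxon, taxa$order,
                ifelse(taxa$is_copepodite, "true", "false"), sep = ",")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a station partition CSV (columns: station, group)
#' @param path path to a CSV file.
#' @return named factor, station -> group.
#' @export
read_partition <- function(path) {
  df <- read_csv_strict(path)
  if (!all(c("station", "group") %in% names(df)))
    stop("partition CSV needs columns: station, group")
  validate_partition(setNames(as.character(df$group), as.character(df$station)))
}

#' Write a station partition CSV
#' @param partition named factor, station -> group.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  partition <- validate_partition(partition)
  writeLines(c("station,group",
               paste(names(partition), as.character(partition), sep = ",")),
             path, useBytes = TRUE)
  invisible(path)
}
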