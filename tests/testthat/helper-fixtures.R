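# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdirs.

make_abund <- function(values, stations = NULL, taxa = NULL) {
  x <- as.matrix(values)
  rownames(x) <- stations %||% sprintf("st%02d", seq_len(nrow(x)))
  colnames(x) <- taxa %||% sprintf("sp%02d", seq_len(ncol(x)))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_env <- function(temperature, salinity = 34.2, dissolved_oxygen = 6.9,
                     pH = 8.36, stations = NULL) {
  n <- length(temperature)
  data.frame(station = stations %||% sprintf("st%02d", seq_len(n)),
             temperature = temperature,
             salinity = rep_len(salinity, n),
             dissolved_oxygen = rep_len(dissolved_oxygen, n),
             pH = rep_len(pH, n), stringsAsFactors = FALSE)
}

# well-separated hydrographic profiles: same group means as the survey, SDs
# shrunk so the between-group gaps are ~8 SD on temperature (the clustering
# property's separation premise comfortably satisfied)
separated_profiles <- function(factor = 1 / 3) {
  prof <- survey_env_profiles()
  for (col in grep("_sd$", names(prof), value = TRUE))
    prof[[col]] <- prof[[col]] * factor
  prof
}

default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_community(synthetic_design(seed = 1L))
    cache
  }
})

# partition helper for hand-built matrices
make_partition <- function(labels, stations) {
  validate_partition(setNames(labels, stations))
}
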