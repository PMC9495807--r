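#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated list.
#' `abundance`, `env` and `taxa` may be in-memory objects or CSV paths.
#'
#' @param abundance abundance matrix or CSV path.
#' @param env environment table or CSV path.
#' @param taxa taxon metadata table or CSV path.
#' @param out_dir output directory for all result files.
#' @param k number of station groups to cut (default 3).
#' @param ra_threshold dominance cut in percent RA (default 2).
#' @param indval_threshold indicator selection threshold in percent
#'   (default 50, strict inequality).
#' @param n_perm permutations for SIMPROF and IndVal inference (default 199;
#'   set 0 to skip permutation inference).
#' @param seed integer seed driving all randomness (recorded in the report).
#' @param standardize_env range-standardise hydrographic variables before
#'   Bray-Curtis (default FALSE: raw units).
#' @param scale_species,hellinger passed to [fit_rda()].
#' @return list of class `run_config`.
#' @export
run_config <- function(abundance, env, taxa, out_dir, k = 3L,
                       ra_threshold = 2, indval_threshold = 50,
                       n_perm = 199L, seed = 1L, standardize_env = FALSE,
                       scale_species = FALSE, hellinger = FALSE) {
  if (k < 1L) stop("k must be >= 1")
  if (ra_threshold <= 0 || ra_threshold > 100)
    stop("ra_threshold must lie in (0, 100]")
  if (indval_threshold <= 0 || indval_threshold >= 100)
    stop("indval_threshold must lie in (0, 100)")
  if (n_perm < 0) stop("n_perm must be >= 0")
  structure(list(abundance = abundance, env = env, taxa = taxa,
                 out_dir = out_dir, k = as.integer(k),
                 ra_threshold = ra_threshold,
                 indval_threshold = indval_threshold,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 standardize_env = isTRUE(standardize_env),
                 scale_species = isTRUE(scale_species),
                 hellinger = isTRUE(hellinger)),
            class = "run_config")
}

#' Read a flat YAML configuration file
#'
#' Keys mirror the arguments of [run_config()]; command-line or call-site
#' overrides win over file values.
#'
#' @param path YAML file of flat key/value pairs.
#' @param ... overrides passed on to [run_config()].
#' @return list of class `run_config`.
#' @export
load_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

hclust_newick <- function(tree) {
  m <- tree$merge; h <- tree$height; labs <- tree$labels
  child_height <- function(i) if (i < 0) 0 else h[i]
  node <- function(i) {
    if (i < 0) return(labs[-i])
    l <- m[i, 1L]; r <- m[i, 2L]
    sprintf("(%s:%.10g,%s:%.10g)", node(l), h[i] - child_height(l),
            node(r), h[i] - child_height(r))
  }
  paste0(node(nrow(m)), ";")
}

write_result_csv <- function(df, dir, name) {
  write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
}

scores_to_df <- function(m, idcol) {
  df <- data.frame(rownames(m), as.data.frame(m), row.names = NULL)
  names(df) <- c(idcol, colnames(m))
  df
}

#' Run the full water-mass indicator analysis
#'
#' Executes the stages in survey order — community dominance statistics,
#' Bray-Curtis environmental clustering with SIMPROF, one-way ANOVA with
#' Tukey HSD on station totals, IndVal indicator selection, and the
#' DCA-gated RDA of dominant taxa on environment — writing each stage's CSV
#' outputs, a machine-readable `summary.json` and a run log into
#' `config$out_dir`.  A stage failure aborts with a stage-tagged message;
#' outputs of completed stages are retained.  Fully deterministic under the
#' configured seed (reruns produce byte-identical CSV and JSON outputs; only
#' the log carries timestamps).
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...,
                               "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logline("copindval ", as.character(packageVersion("copindval")),
          " | R ", paste(R.version$major, R.version$minor, sep = "."),
          " | seed ", config$seed)
  stage <- function(name, expr) {
    logline("stage ", name, " start")
    out <- tryCatch(expr, error = function(e) {
      logline("stage ", name, " FAILED: ", conditionMessage(e))
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
    logline("stage ", name, " done")
    out
  }
  set.seed(config$seed)

  inp <- stage("input", {
    abund <- if (is.character(config$abundance)) read_abundance(config$abundance) else config$abundance
    env <- if (is.character(config$env)) read_env(config$env) else config$env
    taxa <- if (is.character(config$taxa)) read_taxa(config$taxa) else config$taxa
    validate_joint(abund, env = env, taxa = taxa)
    env <- env[match(rownames(abund), env$station), ]
    list(abund = abund, env = env, taxa = taxa)
  })

  comm <- stage("community", {
    dom <- dominance_table(inp$abund)
    comp <- order_composition(inp$abund, inp$taxa)
    dtx <- dominant_taxa(dom, ra_threshold = config$ra_threshold)
    write_result_csv(dom, config$out_dir, "dominance.csv")
    write_result_csv(comp, config$out_dir, "order_composition.csv")
    write_result_csv(dtx, config$out_dir, "dominant_taxa.csv")
    list(dom = dom, comp = comp, dominant = dtx)
  })

  clus <- stage("cluster", {
    d <- env_dissimilarity(inp$env, standardize = config$standardize_env)
    tree <- cluster_env(d)
    part <- cut_partition(tree, config$k, inp$env)
    gsim <- group_similarity(d, part)
    sprof <- if (config$n_perm > 0)
      simprof_by_group(inp$env, part, n_perm_expected = config$n_perm,
                       n_perm_test = config$n_perm,
                       standardize = config$standardize_env)
    else NULL
    write_partition(part, file.path(config$out_dir, "partition.csv"))
    write_result_csv(gsim, config$out_dir, "group_similarity.csv")
    if (!is.null(sprof)) write_result_csv(sprof, config$out_dir, "simprof.csv")
    writeLines(hclust_newick(tree), file.path(config$out_dir, "dendrogram.nwk"))
    list(d = d, tree = tree, partition = part, gsim = gsim, simprof = sprof)
  })

  aov_res <- stage("anova", {
    totals <- station_totals(inp$abund)
    if (nlevels(droplevels(clus$partition)) < 2L)
      stop("group comparisons need at least 2 groups (k = ", config$k, ")")
    an <- oneway_anova(totals, clus$partition)
    tk <- tukey_hsd(totals, clus$partition)
    write_result_csv(data.frame(station = names(totals), total = unname(totals)),
                     config$out_dir, "station_totals.csv")
    write_result_csv(data.frame(F = an$F, df_between = an$df[["between"]],
                                df_within = an$df[["within"]],
                                p_value = an$p_value),
                     config$out_dir, "anova.csv")
    write_result_csv(tk, config$out_dir, "tukey.csv")
    list(totals = totals, anova = an, tukey = tk)
  })

  ind <- stage("indval", {
    iv <- if (config$n_perm >= 99)
      indval_permutation_p(inp$abund, clus$partition, n_perm = config$n_perm)
    else indval_table(inp$abund, clus$partition)
    sel <- select_indicators(iv, threshold = config$indval_threshold)
    iv_out <- iv
    iv_out$indval <- round(iv_out$indval, 2)
    write_result_csv(iv_out, config$out_dir, "indval.csv")
    write_result_csv(sel, config$out_dir, "indicators.csv")
    list(table = iv, selection = sel)
  })

  ord <- stage("ordination", {
    sp <- inp$abund[, comm$dominant$taxon, drop = FALSE]
    oc <- ordination_chain(sp, inp$env, scale_species = config$scale_species,
                           hellinger = config$hellinger)
    write_result_csv(data.frame(axis = names(oc$dca$axis_lengths),
                                length = unname(oc$dca$axis_lengths)),
                     config$out_dir, "dca_axis_lengths.csv")
    write_result_csv(data.frame(axis = names(oc$rda$eig),
                                eigenvalue = unname(oc$rda$eig)),
                     config$out_dir, "rda_eigenvalues.csv")
    write_result_csv(scores_to_df(oc$rda$species_scores, "taxon"),
                     config$out_dir, "rda_species_scores.csv")
    write_result_csv(scores_to_df(oc$rda$site_scores, "station"),
                     config$out_dir, "rda_site_scores.csv")
    write_result_csv(scores_to_df(oc$rda$biplot_scores, "variable"),
                     config$out_dir, "rda_biplot_scores.csv")
    oc
  })

  sizes <- group_sizes(clus$partition)
  indicators_by_group <- lapply(split(ind$selection$taxon,
                                      ind$selection$group), as.character)
  summary <- list(
    seed = config$seed, k = config$k,
    n_stations = nrow(inp$abund), n_taxa = ncol(inp$abund),
    total_mean_abundance = attr(comm$dom, "total_mean_abundance"),
    group_sizes = as.list(sizes),
    anova = list(F = aov_res$anova$F, p_value = aov_res$anova$p_value),
    indicators = indicators_by_group,
    dca_first_axis_length = unname(ord$dca$axis_lengths[[1L]]),
    dca_gate_linear = ord$dca$gate_linear,
    rda_prop_constrained = ord$rda$prop_constrained)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logline("pipeline complete")
  invisible(summary)
}
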