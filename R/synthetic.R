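# Synthetic site-by-taxon communities with planted indicator species.
# The generator emulates the study design the package targets: ~25 coastal
# stations split across three hydrographically distinct water masses,
# right-skewed taxon abundances, and a handful of taxa concentrated in one
# group (known specificity A* and fidelity B*) so downstream IndVal, ANOVA,
# clustering and ordination all have ground truth.

#' Default planted indicator plan
#'
#' Twelve taxa (one a copepodite category) planted across the three water
#' masses with specificities, fidelities and abundance scales typical of the
#' indicator copepods of the region (e.g. a strong monsoon-water indicator at
#' A* = 0.83, B* = 5/6 and ~94 ind m^-3 when present).
#'
#' @return data.frame with columns `taxon`, `group`, `A`, `B`,
#'   `mean_present`, `order`, `is_copepodite`.
#' @export
default_indicator_plan <- function() {
  data.frame(
    taxon = c("Temora turbinata", "Canthocalanus pauper", "Paracalanus parvus",
              "Acartia pacifica", "Paracalanus aculeatus", "Oncaea clevei",
              "Paracandacia truncata", "Euchaeta (copepodites)",
              "Farranula concinna", "Copilia mirabilis", "Corycaeus agilis",
              "Farranula gibbula"),
    group = c("A", "A", "A", "A", "B", "B", "B", "B", "C", "C", "C", "C"),
    A = c(0.83, 0.65, 0.54, 0.71, 0.53, 0.55, 0.84, 0.63,
          0.94, 0.92, 0.55, 0.51),
    B = c(5 / 6, 1, 1, 5 / 6, 1, 1, 8 / 11, 9 / 11, 1, 1, 1, 1),
    mean_present = c(94, 61, 43, 22.6, 217, 21.3, 1.6, 76,
                     33.3, 3.1, 17.6, 26.3),
    order = c("Calanoida", "Calanoida", "Calanoida", "Calanoida",
              "Calanoida", "Poecilostomatoida", "Calanoida", "Calanoida",
              "Poecilostomatoida", "Poecilostomatoida", "Poecilostomatoida",
              "Poecilostomatoida"),
    is_copepodite = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                      FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Design of a synthetic community
#'
#' Defaults reproduce the conditions of the surveyed system: 25 stations in
#' groups of (6, 11, 8); per-group hydrographic means and SDs as published
#' for the monsoon (A), mixed (B) and oceanic-intrusion (C) water masses;
#' 108 identified species plus 13 copepodite categories; lognormal
#' right-skewed abundances calibrated so station totals centre on the
#' published 774.24 ind m^-3.  The group split (6, 11, 8) is not printed in
#' the survey; it is the unique composition recovered by
#' [indval_consistency_solver()] from the published indicator table.
#'
#' @param group_sizes named integer vector of stations per group (>= 2 each).
#' @param env_profiles data.frame as [survey_env_profiles()]: per group mean
#'   and SD of temperature, salinity, dissolved oxygen, pH.
#' @param indicators planted indicator plan ([default_indicator_plan()]);
#'   `A`, `B` in [0, 1], `mean_present` > 0.
#' @param background_species named integer vector: background identified
#'   species per order.
#' @param background_copepodites named integer vector: background copepodite
#'   categories per order.
#' @param background_sdlog lognormal sd (log scale) of the species base
#'   means — controls how right-skewed the rank-abundance curve is.
#' @param noise_sdlog lognormal sd (log scale) of per-station abundance
#'   noise around each taxon's mean.
#' @param total_mean_abundance target expected station total (ind m^-3).
#' @param seed integer seed; one seed, one community.
#' @return list of class `synthetic_design`.
#' @export
synthetic_design <- function(group_sizes = c(A = 6L, B = 11L, C = 8L),
                             env_profiles = survey_env_profiles(),
                             indicators = default_indicator_plan(),
                             background_species = c(Calanoida = 62L,
                                                    Poecilostomatoida = 28L,
                                                    Cyclopoida = 4L,
                                                    Harpacticoida = 3L),
                             background_copepodites = c(Calanoida = 6L,
                                                        Poecilostomatoida = 3L,
                                                        Cyclopoida = 2L,
                                                        Harpacticoida = 1L),
                             background_sdlog = 1.5,
                             noise_sdlog = 0.8,
                             total_mean_abundance = 774.24,
                             seed = 1L) {
  if (any(group_sizes < 2L)) stop("group sizes must be >= 2")
  if (is.null(names(group_sizes))) names(group_sizes) <- LETTERS[seq_along(group_sizes)]
  if (!all(names(group_sizes) %in% env_profiles$group))
    stop("every group needs a row in env_profiles")
  sds <- as.matrix(env_profiles[, grep("_sd$", names(env_profiles))])
  if (any(sds < 0)) stop("environmental SDs must be >= 0")
  if (nrow(indicators) > 0L) {
    if (any(indicators$A < 0 | indicators$A > 1) ||
        any(indicators$B < 0 | indicators$B > 1))
      stop("planted specificity A and fidelity B must lie in [0, 1]")
    if (any(indicators$mean_present > 0 & indicators$A == 0))
      stop("infeasible design: A = 0 with positive abundance would require ",
           "infinite off-group abundance")
    if (!all(indicators$group %in% names(group_sizes)))
      stop("planted indicator group not among group labels")
  }
  if (background_sdlog < 0 || noise_sdlog < 0) stop("sdlog values must be >= 0")
  if (total_mean_abundance <= 0) stop("total mean abundance must be > 0")
  structure(list(group_sizes = group_sizes, env_profiles = env_profiles,
                 indicators = indicators,
                 background_species = background_species,
                 background_copepodites = background_copepodites,
                 background_sdlog = background_sdlog,
                 noise_sdlog = noise_sdlog,
                 total_mean_abundance = total_mean_abundance,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

lognoise <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # unit mean
}

#' Generate a synthetic community from a design
#'
#' Station environments are drawn normal from their group profiles.  A
#' planted indicator of group j is present at each group-j station with
#' probability B*, with lognormal abundance of mean `mean_present`; outside
#' j it is present with the same probability but with mean-when-present
#' `mean_present * (1 - A*) / (A* * (G - 1))`, so its expected specificity
#' equals A*.  Background taxa are drawn independently of the groups with
#' lognormal base means rescaled so the expected station total matches the
#' design.  Deterministic under the design seed.
#'
#' @param design a [synthetic_design()].
#' @return list with `abundance` (matrix), `env` (data.frame), `taxa`
#'   (data.frame) and `truth`: the true partition, the planted targets
#'   (A*, B*, expected IndVal = 100 A* B*) and the realized A, B and IndVal
#'   recomputed from the emitted matrix by [indval_table()].
#' @export
generate_community <- function(design) {
  if (!inherits(design, "synthetic_design")) stop("design must be a synthetic_design")
  set.seed(design$seed)
  gs <- design$group_sizes
  G <- length(gs)
  n <- sum(gs)
  glab <- rep(names(gs), times = gs)
  stations <- sprintf("st%02d", seq_len(n))
  partition <- validate_partition(setNames(glab, stations))

  prof <- design$env_profiles[match(glab, design$env_profiles$group), ]
  env <- data.frame(
    station = stations,
    temperature = round(rnorm(n, prof$temperature_mean, prof$temperature_sd), 4),
    salinity = round(rnorm(n, prof$salinity_mean, prof$salinity_sd), 4),
    dissolved_oxygen = round(rnorm(n, prof$do_mean, prof$do_sd), 4),
    pH = round(rnorm(n, prof$ph_mean, prof$ph_sd), 4),
    stringsAsFactors = FALSE)

  plan <- design$indicators
  n_pl <- nrow(plan)
  # expected per-station mean of each planted taxon in each group
  exp_mean <- matrix(0, n_pl, G, dimnames = list(plan$taxon, names(gs)))
  planted <- matrix(0, n, n_pl, dimnames = list(stations, plan$taxon))
  for (t in seq_len(n_pl)) {
    mu <- plan$mean_present[t]; Astar <- plan$A[t]; Bstar <- plan$B[t]
    mu_off <- if (Astar == 1 || G == 1L) 0 else mu * (1 - Astar) / (Astar * (G - 1))
    for (g in seq_len(G)) {
      in_g <- glab == names(gs)[g]
      m <- if (names(gs)[g] == plan$group[t]) mu else mu_off
      exp_mean[t, g] <- Bstar * m
      if (m > 0) {
        pres <- rbinom(sum(in_g), 1L, Bstar)
        planted[in_g, t] <- pres * m * lognoise(sum(in_g), design$noise_sdlog)
      }
    }
  }
  planted_per_station <- sum(exp_mean %*% (gs / n))

  orders_bg <- c(rep(names(design$background_species),
                     design$background_species),
                 rep(names(design$background_copepodites),
                     design$background_copepodites))
  cop_bg <- c(rep(FALSE, sum(design$background_species)),
              rep(TRUE, sum(design$background_copepodites)))
  bg_names <- character(length(orders_bg))
  for (o in unique(orders_bg)) {
    sp <- which(orders_bg == o & !cop_bg)
    cp <- which(orders_bg == o & cop_bg)
    bg_names[sp] <- sprintf("%s sp. %02d", o, seq_along(sp))
    bg_names[cp] <- sprintf("%s copepodites %02d", o, seq_along(cp))
  }
  n_bg <- length(bg_names)
  base <- rlnorm(n_bg, meanlog = 0, sdlog = design$background_sdlog)
  budget <- design$total_mean_abundance - planted_per_station
  if (budget <= 0)
    stop("planted taxa already exceed the target total mean abundance")
  base <- base * budget / sum(base)
  background <- matrix(rep(base, each = n),
                       n, n_bg, dimnames = list(stations, bg_names)) *
    matrix(lognoise(n * n_bg, design$noise_sdlog), n, n_bg)

  abundance <- round(cbind(planted, background), 6)
  validate_abundance(abundance)

  taxa <- rbind(
    data.frame(taxon = plan$taxon, order = plan$order,
               is_copepodite = plan$is_copepodite, stringsAsFactors = FALSE),
    data.frame(taxon = bg_names, order = orders_bg, is_copepodite = cop_bg,
               stringsAsFactors = FALSE))
  validate_taxa(taxa)

  iv <- indval_table(abundance, partition)
  realized <- do.call(rbind, lapply(seq_len(n_pl), function(t) {
    row <- iv[iv$taxon == plan$taxon[t] & iv$group == plan$group[t], ]
    data.frame(taxon = plan$taxon[t], group = plan$group[t],
               A_target = plan$A[t], B_target = plan$B[t],
               indval_target = 100 * plan$A[t] * plan$B[t],
               A_realized = row$A, B_realized = row$B,
               indval_realized = row$indval, stringsAsFactors = FALSE)
  }))

  list(abundance = abundance, env = env, taxa = taxa,
       truth = list(partition = partition, planted = realized),
       design = design)
}

#' Write a synthetic community to disk
#'
#' Emits `abundance.csv`, `env.csv`, `taxa.csv` and `ground_truth.json`
#' (true partition and planted-indicator targets/realizations) into `dir`.
#'
#' @param sim result of [generate_community()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance(sim$abundance, file.path(dir, "abundance.csv"))
  write_env(sim$env, file.path(dir, "env.csv"))
  write_taxa(sim$taxa, file.path(dir, "taxa.csv"))
  truth <- list(
    partition = as.list(setNames(as.character(sim$truth$partition),
                                 names(sim$truth$partition))),
    planted = sim$truth$planted,
    seed = sim$design$seed)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
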