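#' DCA gradient length (linear-vs-unimodal gate)
#'
#' Detrended correspondence analysis of the (dominant-taxon) abundance
#' matrix; the first-axis length in standard-deviation units of species
#' turnover decides the ordination family: lengths below 3 justify linear
#' methods (RDA), longer gradients call for unimodal ones.  Computed with
#' [vegan::decorana()] (reciprocal averaging with detrending-by-segments and
#' Hill's nonlinear rescaling); axis length is the range of the site scores.
#'
#' @param abund non-negative abundance matrix, no all-zero rows or columns.
#' @param segments number of detrending segments (default 26).
#' @param rescale apply Hill's nonlinear rescaling (default TRUE).
#' @return list of class `dca_gate`: `axis_lengths` (per DCA axis),
#'   `site_scores`, `gate_linear` (first axis < 3), `segments`, `rescale`.
#' @export
dca_gradient_length <- function(abund, segments = 26L, rescale = TRUE) {
  validate_abundance(abund)
  zr <- rownames(abund)[rowSums(abund) == 0]
  zc <- colnames(abund)[colSums(abund) == 0]
  if (length(zr)) stop("all-zero station(s): ", paste(zr, collapse = ", "))
  if (length(zc)) stop("all-zero taxon/taxa: ", paste(zc, collapse = ", "))
  d <- vegan::decorana(abund, mk = segments, iresc = if (rescale) 4L else 0L)
  sc <- vegan::scores(d, display = "sites")
  len <- apply(sc, 2L, function(x) {
    r <- diff(range(x))
    if (!is.finite(r)) 0 else r
  })
  structure(list(axis_lengths = len, eigenvalues = d$evals,
                 site_scores = sc, gate_linear = len[[1L]] < 3,
                 segments = segments, rescale = rescale),
            class = "dca_gate")
}

#' Redundancy analysis of taxon abundances on hydrographic variables
#'
#' Species columns are centred (optionally scaled, or Hellinger-transformed
#' first); environmental columns are standardised to zero mean and unit
#' variance; canonical axes are the principal components of the fitted
#' values of the least-squares regression of species on environment
#' (computed with [vegan::rda()], scaling type 2 scores).  Axis signs are
#' fixed deterministically: each canonical axis is oriented so that its
#' largest-magnitude species loading is positive.
#'
#' @param species matrix of (dominant-) taxon abundances, stations x taxa.
#' @param env environment table covering the same stations.
#' @param scale_species scale species columns to unit variance.
#' @param hellinger apply the Hellinger transformation to the species matrix
#'   before centring.
#' @param variables which environmental columns to constrain on (default all
#'   four); the recommended remedy when two variables are collinear.
#' @return list of class `rda_fit`: `eig` (canonical eigenvalues,
#'   descending), `residual_eig`, `total_variance`, `prop_constrained`,
#'   `species_scores`, `site_scores` (weighted-average), `site_constraints`
#'   (linear-combination site scores), `biplot_scores`, `env_correlations`
#'   (correlation of each standardised variable with each canonical axis)
#'   and the underlying vegan `model`.
#' @export
fit_rda <- function(species, env, scale_species = FALSE, hellinger = FALSE,
                    variables = c("temperature", "salinity",
                                  "dissolved_oxygen", "pH")) {
  if (!is.matrix(species) || !is.numeric(species))
    stop("species must be a numeric matrix")
  validate_env(env)
  idx <- match(rownames(species), env$station)
  if (anyNA(idx)) stop("station sets differ between species matrix and env")
  X <- env_numeric(env[idx, ])[, variables, drop = FALSE]
  if (nrow(species) <= ncol(X) + 1L)
    stop("need more stations than environmental variables + 1")
  Xs <- scale(X)
  if (any(!is.finite(Xs))) stop("constant environmental variable cannot be standardized")
  sv <- svd(Xs, nu = 0, nv = 0)$d
  if (max(sv) / max(min(sv), .Machine$double.eps) > 1e10)
    stop("collinear environmental variables (condition number > 1e10); ",
         "remove one before fitting")
  Y <- species
  if (hellinger) Y <- vegan::decostand(Y, method = "hellinger")
  m <- vegan::rda(X = Y, Y = Xs, scale = scale_species)
  eig <- m$CCA$eig
  resid_eig <- m$CA$eig
  naxes <- length(eig)
  sc <- vegan::scores(m, display = c("sp", "wa", "lc", "bp"), scaling = 2,
                      choices = seq_len(naxes))
  lc <- sc$constraints
  env_cor <- cor(Xs, lc)
  # deterministic orientation: largest-|loading| species positive per axis
  for (a in seq_len(naxes)) {
    top <- which.max(abs(sc$species[, a]))
    if (sc$species[top, a] < 0) {
      sc$species[, a] <- -sc$species[, a]
      sc$sites[, a] <- -sc$sites[, a]
      sc$constraints[, a] <- -sc$constraints[, a]
      sc$biplot[, a] <- -sc$biplot[, a]
      env_cor[, a] <- -env_cor[, a]
    }
  }
  structure(list(eig = eig, residual_eig = resid_eig,
                 total_variance = m$tot.chi,
                 prop_constrained = sum(eig) / m$tot.chi,
                 species_scores = sc$species, site_scores = sc$sites,
                 site_constraints = sc$constraints,
                 biplot_scores = sc$biplot, env_correlations = env_cor,
                 model = m),
            class = "rda_fit")
}

#' DCA-gated ordination chain
#'
#' Computes the DCA gradient length of the species matrix and proceeds to
#' RDA.  When the first DCA axis is 3 or longer the linear model is
#' questionable; a warning is emitted (unimodal alternatives are outside
#' this package's scope) and the RDA is still returned.
#'
#' @inheritParams fit_rda
#' @param segments passed to [dca_gradient_length()].
#' @return list with elements `dca` ([dca_gate]) and `rda` ([rda_fit]).
#' @export
ordination_chain <- function(species, env, segments = 26L,
                             scale_species = FALSE, hellinger = FALSE) {
  dca <- dca_gradient_length(species, segments = segments)
  if (!dca$gate_linear)
    warning("first DCA axis length ", round(dca$axis_lengths[[1L]], 2),
            " >= 3: linear ordination (RDA) may be inappropriate")
  rda <- fit_rda(species, env, scale_species = scale_species,
                 hellinger = hellinger)
  list(dca = dca, rda = rda)
}
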