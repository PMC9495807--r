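# deterministic Gaussian coenocline: sites along a gradient of G standard
# deviations of species turnover, unit-tolerance species responses
coenocline <- function(G, n_sites = 50, n_sp = 40, seed = 7) {
  set.seed(seed)
  x <- seq(0, G, length.out = n_sites)
  opt <- runif(n_sp, -1, G + 1)
  lam <- outer(x, opt, function(s, u) 60 * exp(-(s - u)^2 / 2))
  ab <- matrix(rpois(length(lam), lam), n_sites, n_sp,
               dimnames = list(sprintf("s%02d", 1:n_sites),
                               sprintf("sp%02d", 1:n_sp)))
  ab[rowSums(ab) > 0, colSums(ab) > 0]
}

rand_env <- function(n, seed) {
  set.seed(seed)
  make_env(runif(n, 20, 27), salinity = runif(n, 33.9, 34.4),
           dissolved_oxygen = runif(n, 6.4, 7.3), pH = runif(n, 8.25, 8.45))
}

test_that("DCA axis length recovers simulated gradient lengths", {
  # no gradient: identical stations span zero turnover
  flat <- make_abund(matrix(rep(c(1, 2, 3), each = 4), 4, 3))
  expect_equal(unname(dca_gradient_length(flat)$axis_lengths[1L]), 0)

  # a 4-SD coenocline is recovered within 25%
  long <- dca_gradient_length(coenocline(4))
  expect_lt(abs(long$axis_lengths[[1L]] - 4) / 4, 0.25)
  expect_false(long$gate_linear)

  # a short gradient fires the linear-methods gate
  short <- dca_gradient_length(coenocline(1.5))
  expect_lt(short$axis_lengths[[1L]], 3)
  expect_true(short$gate_linear)

  # zero rows/columns are named
  z <- make_abund(rbind(c(1, 2, 0), c(0, 0, 0), c(2, 1, 0)))
  expect_error(dca_gradient_length(z), "st02")
  expect_error(dca_gradient_length(z[-2L, ]), "sp03")
})

test_that("detrending leaves the first axis of correspondence analysis alone", {
  ab <- coenocline(2.5, seed = 11)
  dca <- dca_gradient_length(ab, rescale = FALSE)
  ca <- vegan::cca(ab)  # independent un-detrended oracle
  ca1 <- vegan::scores(ca, display = "sites", choices = 1)[, 1L]
  expect_gt(abs(cor(dca$site_scores[, 1L], ca1)), 0.999)
})

test_that("RDA matches the explicit regression-then-eigendecomposition oracle", {
  for (seed in c(5, 23)) {
    set.seed(seed)
    n <- 20
    Y <- matrix(abs(rnorm(n * 8, 5, 2)), n, 8,
                dimnames = list(sprintf("st%02d", 1:n), paste0("sp", 1:8)))
    env <- rand_env(n, seed + 100)
    r <- fit_rda(Y, env)

    Xs <- scale(as.matrix(env[, 2:5]))
    Yc <- scale(Y, scale = FALSE)
    H <- Xs %*% solve(crossprod(Xs)) %*% t(Xs)
    fitted <- H %*% Yc
    ev <- sort(eigen(crossprod(fitted) / (n - 1), symmetric = TRUE)$values,
               decreasing = TRUE)
    expect_equal(unname(r$eig), ev[seq_along(r$eig)], tolerance = 1e-8)
    # eigenvalue bookkeeping: constrained + residual = total variance
    expect_equal(sum(r$eig) + sum(r$residual_eig), r$total_variance,
                 tolerance = 1e-8 * r$total_variance)
    expect_equal(r$total_variance, sum(apply(Yc, 2L, var)),
                 tolerance = 1e-10)
    # biplot/env scores are correlations
    expect_true(all(abs(r$env_correlations) <= 1 + 1e-12))
    # orientation convention: strongest species loading positive per axis
    for (a in seq_along(r$eig)) {
      expect_gt(r$species_scores[which.max(abs(r$species_scores[, a])), a], 0)
    }
  }
})

test_that("a species matrix linear in the environment is fully constrained", {
  set.seed(3)
  n <- 12
  env <- rand_env(n, 4)
  Xs <- scale(as.matrix(env[, 2:5]))
  Y <- Xs %*% matrix(rnorm(4 * 6), 4, 6)
  Y <- Y - min(Y) + 0.1
  dimnames(Y) <- list(env$station, paste0("t", 1:6))
  r <- suppressWarnings(fit_rda(Y, env))
  expect_equal(r$prop_constrained, 1, tolerance = 1e-10)
})

test_that("explained variance is non-decreasing in the predictor set", {
  set.seed(17)
  n <- 18
  env <- rand_env(n, 8)
  Y <- matrix(abs(rnorm(n * 6, 4, 1.5)), n, 6,
              dimnames = list(env$station, paste0("sp", 1:6)))
  vars <- c("temperature", "salinity", "dissolved_oxygen", "pH")
  props <- vapply(2:4, function(k)
    fit_rda(Y, env, variables = vars[1:k])$prop_constrained, numeric(1L))
  expect_true(all(diff(props) >= -1e-12))
})

test_that("degenerate environmental designs are rejected", {
  env <- rand_env(10, 2)
  Y <- matrix(abs(rnorm(40)), 10, 4,
              dimnames = list(env$station, paste0("s", 1:4)))
  env_coll <- env
  env_coll$salinity <- 2 * env_coll$temperature  # exact collinearity
  expect_error(fit_rda(Y, env_coll), "collinear")
  expect_error(fit_rda(Y[1:5, ], env[1:5, ]), "more stations")
})

test_that("the ordination chain warns when the linear gate fails", {
  ab <- coenocline(9, n_sites = 60, n_sp = 60, seed = 2)
  env <- rand_env(nrow(ab), 77)
  env$station <- rownames(ab)
  expect_warning(ordination_chain(ab, env), "may be inappropriate")
})
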