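test_that("Bray-Curtis on hydrographic profiles follows the formula", {
  # identity: d(x, x) = 0
  env <- make_env(c(24, 24), 34.2, 6.9, 8.36)
  expect_equal(as.numeric(env_dissimilarity(env)), 0)

  # disjoint support approaches d = 1
  envd <- data.frame(station = c("a", "b"),
                     temperature = c(1, 1e-9), salinity = c(1e-9, 1),
                     dissolved_oxygen = c(1e-9, 1e-9), pH = c(1e-9, 1e-9))
  expect_equal(as.numeric(env_dissimilarity(envd)), 1, tolerance = 1e-6)

  # published group-A vs group-C mean profiles: d = 4.32 / 148.18
  envp <- data.frame(station = c("A", "C"),
                     temperature = c(22.78, 26.52), salinity = c(34.19, 34.27),
                     dissolved_oxygen = c(7.07, 6.63), pH = c(8.33, 8.39))
  d <- as.numeric(env_dissimilarity(envp))
  expect_equal(d, 4.32 / 148.18, tolerance = 1e-10)
  expect_equal(as.numeric(similarity_percent(env_dissimilarity(envp))),
               97.0846, tolerance = 1e-4)

  # invariance to scaling both stations by the same positive constant
  env2 <- envp
  env2[, 2:5] <- env2[, 2:5] * 1.5
  expect_equal(as.numeric(env_dissimilarity(env2)), d, tolerance = 1e-12)

  # symmetry and bounds on a larger instance
  sim <- default_sim()
  m <- as.matrix(env_dissimilarity(sim$env))
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(diag(m) == 0))
})

test_that("complete linkage matches the exhaustive three-point solution", {
  d <- as.dist(matrix(c(0, 0.1, 0.9, 0.1, 0, 0.8, 0.9, 0.8, 0), 3, 3,
                      dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  tree <- cluster_env(d)
  expect_equal(tree$height, c(0.1, 0.9))
  # first merge joins a and b (leaves 1 and 2)
  expect_setequal(tree$merge[1L, ], c(-1L, -2L))
})

test_that("merge heights equal the maximum within-cluster dissimilarity", {
  sim <- default_sim()
  env <- sim$env[1:12, ]
  d <- env_dissimilarity(env)
  tree <- cluster_env(d)
  dm <- as.matrix(d)
  members <- function(i) {
    if (i < 0) return(tree$labels[-i])
    c(members(tree$merge[i, 1L]), members(tree$merge[i, 2L]))
  }
  for (i in seq_along(tree$height)) {
    cl <- members(i)
    expect_equal(tree$height[i], max(dm[cl, cl]), tolerance = 1e-12)
  }
})

test_that("partition cutting labels groups by descending dissolved oxygen", {
  sim <- generate_community(synthetic_design(
    env_profiles = separated_profiles(), seed = 2L))
  d <- env_dissimilarity(sim$env)
  part <- cut_partition(cluster_env(d), 3, sim$env)
  do_means <- tapply(sim$env$dissolved_oxygen[match(names(part),
                                                    sim$env$station)],
                     part, mean)
  expect_true(all(diff(do_means[c("A", "B", "C")]) < 0))
  # and the planted partition is recovered under this separation
  expect_equal(rand_index(part, sim$truth$partition), 1)

  # hydrographic within-group similarities sit in the surveyed 97-100% band
  gs <- group_similarity(d, part)
  expect_true(all(gs$similarity >= 97 & gs$similarity <= 100))
})

test_that("group similarity handles k = 1 and singleton groups", {
  sim <- default_sim()
  d <- env_dissimilarity(sim$env)
  tree <- cluster_env(d)

  p1 <- cut_partition(tree, 1, sim$env)
  g1 <- group_similarity(d, p1)
  s <- similarity_percent(d)
  expect_equal(g1$similarity, mean(s))

  pn <- cut_partition(tree, nrow(sim$env), sim$env)
  gn <- group_similarity(d, pn)
  expect_true(all(gn$singleton))
  expect_true(all(gn$similarity == 100))
})

test_that("SIMPROF finds no structure in identical stations and flags planted structure", {
  env_flat <- make_env(rep(24, 6))
  r <- simprof(env_flat, n_perm_expected = 50, n_perm_test = 99, seed = 1)
  expect_equal(r$pi, 0)
  expect_equal(r$p_value, 1)

  # two well-separated sub-blobs whose variables covary (the structure the
  # independent-column-shuffle null is sensitive to)
  set.seed(42)
  blob <- rep(c(0, 1), each = 5)
  env2 <- data.frame(station = sprintf("s%d", 1:10),
                     temperature = 22 + 5 * blob + rnorm(10, 0, 0.1),
                     salinity = 34.1 + 0.2 * blob + rnorm(10, 0, 0.01),
                     dissolved_oxygen = 7.1 - 0.5 * blob + rnorm(10, 0, 0.02),
                     pH = 8.31 + 0.08 * blob + rnorm(10, 0, 0.005))
  r2 <- simprof(env2, n_perm_expected = 199, n_perm_test = 999, seed = 9)
  expect_lte(r2$p_value, 0.01)

  expect_error(simprof(make_env(c(24, 25))), "at least 3")
})
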