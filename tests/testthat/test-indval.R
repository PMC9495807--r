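# 25 stations in the group sizes recovered from the published indicator
# table; per-taxon column built from target group means and presence counts
survey_sized_matrix <- function(cols) {
  sizes <- c(A = 6L, B = 11L, C = 8L)
  stations <- sprintf("st%02d", 1:25)
  part <- make_partition(rep(names(sizes), sizes), stations)
  x <- do.call(cbind, cols)
  rownames(x) <- stations
  list(abund = x, partition = part, sizes = sizes)
}

# column with group means `means` and presence at `k` sites per group
col_from_means <- function(means, k, sizes = c(6L, 11L, 8L)) {
  unlist(mapply(function(m, kk, n) {
    v <- rep(0, n)
    if (kk > 0L) v[seq_len(kk)] <- m * n / kk
    v
  }, means, k, sizes, SIMPLIFY = FALSE))
}

test_that("a taxon confined to one group with full fidelity scores IndVal 100", {
  fix <- survey_sized_matrix(list(
    perfect = col_from_means(c(0, 12.5, 0), c(0L, 11L, 0L)),
    other = rep(1, 25)))
  iv <- indval_table(fix$abund, fix$partition)
  row <- iv[iv$taxon == "perfect", ]
  expect_equal(row$indval[row$group == "B"], 100)
  expect_equal(row$indval[row$group != "B"], c(0, 0))
  expect_equal(row$A[row$group == "B"], 1)
  expect_equal(row$B[row$group == "B"], 1)
})

test_that("IndVal reproduces published values from group means and presence", {
  fix <- survey_sized_matrix(list(
    # full fidelity in B: IndVal_B = 100 * 21.31 / 38.61 = 55.19
    oncaea = col_from_means(c(8.74, 21.31, 8.56), c(5L, 11L, 3L)),
    # presence at 5 of 6 group-A sites: 100 * (78.28/94.45) * (5/6) = 69.07
    temora = col_from_means(c(78.28, 16.07, 0.10), c(5L, 6L, 1L))))
  iv <- indval_table(fix$abund, fix$partition)
  expect_equal(round(iv$indval[iv$taxon == "oncaea" & iv$group == "B"], 2),
               55.19)
  expect_equal(round(iv$indval[iv$taxon == "temora" & iv$group == "A"], 2),
               69.07)
  # the same arithmetic through the published-table helper
  expect_equal(round(indval_from_means(c(8.74, 21.31, 8.56))[2L], 2), 55.19)
})

test_that("specificity sums to one and IndVal is scale invariant", {
  sim <- default_sim()
  iv <- indval_table(sim$abundance, sim$truth$partition)
  expect_true(all(iv$indval >= 0 & iv$indval <= 100))
  a_sums <- tapply(iv$A[!iv$all_zero], iv$taxon[!iv$all_zero], sum)
  expect_true(all(abs(a_sums - 1) < 1e-9))
  # IndVal = 100 iff A = 1 and B = 1
  at100 <- iv[abs(iv$indval - 100) < 1e-12, ]
  expect_true(all(abs(at100$A - 1) < 1e-12 & abs(at100$B - 1) < 1e-12))

  iv2 <- indval_table(sim$abundance * 7.3, sim$truth$partition)
  expect_equal(iv2$indval, iv$indval, tolerance = 1e-9)

  expect_error(indval_table(sim$abundance,
                            make_partition(rep("A", 25),
                                           rownames(sim$abundance))),
               "2 groups")
})

test_that("indicator selection uses a strict threshold and sorts by IndVal", {
  iv <- data.frame(taxon = c("t1", "t2", "t3", "t4"),
                   group = c("A", "A", "B", "B"),
                   indval = c(50, 72.4, 50.0001, 49.9))
  sel <- select_indicators(iv, threshold = 50)
  expect_equal(sel$taxon, c("t2", "t3"))

  # all exactly at the threshold: empty selection
  iv50 <- data.frame(taxon = c("a", "b"), group = c("A", "B"),
                     indval = c(50, 50))
  expect_equal(nrow(select_indicators(iv50, 50)), 0L)

  expect_error(select_indicators(iv, threshold = 0), "\\(0, 100\\)")
})

test_that("permutation p-values flag planted indicators and respect bounds", {
  sim <- default_sim()
  iv <- indval_permutation_p(sim$abundance, sim$truth$partition,
                             n_perm = 999, seed = 5)
  expect_true(all(iv$p_value > 0 & iv$p_value <= 1))
  # the strongest planted indicator is detected
  strong <- sim$truth$planted[which.max(sim$truth$planted$indval_realized), ]
  p <- iv$p_value[iv$taxon == strong$taxon & iv$group == strong$group]
  expect_lte(p, 0.01)

  # a constant taxon carries no information: p = 1 in every group
  fix <- survey_sized_matrix(list(flat = rep(3, 25), other = runif(25)))
  ivc <- indval_permutation_p(fix$abund, fix$partition, n_perm = 99, seed = 2)
  expect_true(all(ivc$p_value[ivc$taxon == "flat"] == 1))

  expect_error(indval_permutation_p(sim$abundance, sim$truth$partition,
                                    n_perm = 50), "99")
})

test_that("the consistency solver recovers known designs exactly", {
  # synthetic printed table from known sizes (7, 9, 4) with exact arithmetic
  sizes <- c(7L, 9L, 4L)
  set.seed(21)
  means <- matrix(rlnorm(15, 2, 1), 5, 3)
  pres <- cbind(sample(0:7, 5, TRUE), sample(0:9, 5, TRUE), sample(1:4, 5, TRUE))
  printed <- 100 * (means / rowSums(means)) * sweep(pres, 2L, sizes, "/")
  sol <- indval_consistency_solver(means, printed, sum(sizes))
  expect_equal(sol$sizes, sizes)
  expect_equal(sol$max_residual, 0, tolerance = 1e-9)
  keep <- !is.na(sol$presence)
  expect_equal(sol$presence[keep], pres[keep])

  # a single taxon with B = 1 cannot identify the sizes
  m1 <- matrix(c(10, 30, 10), 1, 3)
  p1 <- 100 * m1 / sum(m1)
  sol1 <- indval_consistency_solver(rbind(m1, m1, m1),
                                    rbind(p1, p1, p1), 20)
  expect_true(sol1$ambiguous)

  # an impossible table is reported as inconsistent
  bad <- matrix(c(10, 10, 10), 3, 3)
  expect_error(indval_consistency_solver(bad, bad * 0 + 47.123, 9,
                                         max_residual = 0.05),
               "no station composition")
})
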