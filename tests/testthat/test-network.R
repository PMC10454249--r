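test_that("volumes exactly linear in age residualize to zero", {
  set.seed(1)
  age <- runif(12, 50, 90)
  sex <- rep(c(0, 1), 6)
  vols <- cbind(2 * age + 5, -3 * age + 1000, 0.5 * age)
  colnames(vols) <- c("A", "B", "C")
  coh <- cohort(paste0("s", 1:12), rep("g", 12), age, sex, vols,
                region_set(c("A", "B", "C")))
  res <- residualize(coh)
  expect_lt(max(abs(res$values)), 1e-9)
})

test_that("residuals match an explicit normal-equations solve", {
  set.seed(2)
  n <- 20
  age <- runif(n, 50, 90)
  sex <- rep(c(0, 1), n / 2)
  vols <- matrix(runif(n * 5, 1000, 9000), n, 5)
  coh <- cohort(paste0("s", 1:n), rep("g", n), age, sex, vols,
                region_set(paste0("R", 1:5)))
  res <- residualize(coh)
  expected <- oracle_ols_residuals(cbind(1, age, sex), vols)
  expect_lt(max(abs(res$values - expected)), 1e-8)
  # residuals orthogonal to every design column, columns mean-zero
  X <- cbind(1, age, sex)
  rel <- abs(t(X) %*% res$values) / sqrt(colSums(X^2))
  expect_lt(max(rel), 1e-6)
  expect_lt(max(abs(colMeans(res$values))), 1e-8)
})

test_that("constant sex is dropped with a warning, constant age errors", {
  set.seed(3)
  n <- 10
  age <- runif(n, 50, 90)
  vols <- matrix(runif(n * 3, 1, 2), n, 3)
  coh <- cohort(paste0("s", 1:n), rep("g", n), age, rep(1, n), vols,
                region_set(paste0("R", 1:3)))
  expect_warning(res <- residualize(coh), "sex is constant")
  expected <- oracle_ols_residuals(cbind(1, age), vols)
  expect_lt(max(abs(res$values - expected)), 1e-10)

  coh2 <- cohort(paste0("s", 1:n), rep("g", n), rep(70, n),
                 rep(c(0, 1), 5), vols, region_set(paste0("R", 1:3)))
  expect_error(residualize(coh2), "age is constant")
})

test_that("zero-variance volume columns warn and give zero residuals", {
  set.seed(4)
  n <- 10
  vols <- cbind(rep(5000, n), matrix(runif(n * 2, 1, 2), n, 2))
  coh <- cohort(paste0("s", 1:n), rep("g", n), runif(n, 50, 90),
                rep(c(0, 1), 5), vols,
                region_set(c("Flat", "R1", "R2")))
  expect_warning(res <- residualize(coh), "Flat")
  expect_identical(res$values[, 1], rep(0, n))
})

test_that("too-small groups are rejected", {
  vols <- matrix(runif(9, 1, 2), 3, 3)
  coh <- cohort(paste0("s", 1:3), rep("g", 3), c(70, 75, 80),
                c(0, 1, 0), vols, region_set(paste0("R", 1:3)))
  expect_error(residualize(coh), "at least 4 subjects")
  expect_error(group_network(coh, "g"), "at least 4 subjects")
})

test_that("edge weights equal zero-clipped Pearson correlations", {
  set.seed(5)
  n <- 30
  age <- runif(n, 50, 90)
  sex <- rep(c(0, 1), n / 2)
  vols <- matrix(runif(n * 6, 1000, 9000), n, 6)
  coh <- cohort(paste0("s", 1:n), rep("g", n), age, sex, vols,
                region_set(paste0("R", 1:6)))
  res <- residualize(coh)
  net <- build_network(res)
  for (i in 1:5) for (j in (i + 1):6) {
    r <- oracle_pearson(res$values[, i], res$values[, j])
    expect_equal(net$weights[i, j], max(0, r), tolerance = 1e-10)
    expect_identical(net$weights[i, j], net$weights[j, i])
  }
  expect_identical(diag(net$weights), stats::setNames(rep(0, 6),
                                                      paste0("R", 1:6)))
  expect_true(all(net$weights >= 0 & net$weights <= 1))
})

test_that("identical and negated residual columns hit the weight bounds", {
  set.seed(6)
  n <- 12
  base <- rnorm(n)
  age <- runif(n, 50, 90)
  sex <- rep(c(0, 1), 6)
  X <- cbind(1, age, sex)
  r <- oracle_ols_residuals(X, cbind(base))  # make columns design-orthogonal
  vals <- cbind(r, r, -r) + 100  # equal, equal, negated after demeaning
  coh <- cohort(paste0("s", 1:n), rep("g", n), age, sex,
                vals + 10, region_set(c("A", "B", "C")))
  net <- build_network(residualize(coh))
  expect_equal(net$weights["A", "B"], 1, tolerance = 1e-10)
  expect_equal(net$weights["A", "C"], 0)
})

test_that("unknown groups are rejected listing the available ones", {
  coh <- make_test_cohort(c(a = 8, b = 8))
  expect_error(group_network(coh, "c"), "a, b")
})

test_that("networks are invariant to subject order and nuisance shifts", {
  coh <- make_test_cohort(c(g = 25), regions = 6, strength = 0.4,
                          seed = 11)
  net <- group_network(coh, "g")

  # subject permutation
  set.seed(12)
  perm <- sample(25)
  coh2 <- cohort(coh$subjects$subject_id[perm], coh$subjects$group[perm],
                 coh$subjects$age[perm], coh$subjects$sex[perm],
                 coh$volumes[perm, ], coh$region_set)
  expect_equal(group_network(coh2, "g")$weights, net$weights,
               tolerance = 1e-12)

  # adding constants and multiples of age / sex is absorbed
  vols3 <- coh$volumes
  vols3[, 2] <- vols3[, 2] + 500 + 3 * coh$subjects$age
  vols3[, 5] <- vols3[, 5] + 40 * coh$subjects$sex - 100
  coh3 <- cohort(coh$subjects$subject_id, coh$subjects$group,
                 coh$subjects$age, coh$subjects$sex, vols3,
                 coh$region_set)
  expect_equal(group_network(coh3, "g")$weights, net$weights,
               tolerance = 1e-8)

  # region permutation permutes rows/columns identically
  ord <- c(4, 1, 6, 2, 5, 3)
  coh4 <- cohort_subset(coh, regions = coh$region_set$regions[ord])
  expect_equal(group_network(coh4, "g")$weights,
               net$weights[ord, ord], tolerance = 1e-12)
})

test_that("i.i.d. regions give near-zero weights at large n", {
  coh <- make_test_cohort(c(g = 2000), regions = 6, seed = 21)
  net <- group_network(coh, "g")
  expect_lt(max(net$weights), 0.1)
})

test_that("uniform target correlation 0.6 is recovered at large n", {
  coh <- make_test_cohort(c(g = 2000), regions = 6, strength = 0.6,
                          seed = 22)
  net <- group_network(coh, "g")
  off <- net$weights[upper.tri(net$weights)]
  expect_lt(max(abs(off - 0.6)), 0.05)
})

test_that("connectivity matrices and edge lists round-trip", {
  coh <- make_test_cohort(c(g = 15), regions = 5, strength = 0.5,
                          seed = 31)
  net <- group_network(coh, "g")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back, net$weights, tolerance = 1e-12)
  el <- network_edge_list(net)
  expect_named(el, c("region_a", "region_b", "weight"))
  expect_equal(nrow(el), sum(net$weights > 0) / 2)
})
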