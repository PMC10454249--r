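test_that("shortest-path distances follow the inverse-weight convention", {
  tri <- k_complete(3, 0.5)
  d <- net_distances(tri)
  expect_equal(d[row(d) != col(d)], rep(2, 6))
  expect_identical(diag(d), rep(0, 3))

  w <- two_hop_triangle()
  d <- net_distances(w)
  expect_equal(d[1, 3], 1 / 0.9 + 1 / 0.9, tolerance = 1e-12)
  expect_equal(d[1, 2], 1 / 0.9, tolerance = 1e-12)
  expect_identical(d, t(d))

  # two disconnected unit edges on 4 nodes
  w4 <- matrix(0, 4, 4)
  w4[1, 2] <- w4[2, 1] <- 1
  w4[3, 4] <- w4[4, 3] <- 1
  d4 <- net_distances(w4)
  expect_true(all(is.infinite(d4[1:2, 3:4])))
})

test_that("distances agree with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    w <- random_weight_matrix(n, density = 0.5)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    ref <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(unname(net_distances(w)), unname(ref),
                 tolerance = 1e-10)
  }
})

test_that("global efficiency matches hand-computed examples", {
  expect_equal(global_efficiency(k_complete(4)), 1)
  expect_equal(global_efficiency(two_hop_triangle()),
               (0.9 + 0.45 + 0.9) / 3, tolerance = 1e-12)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
})

test_that("local efficiency matches its neighbor-subgraph definition", {
  expect_equal(local_efficiency(k_complete(3)), 1)
  expect_equal(local_efficiency(star_graph(3)), 0)
  set.seed(42)
  for (rep in 1:10) {
    w <- random_weight_matrix(8, density = 0.5)
    expect_equal(local_efficiency(w), oracle_local_efficiency(w),
                 tolerance = 1e-10)
  }
})

test_that("Onnela clustering matches direct evaluation", {
  expect_equal(mean_clustering(k_complete(4)), 1)
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 0.8
  tri[1, 3] <- tri[3, 1] <- 0.5
  tri[2, 3] <- tri[3, 2] <- 0.2
  expect_equal(mean_clustering(tri), (1 * 0.625 * 0.25)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(mean_clustering(path_graph3()), 0)
  expect_warning(z <- mean_clustering(matrix(0, 3, 3)), "all-zero")
  expect_identical(z, 0)
})

test_that("characteristic path length handles disconnection as documented", {
  expect_equal(as.numeric(characteristic_path_length(k_complete(4))), 1)
  expect_equal(as.numeric(characteristic_path_length(two_hop_triangle())),
               (1 / 0.9 + 2 / 0.9 + 1 / 0.9) / 3, tolerance = 1e-12)
  expect_equal(as.numeric(characteristic_path_length(path_graph3())),
               4 / 3, tolerance = 1e-12)

  w4 <- matrix(0, 4, 4)
  w4[1, 2] <- w4[2, 1] <- 1
  w4[3, 4] <- w4[4, 3] <- 1
  expect_message(cpl <- characteristic_path_length(w4), "unreachable")
  expect_equal(as.numeric(cpl), 1)
  expect_identical(attr(cpl, "excluded_pairs"), 8L)

  cpl0 <- characteristic_path_length(matrix(0, 3, 3))
  expect_identical(as.numeric(cpl0), Inf)
})

test_that("strength and degree are plain row summaries", {
  sd4 <- strength_degree(k_complete(4))
  expect_equal(sd4$average_strength, 3)
  expect_equal(sd4$average_degree, 3)
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 0.8
  tri[1, 3] <- tri[3, 1] <- 0.5
  tri[2, 3] <- tri[3, 2] <- 0.2
  sdt <- strength_degree(tri)
  expect_equal(unname(sdt$strength), c(1.3, 1.0, 0.7))
  expect_equal(sdt$average_strength, 1)
  expect_equal(sdt$average_degree, 2)
  sd0 <- strength_degree(matrix(0, 3, 3))
  expect_equal(c(sd0$average_strength, sd0$average_degree), c(0, 0))
})

test_that("degree assortativity matches the directed-edge-list definition", {
  expect_equal(degree_assortativity(star_graph(3)), -1)
  expect_equal(degree_assortativity(path_graph3()), -1)
  expect_true(is.na(degree_assortativity(k_complete(4))))
  one_edge <- matrix(0, 3, 3)
  one_edge[1, 2] <- one_edge[2, 1] <- 1
  expect_true(is.na(degree_assortativity(one_edge)))
})

test_that("all seven measures match brute force on random small graphs", {
  set.seed(43)
  for (rep in 1:25) {
    n <- sample(3:7, 1)
    w <- random_weight_matrix(n, density = runif(1, 0.3, 0.9))
    got <- unclass(all_measures(w))
    want <- oracle_all_measures(w)
    expect_equal(got[!is.na(want)], want[!is.na(want)],
                 tolerance = 1e-10)
    expect_identical(is.na(got), is.na(want))
  }
})

test_that("relabeling nodes leaves every measure unchanged", {
  set.seed(44)
  for (rep in 1:10) {
    w <- random_weight_matrix(7, density = 0.6)
    perm <- sample(7)
    m1 <- unclass(all_measures(w))
    m2 <- unclass(all_measures(w[perm, perm]))
    expect_equal(m1, m2, tolerance = 1e-12)
  }
})

test_that("uniform weight scaling obeys the expected laws", {
  set.seed(45)
  for (c_ in c(0.2, 0.7)) {
    w <- random_weight_matrix(8, density = 0.7)
    m1 <- unclass(all_measures(w))
    m2 <- unclass(all_measures(c_ * w))
    expect_equal(m2[["average_strength"]],
                 c_ * m1[["average_strength"]], tolerance = 1e-12)
    expect_equal(m2[["characteristic_path_length"]],
                 m1[["characteristic_path_length"]] / c_,
                 tolerance = 1e-10)
    expect_equal(m2[["global_efficiency"]],
                 c_ * m1[["global_efficiency"]], tolerance = 1e-10)
    expect_equal(m2[["mean_clustering_coefficient"]],
                 m1[["mean_clustering_coefficient"]], tolerance = 1e-12)
    expect_equal(m2[["average_degree"]], m1[["average_degree"]])
  }
})

test_that("raising a weight never hurts efficiency or path length", {
  set.seed(46)
  for (rep in 1:10) {
    w <- random_weight_matrix(7, density = 0.4)
    ij <- sample(7, 2)
    w2 <- w
    w2[ij[1], ij[2]] <- w2[ij[2], ij[1]] <-
      min(1, w[ij[1], ij[2]] + runif(1, 0.1, 0.5))
    expect_gte(global_efficiency(w2) - global_efficiency(w), -1e-12)
    d1 <- net_distances(w)
    d2 <- net_distances(w2)
    expect_true(all(d2 <= d1 + 1e-12))
  }
})

test_that("alternative distance conventions are honored", {
  w <- two_hop_triangle()
  d <- net_distances(w, convention = "neglog")
  expect_equal(d[1, 2], -log(0.9), tolerance = 1e-12)
  # direct edge wins under -log for this graph
  expect_equal(d[1, 3], min(-log(0.1), 2 * -log(0.9)), tolerance = 1e-12)
  d2 <- net_distances(w, convention = "one-minus")
  expect_equal(d2[1, 2], 0.1, tolerance = 1e-12)
})

test_that("weight-matrix validation rejects malformed input", {
  expect_error(all_measures(matrix(1:6, 2, 3)), "square")
  m <- k_complete(4); m[1, 2] <- -0.5
  expect_error(all_measures(m), "symmetric|non-negative")
  m2 <- k_complete(4); m2[1, 2] <- m2[2, 1] <- -0.5
  expect_error(all_measures(m2), "non-negative")
})

test_that("measures serialize with NA for undefined values", {
  m <- all_measures(k_complete(4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_measures(m, path, network = "toy", group = "g")
  df <- read.delim(path)
  expect_identical(nrow(df), 1L)
  expect_true(is.na(df$assortative_coefficient))
  expect_equal(df$average_strength, 3)
})
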