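test_that("closed-form path lengths and efficiencies are exact", {
  P3 <- unit_path(3)
  L <- shortest_path_lengths(P3)
  expect_equal(L[1, 3], 2)
  expect_equal(diag(L), rep(0, 3), ignore_attr = TRUE)

  disc <- matrix(0, 4, 4); disc[1, 2] <- disc[2, 1] <- 1
  expect_equal(shortest_path_lengths(disc)[1, 3], Inf)

  expect_equal(global_efficiency(unit_complete(5)), 1)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  expect_equal(global_efficiency(P3), 5 / 6)

  expect_equal(local_efficiency(unit_triangle()), 1)
  expect_equal(local_efficiency(unit_star(6)), 0)

  expect_equal(unname(nodal_efficiency(unit_complete(6))), rep(1, 6))
  expect_equal(unname(nodal_efficiency(P3)[1]), 0.75)
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(unname(nodal_efficiency(iso)[3]), 0)

  expect_equal(unname(nodal_degree(unit_star(7))[1]), 6)
  Wd <- matrix(0, 3, 3)
  Wd[1, 2] <- Wd[2, 1] <- 0.5; Wd[1, 3] <- Wd[3, 1] <- 0.25
  expect_equal(unname(nodal_degree(Wd)[1]), 0.75)

  expect_equal(weighted_clustering(unit_triangle()), 1)
  expect_equal(weighted_clustering(unit_star(8)), 0)   # trees have no triangles
  expect_equal(weighted_clustering(unit_path(6)), 0)

  expect_equal(characteristic_path_length(unit_complete(4)), 1)
  expect_equal(characteristic_path_length(unit_path(3)), 4 / 3)
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "disconnected")
})

test_that("degree sums satisfy the handshake identity on random graphs", {
  withr::with_seed(11, {
    for (i in 1:20) {
      W <- rand_graph(10, runif(1, 0.2, 0.9))
      expect_equal(sum(nodal_degree(W)), 2 * sum(W[upper.tri(W)]))
    }
  })
})

test_that("path lengths, clustering and local efficiency match brute-force oracles", {
  withr::with_seed(42, {
    for (i in 1:100) {
      n <- sample(5:12, 1)
      W <- rand_graph(n, runif(1, 0.3, 0.9))
      expect_equal(shortest_path_lengths(W), oracle_spl(W))
      # independent library route for the same quantity
      g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                               weighted = TRUE)
      igraph::E(g)$weight <- 1 / igraph::E(g)$weight
      expect_equal(shortest_path_lengths(W), igraph::distances(g),
                   ignore_attr = TRUE)
      if (i <= 50) {
        expect_equal(local_efficiency(W), oracle_local_eff(W))
        if (max(W) > 0) expect_equal(weighted_clustering(W), oracle_clustering(W))
      }
    }
  })
})

test_that("global efficiency is the mean of nodal efficiencies", {
  withr::with_seed(5, {
    for (i in 1:20) {
      W <- rand_graph(9, 0.5)
      expect_equal(global_efficiency(W), mean(nodal_efficiency(W)))
    }
  })
})

test_that("strengthening the network never lowers efficiency", {
  withr::with_seed(9, {
    for (i in 1:20) {
      W <- rand_graph(8, 0.4)
      e0 <- global_efficiency(W)
      n0 <- nodal_efficiency(W)
      W2 <- W
      off <- which(upper.tri(W2) & W2 == 0)
      if (length(off) > 0) {
        pick <- off[sample.int(length(off), 1)]
        ij <- arrayInd(pick, dim(W2))
        W2[ij[1], ij[2]] <- W2[ij[2], ij[1]] <- runif(1, 0.1, 1)
      } else {
        W2 <- W2 * 1.5
      }
      expect_gte(global_efficiency(W2), e0 - 1e-12)
      expect_true(all(nodal_efficiency(W2) >= n0 - 1e-12))
    }
  })
})

test_that("all metrics are equivariant under node relabelling", {
  withr::with_seed(3, {
    W <- rand_graph(10, 0.5)
    p <- sample(10)
    Wp <- W[p, p]
    expect_equal(global_efficiency(Wp), global_efficiency(W))
    expect_equal(local_efficiency(Wp), local_efficiency(W))
    expect_equal(weighted_clustering(Wp), weighted_clustering(W))
    expect_equal(characteristic_path_length(Wp), characteristic_path_length(W))
    expect_equal(unname(nodal_degree(Wp)), unname(nodal_degree(W)[p]))
    expect_equal(unname(nodal_efficiency(Wp)), unname(nodal_efficiency(W)[p]))
  })
})

test_that("rewired nulls preserve degrees and weights, and are seeded", {
  withr::with_seed(21, {
    W <- rand_graph(20, 0.3)
    for (i in 1:10) {
      Wn <- rewire_null(W, seed = 100 + i)
      expect_equal(rowSums(Wn > 0), rowSums(W > 0))              # degree sequence
      expect_equal(sort(Wn[upper.tri(Wn)][Wn[upper.tri(Wn)] > 0]),
                   sort(W[upper.tri(W)][W[upper.tri(W)] > 0]))   # weight multiset
      expect_equal(Wn, t(Wn))
    }
    expect_identical(rewire_null(W, seed = 7), rewire_null(W, seed = 7))
    expect_false(identical(rewire_null(W, seed = 7), rewire_null(W, seed = 8)))
    expect_error(rewire_null(unit_path(3)), "4 edges")
  })
})

test_that("rewiring a complete graph cannot make progress and warns", {
  expect_warning(rewire_null(unit_complete(6), seed = 1), "proposal limit")
})

test_that("small-worldness is reproducible and detects lattice structure", {
  withr::with_seed(2, {
    W <- ring_lattice(40, k = 6, p_rewire = 0.05)
  })
  s1 <- small_worldness(W, n_null = 20, seed = 5)
  s2 <- small_worldness(W, n_null = 20, seed = 5)
  expect_identical(s1, s2)
  expect_gt(as.numeric(s1), 1.2)
  comp <- attr(s1, "components")
  expect_equal(as.numeric(s1),
               (comp["C_net"] / comp["C_rand"]) / (comp["L_net"] / comp["L_rand"]),
               ignore_attr = TRUE)
})
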