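test_that("weights map to distances by reciprocal", {
  cn <- cn_of(sym_matrix(3, list(c(1, 2, 2))))
  dg <- weight_to_distance(cn)
  expect_equal(dg$distances[1, 2], 0.5)
  expect_equal(dg$distances[1, 3], Inf)
  expect_equal(diag(dg$distances), rep(0, 3))
  expect_equal(weight_to_distance(unit_triangle())$distances[1, 2], 1)
})

test_that("geodesics count tied shortest paths", {
  g3 <- geodesics(unit_path3())
  expect_equal(g3$lengths[1, 3], 2)
  expect_equal(g3$counts[1, 3], 1)

  g4 <- geodesics(unit_cycle(4))
  expect_equal(g4$lengths[1, 3], 2)
  expect_equal(g4$counts[1, 3], 2)  # both ways round

  disc <- geodesics(cn_of(sym_matrix(4, list(c(1, 2, 1), c(3, 4, 1)))))
  expect_equal(disc$lengths[1, 3], Inf)
  expect_equal(disc$counts[1, 3], 0)
})

test_that("strength sums incident weights and is linear in an edge bump", {
  cn <- cn_of(sym_matrix(3, list(c(1, 2, 2), c(2, 3, 3))))
  expect_equal(node_strength(cn), c(2, 5, 3))
  expect_equal(node_strength(cn_of(matrix(0, 4, 4))), rep(0, 4))

  W2 <- cn$weights
  W2[1, 2] <- W2[2, 1] <- W2[1, 2] + 0.7
  expect_equal(node_strength(cn_of(W2)) - node_strength(cn), c(0.7, 0.7, 0))
})

test_that("betweenness matches the textbook cases", {
  expect_equal(betweenness_centrality(unit_path3()), c(0, 1, 0))
  expect_equal(betweenness_centrality(unit_star(3)), c(3, 0, 0, 0))
  expect_equal(betweenness_centrality(complete_graph(5)), rep(0, 5))
  expect_equal(betweenness_centrality(unit_star(3), normalized = TRUE),
               c(1, 0, 0, 0))
})

test_that("clustering is the Onnela coefficient with max-normalized weights", {
  expect_equal(clustering_coefficient(unit_triangle()), rep(1, 3))
  expect_equal(clustering_coefficient(unit_path3()), rep(0, 3))
  tri <- cn_of(sym_matrix(3, list(c(1, 2, 1), c(2, 3, 1), c(1, 3, 8))))
  expect_equal(clustering_coefficient(tri), rep(0.25, 3))
})

test_that("clustering stays in [0,1] and reduces to the binary form", {
  set.seed(11)
  for (r in 1:20) {
    cn <- random_small_graph(sample(4:7, 1))
    cc <- clustering_coefficient(cn)
    expect_true(all(cc >= 0 & cc <= 1))
    bin <- binarize(cn)
    A <- bin$weights
    k <- rowSums(A)
    tri <- diag(A %*% A %*% A)
    expected <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
    expect_equal(clustering_coefficient(bin), expected, tolerance = 1e-12)
  }
})

test_that("path-based measures agree with exhaustive enumeration", {
  set.seed(21)
  for (r in 1:25) {
    cn <- random_small_graph(sample(4:7, 1))
    oracle <- oracle_paths(cn$weights)
    geo <- geodesics(cn)
    expect_equal(geo$lengths, oracle$lengths, tolerance = 1e-9)
    expect_equal(geo$counts, oracle$counts)
    expect_equal(betweenness_centrality(cn), oracle$betweenness,
                 tolerance = 1e-9)
  }
})

test_that("global measures match hand computation on small graphs", {
  tri <- global_measures(unit_triangle(), small_worldness = FALSE)
  expect_equal(tri$density, 1)
  expect_equal(tri$global_efficiency, 1)
  expect_equal(tri$characteristic_path_length, 1)
  expect_equal(tri$diameter, 1)
  expect_false(tri$disconnected)

  p3 <- global_measures(unit_path3(), small_worldness = FALSE)
  expect_equal(p3$global_efficiency, 5 / 6)
  expect_equal(p3$characteristic_path_length, 4 / 3)
  expect_equal(p3$diameter, 2)

  expect_error(global_measures(cn_of(matrix(0, 3, 3))), "degenerate graph")
  expect_equal(global_measures(cn_of(matrix(0, 3, 3) + 1 - diag(3)),
                               small_worldness = FALSE)$density, 1)
})

test_that("efficiency never decreases when a weight increases", {
  set.seed(31)
  for (r in 1:10) {
    cn <- random_small_graph(6)
    e0 <- global_measures(cn, small_worldness = FALSE)$global_efficiency
    W <- cn$weights
    up <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    pick <- up[sample(nrow(up), 1), ]
    W[pick[1], pick[2]] <- W[pick[2], pick[1]] <- W[pick[1], pick[2]] + 1
    e1 <- global_measures(cn_of(W), small_worldness = FALSE)$global_efficiency
    expect_gte(e1, e0 - 1e-12)
  }
})

test_that("measures are equivariant under node relabeling", {
  set.seed(41)
  cn <- random_small_graph(7)
  perm <- sample(7)
  Wp <- cn$weights[perm, perm]
  cnp <- cn_of(Wp)
  expect_equal(node_strength(cnp), node_strength(cn)[perm])
  expect_equal(betweenness_centrality(cnp),
               betweenness_centrality(cn)[perm], tolerance = 1e-9)
  expect_equal(clustering_coefficient(cnp),
               clustering_coefficient(cn)[perm], tolerance = 1e-12)
  expect_equal(node_curvature(cnp), node_curvature(cn)[perm],
               tolerance = 1e-9)
})

test_that("rewired surrogates preserve degrees and the weight multiset", {
  set.seed(51)
  cfg <- generator_config(n_nodes = 40, decay_length = 100, seed = 5)
  cn <- generate_subject_connectome(generate_parcellation(40, 6), cfg,
                                    "control", 77)
  r1 <- rewired_null(cn, n_swaps = 1e4, seed = 99)
  r2 <- rewired_null(cn, n_swaps = 1e4, seed = 99)
  expect_identical(r1$weights, r2$weights)
  expect_equal(rowSums(r1$weights > 0), rowSums(cn$weights > 0))
  expect_equal(sort(r1$weights[upper.tri(r1$weights) & r1$weights > 0]),
               sort(cn$weights[upper.tri(cn$weights) & cn$weights > 0]))
  expect_false(identical(r1$weights, cn$weights))

  tiny <- cn_of(sym_matrix(3, list(c(1, 2, 1))))
  expect_warning(same <- rewired_null(tiny), "fewer than 2 edges")
  expect_identical(same$weights, tiny$weights)
})

test_that("a Watts-Strogatz-style graph is small-world by sigma", {
  set.seed(61)
  g <- igraph::sample_smallworld(1, 100, 3, 0.1)
  W <- igraph::as_adjacency_matrix(g, sparse = FALSE) * 1
  sw <- global_measures(cn_of(W), small_worldness = TRUE, n_null = 20,
                        seed = 62)$small_worldness
  expect_gt(sw, 1)
})
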