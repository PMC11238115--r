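test_that("centering zeroes the centroid and preserves distances", {
  expect_equal(center_coordinates(conformer(matrix(c(3, 4, 5), 1)))$coords,
               matrix(0, 1, 3))
  pair <- center_coordinates(conformer(rbind(c(0, 0, 0), c(2, 0, 0))))
  expect_equal(pair$coords, rbind(c(-1, 0, 0), c(1, 0, 0)))
  set.seed(1)
  conf <- conformer(matrix(rnorm(30, sd = 3), 10, 3))
  cent <- center_coordinates(conf)
  expect_lt(max(abs(colMeans(cent$coords))), 1e-12)
  expect_equal(brute_dist(cent$coords), brute_dist(conf$coords),
               tolerance = 1e-12)
  expect_error(conformer(matrix(numeric(0), 0, 3)), "at least one atom")
  expect_error(conformer(matrix(c(1, NA, 0), 1, 3)), "finite")
})

test_that("gram_from_coords matches hand values and the brute-force oracle", {
  g <- gram_from_coords(conformer(rbind(c(-1, 0, 0), c(1, 0, 0))))
  expect_equal(unclass(g), rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)
  expect_equal(unclass(gram_from_coords(conformer(matrix(c(5, -2, 7), 1)))),
               matrix(0, 1, 1), ignore_attr = TRUE)
  set.seed(7)
  coords <- matrix(rnorm(18, sd = 2), 6, 3)
  g2 <- gram_from_coords(conformer(coords))
  expect_equal(unclass(g2), brute_gram(coords), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(diag(g2)),
               sum(sweep(coords, 2, colMeans(coords))^2), tolerance = 1e-12)
})

test_that("distance_from_coords matches the brute-force oracle", {
  d <- distance_from_coords(conformer(rbind(c(-1, 0, 0), c(1, 0, 0))))
  expect_equal(d[1, 2], 2)
  set.seed(11)
  coords <- matrix(rnorm(24, sd = 2), 8, 3)
  dm <- distance_from_coords(conformer(coords))
  expect_equal(diag(unclass(dm)), rep(0, 8))
  expect_equal(unclass(dm), brute_dist(coords), tolerance = 1e-12,
               ignore_attr = TRUE)
  cc <- sweep(coords, 2, colMeans(coords))
  expect_equal(attr(dm, "origin_distances"), sqrt(rowSums(cc^2)),
               tolerance = 1e-12)
})

test_that("G -> D -> G round trips are exact within tolerance", {
  g <- gram_matrix(rbind(c(1, -1), c(-1, 1)))
  d <- gram_to_distance(g)
  expect_equal(d[1, 2], 2)
  expect_equal(diag(unclass(d)), rep(0, 2))
  for (conf in cloud_set()[1:10]) {
    g1 <- gram_from_coords(conf)
    d1 <- gram_to_distance(g1)
    expect_lt(max(abs(unclass(d1) - unclass(distance_from_coords(conf)))),
              1e-10)
    g2 <- distance_to_gram(d1)
    expect_lt(max(abs(unclass(g2) - unclass(g1))), 1e-10)
  }
  # hand arithmetic: D_0i = D_0j = 1, D_ij = 2 -> G_ij = -1 (antipodal)
  d2 <- dist_matrix(rbind(c(0, 2), c(2, 0)), origin_distances = c(1, 1))
  g3 <- distance_to_gram(d2)
  expect_equal(g3[1, 2], -1)
  expect_equal(diag(unclass(g3)), c(1, 1))
  expect_error(distance_to_gram(dist_matrix(rbind(c(0, 2), c(2, 0)))),
               "origin_distances")
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(gram_to_distance(gram_matrix(bad)), "not a valid Gram")
})

test_that("angle cosines from G match the direct vector formula", {
  we <- worked_examples()
  rt <- we$right_angle_triple
  g <- gram_from_coords(rt$conformer)
  expect_equal(angle_cosine_from_gram(g, rt$expect$i, rt$expect$j,
                                      rt$expect$k), 0, tolerance = 1e-12)
  lc <- we$linear_chain_3
  expect_equal(angle_cosine_from_gram(gram_from_coords(lc$conformer),
                                      1, 2, 3), -1, tolerance = 1e-12)
  tet <- we$tetrahedron_5
  gt <- gram_from_coords(tet$conformer)
  arms <- tet$expect$arms
  for (a in seq_along(arms)) for (b in seq_along(arms)) {
    if (a >= b) next
    expect_equal(angle_cosine_from_gram(gt, arms[a], tet$expect$center,
                                        arms[b]), -1 / 3, tolerance = 1e-12)
  }
  # random conformers, uncentered input: centering offset must not matter
  set.seed(5)
  for (r in 1:5) {
    coords <- matrix(rnorm(15, sd = 2), 5, 3) + 10
    g5 <- gram_from_coords(conformer(coords))
    trip <- sample(5, 3)
    expect_equal(angle_cosine_from_gram(g5, trip[1], trip[2], trip[3]),
                 brute_angle_cos(coords, trip[1], trip[2], trip[3]),
                 tolerance = 1e-10)
  }
  expect_error(angle_cosine_from_gram(g, 1, 1, 2), "distinct")
  degenerate <- gram_from_coords(conformer(rbind(c(0, 0, 0), c(0, 0, 0),
                                                 c(1, 0, 0))))
  expect_error(angle_cosine_from_gram(degenerate, 1, 2, 3), "degenerate")
})

test_that("MDS reconstruction is exact for exact Gram matrices", {
  for (conf in cloud_set()[1:10]) {
    rec <- mds_reconstruct(gram_from_coords(conf))
    expect_lt(aligned_rmsd(conf, rec, allow_reflection = TRUE,
                           heavy_only = FALSE), 1e-8)
    # reconstruction fixed point: G(reconstruction) = G
    expect_lt(max(abs(unclass(gram_from_coords(rec)) -
                        unclass(gram_from_coords(conf)))), 1e-8)
  }
  hexagon <- worked_examples()$planar_ring_6$conformer
  rec2 <- mds_reconstruct(gram_from_coords(hexagon))
  expect_lt(max(abs(rec2$coords[, 3])), 1e-9)
})

test_that("top-3 truncation of a noisy G matches a full-eigendecomposition oracle", {
  conf <- cloud_set()[[1]]
  g <- add_gram_noise(gram_from_coords(conf), sigma = 0.05, seed = 9)
  rec <- mds_reconstruct(g)
  es <- eigen((unclass(g) + t(unclass(g))) / 2, symmetric = TRUE)
  lam <- pmax(es$values[1:3], 0)
  oracle <- es$vectors[, 1:3] %*% diag(sqrt(lam))
  oracle <- sweep(oracle, 2, colMeans(oracle))
  expect_lt(aligned_rmsd(conformer(oracle), rec, allow_reflection = TRUE,
                         heavy_only = FALSE), 1e-10)
})

test_that("Gram noise injection is seeded, symmetric and correctly scaled", {
  g <- gram_from_coords(cloud_set()[[2]])
  expect_identical(unclass(add_gram_noise(g, 0)), unclass(g))
  n1 <- add_gram_noise(g, 0.3, seed = 4)
  n2 <- add_gram_noise(g, 0.3, seed = 4)
  expect_identical(unclass(n1), unclass(n2))
  expect_equal(unclass(n1), t(unclass(n1)))
  expect_error(add_gram_noise(g, -1), "non-negative")
  big <- gram_from_coords(generate_point_clouds(1, 200, box = 20,
                                                seed = 8)[[1]])
  pert <- unclass(add_gram_noise(big, 0.5, seed = 2)) - unclass(big)
  sd_emp <- stats::sd(pert[upper.tri(pert)])
  expect_lt(abs(sd_emp - 0.5) / 0.5, 0.1)
})

test_that("the Gram matrix is E(3)-invariant", {
  set.seed(17)
  for (conf in cloud_set()[1:8]) {
    g0 <- unclass(gram_from_coords(conf))
    for (r in 1:4) {
      moved <- apply_motion(conf, random_rigid_motion(reflect = r %% 2 == 0))
      expect_lt(max(abs(unclass(gram_from_coords(moved)) - g0)), 1e-9)
    }
  }
  we <- worked_examples()$mirror_pair_chiral
  g1 <- gram_from_coords(we$conformers[[1]])
  g2 <- gram_from_coords(we$conformers[[2]])
  expect_lt(max(abs(unclass(g1) - unclass(g2))), 1e-12)
})

test_that("exact conformers give rank-3 Gram matrices (2 planar, 1 collinear)", {
  for (conf in cloud_set()[1:8]) {
    expect_identical(gram_rank(gram_from_coords(conf))$rank, 3L)
  }
  we <- worked_examples()
  expect_identical(gram_rank(gram_from_coords(we$planar_ring_6$conformer))$rank,
                   2L)
  expect_identical(gram_rank(gram_from_coords(we$linear_chain_3$conformer))$rank,
                   1L)
})
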