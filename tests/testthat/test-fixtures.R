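test_that("point clouds respect separation, sizes and seeding", {
  clouds <- generate_point_clouds(50, c(3, 12), min_separation = 0.8,
                                  seed = 42)
  expect_length(clouds, 50)
  for (cl in clouds) {
    expect_gte(min(stats::dist(cl$coords)), 0.8)
    expect_true(all(cl$heavy_mask))
  }
  again <- generate_point_clouds(50, c(3, 12), min_separation = 0.8,
                                 seed = 42)
  expect_identical(clouds, again)
  single <- generate_point_clouds(1, 1L, seed = 1)[[1]]
  expect_identical(nrow(single$coords), 1L)
  expect_error(generate_point_clouds(1, 50, box = 1, min_separation = 2,
                                     seed = 1), "min_separation")
})

test_that("toy molecules are valid, QM9-sized, and internally consistent", {
  mols <- generate_toy_molecules(24, max_heavy = 9, seed = 7)
  for (g in mols) {
    expect_silent(sanitize_graph(g))
    expect_lte(sum(g$elements != "H"), 9L)
    expect_lte(length(g$elements), 29L)
    expect_true(all(g$elements %in% c("H", "C", "N", "O", "F")))
    expect_false(is.null(g$conformer))
    # geometry consistency: targets derived from G reproduce lengths/angles
    tg <- build_targets(g)
    dg <- derive_geometry_from_gram(tg$G, tg$bonds[, c("u", "v")],
                                    tg$angles[, c("i", "j", "k")])
    expect_equal(dg$lengths, tg$bonds$length, tolerance = 1e-10)
    if (nrow(tg$angles)) {
      expect_equal(acos(pmax(-1, pmin(1, dg$cosines))), tg$angles$angle,
                   tolerance = 1e-8)
    }
    # atoms are not on top of each other
    expect_gt(min(stats::dist(g$conformer$coords)), 0.5)
  }
  expect_identical(
    vapply(generate_toy_molecules(4, seed = 9), function(g) g$id, character(1)),
    vapply(generate_toy_molecules(4, seed = 9), function(g) g$id, character(1)))
})

test_that("the default toy set covers every reachable feature value", {
  mols <- generate_toy_molecules(24, max_heavy = 9, seed = 7)
  fts <- lapply(mols, featurize)
  atoms <- do.call(rbind, lapply(fts, `[[`, "atoms"))
  bonds <- do.call(rbind, lapply(fts, `[[`, "bonds"))
  # elements C/N/O/F/H all appear
  expect_true(all(c(1, 6, 7, 8, 9) %in% atoms[, 1]))
  # hybridizations sp, sp2, sp3 all appear (sp3d/sp3d2 unreachable in CNOF)
  expect_true(all(colSums(atoms[, 2:4, drop = FALSE]) > 0))
  # aromatic atoms and bonds appear
  expect_gt(sum(atoms[, 10]), 0)
  expect_gt(sum(bonds[, 2]), 0)
  # all four bond types appear: single, double, triple, aromatic
  expect_true(all(colSums(bonds[, 4:7, drop = FALSE]) > 0))
  # conjugation and rings appear
  expect_gt(sum(bonds[, 1]), 0)
  expect_gt(sum(bonds[, 3]), 0)
})

test_that("worked examples carry their stated analytic properties", {
  we <- worked_examples()
  tet <- we$tetrahedron_5
  g <- gram_from_coords(tet$conformer)
  for (pair in utils::combn(tet$expect$arms, 2, simplify = FALSE)) {
    expect_equal(angle_cosine_from_gram(g, pair[1], tet$expect$center,
                                        pair[2]),
                 tet$expect$cos_arm_pairs, tolerance = 1e-12)
  }
  expect_identical(gram_rank(gram_from_coords(we$planar_ring_6$conformer))$rank,
                   we$planar_ring_6$expect$rank)
  m <- we$mirror_pair_chiral
  expect_lt(max(abs(unclass(gram_from_coords(m$conformers[[1]])) -
                      unclass(gram_from_coords(m$conformers[[2]])))), 1e-12)
  # ... but the mirror pair is genuinely chiral: proper-rotation alignment
  # cannot superpose them
  expect_gt(aligned_rmsd(m$conformers[[1]], m$conformers[[2]],
                         allow_reflection = FALSE, heavy_only = FALSE), 0.05)
  expect_lt(aligned_rmsd(m$conformers[[1]], m$conformers[[2]],
                         allow_reflection = TRUE, heavy_only = FALSE), 1e-10)
})
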