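test_that("R^2, RMSE and MAE follow their definitions", {
  set.seed(2)
  y <- rnorm(50); yh <- y + rnorm(50, 0, 0.3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(rmse(y, y), 0)
  expect_equal(mae(y, y), 0)
  expect_equal(r_squared(y, rep(mean(y), 50)), 0)
  # brute-force formula evaluation
  expect_lt(abs(r_squared(y, yh) -
                  (1 - sum((y - yh)^2) / sum((y - mean(y))^2))), 1e-12)
  expect_lt(abs(rmse(y, yh) - sqrt(sum((y - yh)^2) / 50)), 1e-12)
  expect_lt(abs(mae(y, yh) - sum(abs(y - yh)) / 50), 1e-12)
  expect_gte(rmse(y, yh), mae(y, yh))
  expect_error(r_squared(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(rmse(1:3, 1:4), "shapes differ")
})

test_that("aligned RMSD is invariant to rigid motions and handles mirrors", {
  set.seed(31)
  conf <- cloud_set()[[3]]
  moved <- apply_motion(conf, random_rigid_motion())
  expect_lt(aligned_rmsd(conf, moved, heavy_only = FALSE), 1e-10)
  mirrored <- conformer(conf$coords %*% diag(c(1, 1, -1)),
                        elements = conf$elements)
  expect_lt(aligned_rmsd(conf, mirrored, allow_reflection = TRUE,
                         heavy_only = FALSE), 1e-10)
  # one heavy atom displaced by 1 A in a 4-heavy-atom molecule, no
  # alignment: RMSD = sqrt(1/4) = 0.5
  base <- conformer(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3)))
  disp <- base$coords; disp[1, ] <- disp[1, ] + c(1, 0, 0)
  expect_equal(aligned_rmsd(base, conformer(disp), align = FALSE), 0.5,
               tolerance = 1e-12)
  expect_error(aligned_rmsd(conf, conformer(conf$coords[1:3, , drop = FALSE])),
               "atom counts")
  other <- conformer(conf$coords, elements = rep("N", nrow(conf$coords)))
  expect_error(aligned_rmsd(conf, other), "element order")
})

test_that("aligned RMSD behaves as a pseudo-metric on rigid-motion orbits", {
  set.seed(7)
  confs <- cloud_set()[4:6]
  n <- min(vapply(confs, function(cf) nrow(cf$coords), integer(1)))
  trim <- lapply(confs, function(cf) conformer(cf$coords[1:n, , drop = FALSE]))
  d <- function(a, b) aligned_rmsd(a, b, heavy_only = FALSE)
  for (i in 1:3) expect_lt(d(trim[[i]], trim[[i]]), 1e-12)
  expect_equal(d(trim[[1]], trim[[2]]), d(trim[[2]], trim[[1]]),
               tolerance = 1e-8)
  expect_lte(d(trim[[1]], trim[[3]]),
             d(trim[[1]], trim[[2]]) + d(trim[[2]], trim[[3]]) + 1e-10)
})

test_that("COV and MAT follow their ensemble definitions", {
  conf <- cloud_set()[[1]]
  same <- coverage_and_matching(list(conf), list(conf), delta = 2)
  expect_equal(same$COV, 1)
  expect_lt(same$MAT, 1e-12)
  # a generated conformer 3 A away from the single reference at delta 2
  far <- conformer(conf$coords + matrix(rnorm(length(conf$coords), 0, 4),
                                        ncol = 3))
  dfar <- aligned_rmsd(conf, far, heavy_only = FALSE)
  cm <- coverage_and_matching(list(far), list(conf), delta = 2)
  if (dfar >= 2) expect_equal(cm$COV, 0) else expect_equal(cm$COV, 1)
  expect_equal(cm$MAT, dfar, tolerance = 1e-10)
  expect_error(coverage_and_matching(list(conf), list(), 2), "empty")
  expect_error(coverage_and_matching(list(conf), list(conf), -1), "positive")
})

test_that("COV is non-decreasing in delta and MAT is delta-independent", {
  set.seed(12)
  refs <- cloud_set()[7:12]
  n <- min(vapply(refs, function(cf) nrow(cf$coords), integer(1)))
  refs <- lapply(refs, function(cf) conformer(cf$coords[1:n, , drop = FALSE]))
  gens <- lapply(refs, function(cf) {
    conformer(cf$coords + matrix(rnorm(3 * n, 0, 0.8), n, 3))
  })
  deltas <- c(0.25, 0.5, 1, 2, 4)
  # max_ensemble = 1: COV must equal the indicator mean, MAT the mean RMSD
  rmsds <- mapply(function(r, g) aligned_rmsd(r, g, heavy_only = FALSE),
                  refs, gens)
  covs <- vapply(deltas, function(dl) {
    res <- coverage_and_matching(gens[1], refs[1], delta = dl)$COV
    # pooled over molecules by brute force
    mean(vapply(seq_along(refs), function(i) {
      coverage_and_matching(gens[i], refs[i], delta = dl)$COV
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(covs) >= 0))
  expect_equal(covs, vapply(deltas, function(dl) mean(rmsds < dl),
                            numeric(1)))
  mats <- vapply(deltas, function(dl) {
    mean(vapply(seq_along(refs), function(i) {
      coverage_and_matching(gens[i], refs[i], delta = dl)$MAT
    }, numeric(1)))
  }, numeric(1))
  expect_equal(max(mats) - min(mats), 0)
  expect_equal(mats[1], mean(rmsds), tolerance = 1e-10)
})
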