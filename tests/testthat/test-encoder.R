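small_cfg <- encoder_config(layers = 2L, hidden = 16L, heads = 2L,
                            ffn_width = 32L, noise_sigma = 0, seed = 3L)

test_that("initial states have the documented shape and determinism", {
  enc <- init_encoder(small_cfg)
  g <- toy_set()[[1]]
  h0 <- initialize_states(enc, g)
  expect_identical(dim(h0), c(length(g$elements) + 1L, 16L))
  expect_identical(initialize_states(enc, g), h0)
  # atoms with identical features and equal degree share initial states:
  # methane's four hydrogens are indistinguishable before noise
  met <- methane_graph()
  h0m <- initialize_states(enc, met)
  for (a in 3:5) expect_equal(h0m[a, ], h0m[2, ], tolerance = 1e-12)
  # degree above the cap folds into the cap bucket without error
  star <- molecular_graph(c("C", rep("H", 12)),
                          data.frame(u = 1, v = 2:13, order = "1"))
  cfg_cap <- encoder_config(layers = 1L, hidden = 16L, heads = 2L,
                            max_degree_cap = 4L, noise_sigma = 0)
  expect_silent(initialize_states(init_encoder(cfg_cap), star))
})

test_that("state noise is seeded and has the configured moments", {
  cfg <- encoder_config(hidden = 64L, noise_mu = 0.5, noise_sigma = 0.2)
  z1 <- make_state_noise(200L, cfg, seed = 11L)
  z2 <- make_state_noise(200L, cfg, seed = 11L)
  expect_identical(z1, z2)
  expect_lt(abs(mean(z1) - 0.5) / 0.5, 0.05)
  expect_lt(abs(stats::sd(z1) - 0.2) / 0.2, 0.05)
  cfg0 <- encoder_config(noise_mu = 0, noise_sigma = 0)
  h0 <- matrix(rnorm(40), 5, 8)
  expect_identical(inject_noise(h0, cfg0, seed = 1), h0)
})

test_that("the forward pass is deterministic and finite at sigma = 0", {
  enc <- init_encoder(small_cfg)
  for (g in toy_set()[1:4]) {
    e1 <- encode(enc, g)
    e2 <- encode(enc, g)
    expect_identical(e1$h, e2$h)
    expect_true(all(is.finite(e1$h)))
    expect_true(all(is.finite(e1$super)))
    expect_identical(dim(e1$h), c(length(g$elements), 16L))
  }
})

test_that("the predicted Gram matrix is symmetric PSD for arbitrary parameters", {
  g <- toy_set()[[2]]
  for (s in 1:5) {
    enc <- init_encoder(encoder_config(layers = 2L, hidden = 16L, heads = 2L,
                                       noise_sigma = 0, seed = s * 13L))
    emb <- encode(enc, g)
    Ghat <- predict_gram(emb)
    expect_equal(unclass(Ghat), t(unclass(Ghat)), tolerance = 1e-12)
    ev <- eigen(unclass(Ghat), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev, 1))
    # brute-force double loop of dot products
    n <- nrow(emb$h)
    bf <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      bf[i, j] <- sum(emb$h[i, ] * emb$h[j, ])
    }
    expect_equal(unclass(Ghat), bf, tolerance = 1e-12)
  }
})

test_that("the encoder is permutation-equivariant", {
  enc <- init_encoder(small_cfg)
  for (g in toy_set()[c(1, 3, 4)]) {
    n <- length(g$elements)
    base <- encode(enc, g)$h
    set.seed(n)
    for (r in 1:5) {
      perm <- sample(n)
      inv <- order(perm)
      # relabel atoms by perm: atom perm[i] of the original becomes atom i
      bonds <- g$bonds
      bonds$u <- inv[g$bonds$u]; bonds$v <- inv[g$bonds$v]
      gp <- molecular_graph(g$elements[perm], bonds, id = g$id)
      hp <- encode(enc, gp)$h
      expect_equal(hp, base[perm, , drop = FALSE], tolerance = 1e-8)
    }
  }
})

test_that("geometric heads map into their physical ranges", {
  g <- toy_set()[[1]]
  for (s in c(2L, 31L)) {
    enc <- init_encoder(encoder_config(layers = 2L, hidden = 16L, heads = 2L,
                                       noise_sigma = 0, seed = s))
    emb <- encode(enc, g)
    d0 <- predict_origin_distances(enc, emb)
    expect_length(d0, length(g$elements))
    expect_true(all(d0 >= 0))
    len <- predict_bond_lengths(enc, emb, g$bonds)
    expect_true(all(len > 0))
    tri <- build_targets(g)$angles
    ang <- predict_bond_angles(enc, emb, tri[, c("i", "j", "k")])
    expect_true(all(ang > 0 & ang < pi))
    # angle head is symmetric under (i,j,k) -> (k,j,i)
    rev_tri <- tri[, c("k", "j", "i")]
    names(rev_tri) <- c("i", "j", "k")
    expect_identical(predict_bond_angles(enc, emb, rev_tri), ang)
  }
})

test_that("geometry derived from an exact Gram matrix matches the conformer", {
  g <- toy_set()[[3]]
  tg <- build_targets(g)
  dg <- derive_geometry_from_gram(tg$G, tg$bonds[, c("u", "v")],
                                  tg$angles[, c("i", "j", "k")])
  expect_equal(dg$lengths, tg$bonds$length, tolerance = 1e-10)
  expect_equal(dg$cosines, cos(tg$angles$angle), tolerance = 1e-10)
  expect_false(any(dg$clamped))
  tet <- methane_graph()
  tgt <- build_targets(tet)
  dgt <- derive_geometry_from_gram(tgt$G, tgt$bonds[, c("u", "v")],
                                   tgt$angles[, c("i", "j", "k")])
  expect_equal(dgt$cosines, rep(-1 / 3, 6), tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- encoder_config(layers = 2L, hidden = 8L, heads = 2L,
                        ffn_width = 16L, noise_sigma = 0.05, seed = 5L)
  enc <- init_encoder(cfg)
  g <- generate_toy_molecules(1, max_heavy = 4, seed = 11)[[1]]
  cm <- gramconf:::prep_molecule(g, cfg)
  tg <- build_targets(g)
  set.seed(9)
  noise <- matrix(rnorm(cm$n * cfg$hidden, 0, 0.05), cm$n, cfg$hidden)
  w <- gramconf:::.full_weights(NULL)
  eps <- 1e-6
  for (variant in c("a", "b", "c", "d")) {
    r <- gramconf:::.molecule_loss_grad(enc$params, cfg, cm, tg, variant, w,
                                        TRUE, noise)
    set.seed(match(variant, letters))
    for (nm in sample(names(r$grads), 6)) {
      k <- sample(length(enc$params[[nm]]), 1)
      p2 <- enc$params
      p2[[nm]][k] <- p2[[nm]][k] + eps
      lp <- gramconf:::.molecule_loss_grad(p2, cfg, cm, tg, variant, w, TRUE,
                                           noise, with_grad = FALSE)$total
      p2[[nm]][k] <- p2[[nm]][k] - 2 * eps
      lm <- gramconf:::.molecule_loss_grad(p2, cfg, cm, tg, variant, w, TRUE,
                                           noise, with_grad = FALSE)$total
      fd <- (lp - lm) / (2 * eps)
      an <- r$grads[[nm]][k]
      expect_lt(abs(fd - an), 1e-4 * max(1, abs(fd) + abs(an)))
    }
  }
})
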