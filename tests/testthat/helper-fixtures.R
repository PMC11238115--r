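# Shared helpers for the suite: small cached fixture sets and independent
# brute-force oracles kept deliberately separate from the package's own
# code paths.

toy_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_toy_molecules(8, max_heavy = 6,
                                                         seed = 21)
    cache
  }
})

cloud_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_point_clouds(20, c(4, 12),
                                                        seed = 3)
    cache
  }
})

# brute-force Gram: explicit double loop over centered coordinates
brute_gram <- function(coords) {
  x <- sweep(coords, 2, colMeans(coords))
  n <- nrow(x)
  g <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) g[i, j] <- sum(x[i, ] * x[j, ])
  g
}

brute_dist <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  }
  d
}

# direct vector-formula angle cosine, independent of any Gram arithmetic
brute_angle_cos <- function(coords, i, j, k) {
  a <- coords[i, ] - coords[j, ]
  b <- coords[k, ] - coords[j, ]
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Floyd-Warshall all-pairs shortest hops, independent of the BFS code
brute_hops <- function(n, bonds) {
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (b in seq_len(nrow(bonds))) {
    d[bonds$u[b], bonds$v[b]] <- 1
    d[bonds$v[b], bonds$u[b]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

random_rigid_motion <- function(reflect = FALSE) {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  rot <- qr.Q(qr_)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  if (reflect) rot[, 3] <- -rot[, 3]
  list(rot = rot, shift = stats::rnorm(3, 0, 5))
}

apply_motion <- function(conf, motion) {
  conformer(sweep(conf$coords %*% motion$rot, 2, -motion$shift),
            elements = conf$elements, heavy_mask = conf$heavy_mask)
}

# a small fixed water-like molecule for hand-countable targets
water_graph <- function() {
  ang <- 104.5 * pi / 180
  coords <- rbind(c(0, 0, 0),
                  c(0.9572, 0, 0),
                  c(cos(ang), sin(ang), 0) * 0.9572)
  g <- molecular_graph(c("O", "H", "H"),
                       data.frame(u = c(1, 1), v = c(2, 3), order = "1"),
                       id = "water")
  g$conformer <- conformer(coords, elements = g$elements)
  g
}

methane_graph <- function() {
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  coords <- rbind(c(0, 0, 0), dirs * 1.09)
  g <- molecular_graph(c("C", rep("H", 4)),
                       data.frame(u = 1, v = 2:5, order = "1"),
                       id = "methane")
  g$conformer <- conformer(coords, elements = g$elements)
  g
}

# straight-line reimplementation of the four losses, loops only
brute_loss <- function(pred, tg, variant, angle_squared = TRUE) {
  n <- nrow(tg$G)
  total <- 0
  if (variant %in% c("a", "b")) {
    s <- 0
    for (i in 1:n) for (j in 1:n) s <- s + (tg$D[i, j] - pred$Dhat[i, j])^2
    total <- total + s / n^2
  }
  if (variant == "b") {
    d0 <- attr(tg$D, "origin_distances")
    total <- total + sum((d0 - pred$d0hat)^2) / n
  }
  if (variant %in% c("c", "d")) {
    s <- 0
    for (i in 1:n) for (j in 1:n) s <- s + (tg$G[i, j] - pred$Ghat[i, j])^2
    total <- total + s / n^2
  }
  if (variant == "d") {
    if (nrow(tg$bonds) > 0) {
      total <- total + mean((tg$bonds$length - pred$lengths)^2)
    }
    if (nrow(tg$angles) > 0) {
      total <- total + if (angle_squared) {
        mean((tg$angles$angle - pred$angles)^2)
      } else mean(tg$angles$angle - pred$angles)
    }
  }
  total
}

# random chain molecule of n atoms with arbitrary coordinates, for loss
# tests at sizes the toy generator does not emit (n = 2 upward)
random_chain_instance <- function(n, seed) {
  set.seed(seed)
  bonds <- if (n >= 2) {
    data.frame(u = seq_len(n - 1), v = 2:n, order = "1")
  } else NULL
  g <- molecular_graph(rep("C", n), bonds, id = sprintf("chain%d_%d", n, seed))
  g$conformer <- conformer(matrix(rnorm(3 * n, sd = 1.5), n, 3))
  g
}

random_predictions <- function(tg) {
  n <- nrow(tg$G)
  sym <- matrix(rnorm(n * n), n, n); sym <- (sym + t(sym)) / 2
  dd <- abs(matrix(rnorm(n * n), n, n)); dd <- (dd + t(dd)) / 2; diag(dd) <- 0
  list(Dhat = unclass(tg$D) + dd * 0.3,
       d0hat = attr(tg$D, "origin_distances") + rnorm(n, 0, 0.2),
       Ghat = unclass(tg$G) + sym * 0.3,
       lengths = tg$bonds$length + rnorm(nrow(tg$bonds), 0, 0.1),
       angles = pmin(pi - 0.01, pmax(0.01,
         tg$angles$angle + rnorm(nrow(tg$angles), 0, 0.1))))
}

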