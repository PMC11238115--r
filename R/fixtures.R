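# Synthetic fixtures: random 3D point clouds, small idealized-geometry
# molecules (QM9-like: up to 9 heavy atoms over C/N/O/F plus explicit H),
# and hand-constructed worked examples. Generation code is the source of
# truth for all test inputs; nothing is checked in as an opaque file.

#' Generate random 3D point clouds
#'
#' Uniform points in a cubic box, rejection-sampled until the minimum
#' pairwise distance reaches `min_separation`. Elements are set to carbon so
#' the clouds can stand in for conformers in purely geometric tests.
#'
#' @param n_clouds Number of clouds.
#' @param n_atoms Integer vector (recycled) or range `c(lo, hi)` sampled per
#'   cloud.
#' @param box Edge length of the sampling box (Angstrom).
#' @param min_separation Minimum pairwise distance (Angstrom).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return List of [conformer()] objects.
#' @export
generate_point_clouds <- function(n_clouds, n_atoms = c(4L, 16L), box = 8,
                                  min_separation = 0.8, seed = 1L) {
  stopifnot(n_clouds >= 1L, min_separation > 0, box > 0)
  old <- .save_rng_state(); on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  sizes <- if (length(n_atoms) == 2L && n_atoms[2] > n_atoms[1]) {
    sample(seq(n_atoms[1], n_atoms[2]), n_clouds, replace = TRUE)
  } else rep_len(as.integer(n_atoms), n_clouds)
  lapply(seq_len(n_clouds), function(i) {
    n <- sizes[i]
    for (try in seq_len(200L)) {
      x <- matrix(stats::runif(n * 3, -box / 2, box / 2), n, 3)
      if (n == 1L || min(stats::dist(x)) >= min_separation) {
        return(conformer(x))
      }
    }
    stop("could not satisfy min_separation within the box after 200 tries")
  })
}

# --- idealized coordinate build ------------------------------------------

.ideal_angle <- function(hyb) {
  switch(hyb, sp = pi, sp2 = 2 * pi / 3, sp3 = acos(-1 / 3), acos(-1 / 3))
}

.unit <- function(v) v / sqrt(sum(v^2))

.any_perp <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(a - sum(a * u) * u)
}

# Place coordinates for an acyclic graph by natural-extension: children of
# each atom are laid out at the parent's ideal angle with torsions spread
# evenly (plus a random base torsion), standard bond lengths per element
# pair and order.
.embed_tree <- function(graph) {
  n <- n_atoms(graph)
  adj <- .adjacency_list(graph)
  hyb <- .hybridization(graph)
  coords <- matrix(NA_real_, n, 3)
  parent <- rep(NA_integer_, n)
  coords[1, ] <- 0
  order_bfs <- 1L; queue <- 1L
  placed <- rep(FALSE, n); placed[1] <- TRUE
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    nbrs <- adj[[p]][, 1]
    kids <- nbrs[!placed[nbrs]]
    if (!length(kids)) next
    # reference direction: from parent-of-p to p (pseudo-direction at root)
    u <- if (is.na(parent[p])) c(0, 0, -1) else .unit(coords[p, ] - coords[parent[p], ])
    theta <- .ideal_angle(hyb[p])
    v <- .any_perp(u)
    w <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    base_tor <- stats::runif(1, 0, 2 * pi)
    # sp2/sp3 parents with an existing placed child need torsions offset
    # from that child; even spreading handles clashes well enough here
    k <- 0L
    for (a in kids) {
      ord <- graph$bonds$order[(graph$bonds$u == min(a, p)) &
                                 (graph$bonds$v == max(a, p))]
      len <- .lookup_bond_length(graph$elements[p], graph$elements[a], ord)
      tor <- base_tor + k * 2 * pi / max(1L, length(kids))
      dirv <- cos(pi - theta) * u +
        sin(pi - theta) * (cos(tor) * v + sin(tor) * w)
      coords[a, ] <- coords[p, ] + len * dirv
      parent[a] <- p
      placed[a] <- TRUE
      queue <- c(queue, a)
      k <- k + 1L
    }
  }
  conformer(coords, elements = graph$elements)
}

# Planar aromatic six-ring with radial substituents; ring carbons at the
# benzene radius, substituents pointing outward in the ring plane.
.embed_benzene <- function(graph, ring_idx) {
  n <- n_atoms(graph)
  coords <- matrix(0, n, 3)
  r_ring <- 1.39
  ang <- 2 * pi * (seq_len(6) - 1) / 6
  coords[ring_idx, ] <- cbind(r_ring * cos(ang), r_ring * sin(ang), 0)
  for (b in seq_len(nrow(graph$bonds))) {
    u <- graph$bonds$u[b]; v <- graph$bonds$v[b]
    if (u %in% ring_idx && !(v %in% ring_idx)) {
      len <- .lookup_bond_length(graph$elements[u], graph$elements[v], "1")
      coords[v, ] <- coords[u, ] * (1 + len / r_ring)
    } else if (v %in% ring_idx && !(u %in% ring_idx)) {
      len <- .lookup_bond_length(graph$elements[v], graph$elements[u], "1")
      coords[u, ] <- coords[v, ] * (1 + len / r_ring)
    }
  }
  conformer(coords, elements = graph$elements)
}

.random_heavy_tree <- function(n_heavy) {
  # tree shape first, then elements respecting valence >= degree
  parent <- c(NA_integer_, if (n_heavy > 1L)
    vapply(2:n_heavy, function(i) sample.int(i - 1L, 1L), integer(1)))
  deg <- tabulate(stats::na.omit(parent), nbins = n_heavy) +
    as.integer(!is.na(parent))
  elements <- vapply(seq_len(n_heavy), function(i) {
    cand <- names(.default_valence)[.default_valence >= deg[i]]
    cand <- setdiff(cand, "H")
    sample(cand, 1L, prob = ifelse(cand == "C", 4, 1))
  }, character(1))
  list(parent = parent, elements = elements)
}

.add_hydrogens <- function(elements, bonds) {
  free <- .default_valence[elements] -
    explicit_valence(molecular_graph(elements, bonds))
  for (a in seq_along(elements)) {
    nh <- max(0L, as.integer(round(free[a])))
    if (elements[a] == "H") next
    for (h in seq_len(nh)) {
      elements <- c(elements, "H")
      bonds <- rbind(bonds, data.frame(u = a, v = length(elements),
                                       order = "1"))
    }
  }
  list(elements = elements, bonds = bonds)
}

.toy_tree <- function(n_heavy, id, decorate = c("none", "carbonyl", "nitrile")) {
  decorate <- match.arg(decorate)
  tr <- .random_heavy_tree(n_heavy)
  elements <- tr$elements
  bonds <- data.frame(u = integer(), v = integer(), order = character())
  for (i in seq_along(tr$parent)) {
    if (!is.na(tr$parent[i])) {
      bonds <- rbind(bonds, data.frame(u = tr$parent[i], v = i, order = "1"))
    }
  }
  if (decorate == "carbonyl") {
    deg <- tabulate(c(bonds$u, bonds$v), nbins = length(elements))
    host <- which(elements == "C" & deg <= 2)
    if (length(host)) {
      a <- host[sample.int(length(host), 1L)]
      elements <- c(elements, "O")
      bonds <- rbind(bonds, data.frame(u = a, v = length(elements), order = "2"))
    }
  } else if (decorate == "nitrile") {
    deg <- tabulate(c(bonds$u, bonds$v), nbins = length(elements))
    host <- which(elements == "C" & deg <= 3)
    if (length(host)) {
      a <- host[sample.int(length(host), 1L)]
      elements <- c(elements, "C", "N")
      cidx <- length(elements) - 1L
      bonds <- rbind(bonds,
                     data.frame(u = a, v = cidx, order = "1"),
                     data.frame(u = cidx, v = cidx + 1L, order = "3"))
    }
  }
  withh <- .add_hydrogens(elements, bonds)
  g <- molecular_graph(withh$elements, withh$bonds, id = id)
  g$conformer <- .embed_tree(g)
  g
}

.toy_benzene <- function(id) {
  elements <- rep("C", 6)
  bonds <- data.frame(u = 1:6, v = c(2:6, 1), order = "ar")
  # random substituents: H or F
  subs <- sample(c("H", "F"), 6, replace = TRUE, prob = c(0.8, 0.2))
  for (i in 1:6) {
    elements <- c(elements, subs[i])
    bonds <- rbind(bonds, data.frame(u = i, v = length(elements), order = "1"))
  }
  g <- molecular_graph(elements, bonds, id = id)
  g$conformer <- .embed_benzene(g, 1:6)
  g
}

#' Generate small idealized-geometry toy molecules
#'
#' Samples molecules of up to `max_heavy` heavy atoms over C/N/O/F with
#' explicit hydrogens: random single-bonded trees, trees decorated with a
#' carbonyl (C=O) or a nitrile (C#N) group, and substituted aromatic
#' six-rings. Coordinates come from idealized internal geometry: standard
#' bond lengths by element pair and order, tetrahedral/trigonal/linear
#' angles by hybridization, randomized torsions for trees, exact planar
#' hexagons for rings. The mix deliberately exercises every reachable atom
#' and bond feature of the encoder's input schema.
#'
#' @param n_molecules Number of molecules.
#' @param max_heavy Maximum heavy-atom count (capped at 9, the QM9-style
#'   regime this generator emulates).
#' @param seed Integer seed.
#' @param kinds Character vector of kinds to sample from:
#'   `"tree"`, `"carbonyl"`, `"nitrile"`, `"benzene"`.
#' @return List of [molecular_graph()] objects with attached conformers.
#' @export
generate_toy_molecules <- function(n_molecules, max_heavy = 9L, seed = 1L,
                                   kinds = c("tree", "carbonyl", "nitrile",
                                             "benzene")) {
  stopifnot(n_molecules >= 1L, max_heavy >= 2L)
  max_heavy <- min(as.integer(max_heavy), 9L)
  old <- .save_rng_state(); on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  out <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    kind <- kinds[1L + (i - 1L) %% length(kinds)]
    id <- sprintf("toy_%03d_%s", i, kind)
    g <- switch(kind,
      tree = .toy_tree(sample(3:max_heavy, 1L), id, "none"),
      carbonyl = .toy_tree(sample(2:(max_heavy - 1L), 1L), id, "carbonyl"),
      nitrile = .toy_tree(sample(2:(max_heavy - 2L), 1L), id, "nitrile"),
      benzene = .toy_benzene(id)
    )
    sanitize_graph(g)
    out[[i]] <- g
  }
  out
}

#' Hand-constructed worked examples
#'
#' Small exact-geometry fixtures with their expected Gram/distance/angle
#' values attached as an `expect` list, used throughout the test suite:
#' `right_angle_triple` (90 degree angle at the middle atom),
#' `linear_chain_3` (collinear, cosine -1), `tetrahedron_5` (central atom
#' with four unit arms, every arm-pair cosine -1/3), `mirror_pair_chiral`
#' (a chiral arrangement and its mirror image, identical Gram matrices),
#' `planar_ring_6` (regular hexagon, Gram rank 2).
#'
#' @return Named list of fixtures; each has `conformer` (or `conformers` for
#'   the mirror pair) and an `expect` list of analytic values.
#' @export
worked_examples <- function() {
  tet_dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  hexagon <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6), 0) * 1.39
  chiral <- rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.36, 1.03, 0),
                  c(-0.36, -0.51, 0.89), c(-0.36, -0.51, -0.89) * c(1, 1, 1.2))
  list(
    right_angle_triple = list(
      conformer = conformer(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))),
      expect = list(cos_ijk = 0, i = 1L, j = 2L, k = 3L)
    ),
    linear_chain_3 = list(
      conformer = conformer(rbind(c(-1.5, 0, 0), c(0, 0, 0), c(1.5, 0, 0))),
      expect = list(cos_ijk = -1, i = 1L, j = 2L, k = 3L, rank = 1L)
    ),
    tetrahedron_5 = list(
      conformer = conformer(rbind(c(0, 0, 0), tet_dirs)),
      expect = list(cos_arm_pairs = -1 / 3, center = 1L, arms = 2:5)
    ),
    mirror_pair_chiral = list(
      conformers = list(
        conformer(chiral),
        conformer(chiral * matrix(rep(c(1, 1, -1), each = 5), 5, 3))
      ),
      expect = list(identical_gram = TRUE)
    ),
    planar_ring_6 = list(
      conformer = conformer(hexagon),
      expect = list(rank = 2L)
    )
  )
}
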