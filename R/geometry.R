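# Core geometric objects and exact conversions:
# coordinates <-> Gram matrix <-> distance matrix <-> bond lengths/angles,
# plus eigendecomposition-based (classical MDS) coordinate reconstruction.

#' Construct a conformer
#'
#' A conformer is a specific 3D arrangement of a molecule's atoms: an N x 3
#' coordinate matrix in Angstrom together with element symbols and a
#' heavy-atom (non-hydrogen) mask.
#'
#' @param coords Numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param elements Character vector of length N of element symbols. Defaults
#'   to carbon for bare point clouds.
#' @param heavy_mask Logical vector of length N, `TRUE` for non-hydrogen
#'   atoms. Derived from `elements` when omitted.
#' @return An object of class `"conformer"` with fields `coords`, `elements`,
#'   `heavy_mask`.
#' @examples
#' conf <- conformer(matrix(rnorm(12), 4, 3))
#' gram_from_coords(conf)
#' @export
conformer <- function(coords, elements = NULL, heavy_mask = NULL) {
  coords <- as.matrix(coords)
  if (length(coords) == 3L && nrow(coords) == 3L && ncol(coords) == 1L) {
    coords <- t(coords)
  }
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 1L) stop("conformer must contain at least one atom")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  storage.mode(coords) <- "double"
  if (is.null(elements)) elements <- rep("C", n)
  if (length(elements) != n) stop("elements length must match atom count")
  if (is.null(heavy_mask)) heavy_mask <- elements != "H"
  if (length(heavy_mask) != n) stop("heavy_mask length must match atom count")
  structure(list(coords = unname(coords), elements = as.character(elements),
                 heavy_mask = as.logical(heavy_mask)),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer: %d atoms (%d heavy)>\n",
              nrow(x$coords), sum(x$heavy_mask)))
  invisible(x)
}

.check_conformer <- function(conf) {
  if (!inherits(conf, "conformer")) conf <- conformer(conf)
  conf
}

#' Center a conformer at its centroid
#'
#' Translates the coordinates so that the centroid of all atoms (hydrogens
#' included) sits at the origin. A single consistent origin is what makes the
#' Gram matrix and the atom-to-origin distances well defined.
#'
#' @param conf A [conformer()].
#' @return The centered conformer.
#' @export
center_coordinates <- function(conf) {
  conf <- .check_conformer(conf)
  ctr <- colMeans(conf$coords)
  conf$coords <- sweep(conf$coords, 2L, ctr)
  conf
}

.is_centered <- function(coords) {
  all(abs(colMeans(coords)) <= .tol$centering * max(1, max(abs(coords))))
}

#' Gram matrix of a conformer
#'
#' The Gram matrix of an origin-centered coordinate matrix X is
#' G = X X^T, i.e. G_ij = x_i . x_j (Angstrom^2). It is invariant under
#' rotation, reflection and (after centering) translation of the input
#' coordinates, symmetric, positive semidefinite, and of rank at most 3 for
#' exact 3D structures. Input coordinates are re-centered automatically;
#' whether they were already centered is recorded in the `"was_centered"`
#' attribute.
#'
#' @param conf A [conformer()] or an N x 3 coordinate matrix.
#' @return An object of class `"gram_matrix"`: the N x N matrix itself, with
#'   attributes `elements` and `was_centered`.
#' @export
gram_from_coords <- function(conf) {
  conf <- .check_conformer(conf)
  was <- .is_centered(conf$coords)
  conf <- center_coordinates(conf)
  g <- tcrossprod(conf$coords)
  structure(g, class = "gram_matrix", elements = conf$elements,
            was_centered = was)
}

#' Validate or coerce a Gram matrix
#'
#' @param values Symmetric numeric matrix (Angstrom^2).
#' @param elements Optional element symbols carried along.
#' @return A `"gram_matrix"` object.
#' @export
gram_matrix <- function(values, elements = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("Gram matrix must be square")
  if (!all(is.finite(values))) stop("Gram matrix must be finite")
  scale <- max(abs(values), 1e-300)
  if (max(abs(values - t(values))) > .tol$symmetry * scale) {
    stop("matrix is not symmetric within tolerance")
  }
  structure((values + t(values)) / 2, class = "gram_matrix",
            elements = elements)
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat(sprintf("<gram_matrix: %d x %d (Angstrom^2)>\n", nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

#' Pairwise distance matrix of a conformer
#'
#' D_ij = ||x_i - x_j|| (Angstrom). For centered input the atom-to-origin
#' distances ||x_i|| are attached as the `origin_distances` attribute; for
#' uncentered input they refer to the centroid frame as well, since the
#' conformer is centered first.
#'
#' @param conf A [conformer()] or coordinate matrix.
#' @return A `"dist_matrix"` object (N x N matrix) with attribute
#'   `origin_distances`.
#' @export
distance_from_coords <- function(conf) {
  conf <- .check_conformer(conf)
  conf <- center_coordinates(conf)
  d <- as.matrix(stats::dist(conf$coords))
  dimnames(d) <- NULL
  structure(d, class = "dist_matrix",
            origin_distances = sqrt(rowSums(conf$coords^2)))
}

#' Assemble a distance matrix object
#'
#' @param values N x N matrix of pairwise distances (Angstrom).
#' @param origin_distances Optional length-N vector of distances to the
#'   origin (Angstrom); required for conversion back to a Gram matrix.
#' @return A `"dist_matrix"` object.
#' @export
dist_matrix <- function(values, origin_distances = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (any(values < 0)) stop("distances must be non-negative")
  if (max(abs(diag(values))) > 1e-9) stop("distance matrix diagonal must be 0")
  if (!is.null(origin_distances) &&
      length(origin_distances) != nrow(values)) {
    stop("origin_distances length must match matrix dimension")
  }
  structure(values, class = "dist_matrix", origin_distances = origin_distances)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix: %d x %d (Angstrom)%s>\n", nrow(x), ncol(x),
              if (is.null(attr(x, "origin_distances"))) ""
              else ", with origin distances"))
  invisible(x)
}

#' Convert a Gram matrix to a distance matrix
#'
#' Uses D_ij = sqrt(G_ii + G_jj - 2 G_ij). Tiny negative radicands (below
#' `radicand` tolerance times `max(abs(G))`) are clamped to zero; larger ones
#' mean the input is not the Gram matrix of real points and raise an error.
#' Origin distances sqrt(max(G_ii, 0)) are attached.
#'
#' @param g A `"gram_matrix"` or symmetric matrix.
#' @return A `"dist_matrix"` with `origin_distances`.
#' @export
gram_to_distance <- function(g) {
  if (!inherits(g, "gram_matrix")) g <- gram_matrix(g)
  dg <- diag(g)
  sq <- outer(dg, dg, "+") - 2 * unclass(g)
  clamp <- .tol$radicand * max(abs(g), 1e-300)
  if (min(sq) < -clamp) {
    stop("matrix is not a valid Gram matrix of real points (negative squared distance)")
  }
  sq[sq < 0] <- 0
  d <- sqrt(sq)
  diag(d) <- 0
  structure(d, class = "dist_matrix",
            origin_distances = sqrt(pmax(dg, 0)))
}

#' Convert a distance matrix to a Gram matrix
#'
#' Uses G_ij = (D_0i^2 + D_0j^2 - D_ij^2) / 2, which requires the
#' atom-to-origin distances D_0i. This is the step that makes the Gram matrix
#' strictly more informative than the plain distance matrix.
#'
#' @param d A `"dist_matrix"` with non-`NULL` `origin_distances`.
#' @return A `"gram_matrix"`.
#' @export
distance_to_gram <- function(d) {
  if (!inherits(d, "dist_matrix")) d <- dist_matrix(d)
  d0 <- attr(d, "origin_distances")
  if (is.null(d0)) {
    stop("origin_distances are required to convert distances to a Gram matrix")
  }
  g <- (outer(d0^2, d0^2, "+") - unclass(d)^2) / 2
  gram_matrix((g + t(g)) / 2)
}

#' Bond-angle cosine from a Gram matrix
#'
#' cos(angle i-j-k), vertex at j, computed purely from Gram entries:
#' numerator G_ik + G_jj - G_ij - G_jk, denominator the product of the two
#' arm lengths sqrt((G_ii + G_jj - 2G_ij)(G_jj + G_kk - 2G_jk)). The value is
#' invariant to the common centering offset and clamped into [-1, 1].
#'
#' @param g A `"gram_matrix"`.
#' @param i,j,k Distinct atom indices; `j` is the vertex.
#' @return Cosine of the bond angle, in `[-1, 1]`.
#' @export
angle_cosine_from_gram <- function(g, i, j, k) {
  if (!inherits(g, "gram_matrix")) g <- gram_matrix(g)
  if (length(unique(c(i, j, k))) != 3L) stop("i, j, k must be distinct")
  num <- g[i, k] + g[j, j] - g[i, j] - g[j, k]
  a2 <- g[i, i] + g[j, j] - 2 * g[i, j]
  b2 <- g[j, j] + g[k, k] - 2 * g[j, k]
  if (a2 <= 0 || b2 <= 0) {
    stop("degenerate geometry: zero-length bond arm in angle computation")
  }
  max(-1, min(1, num / sqrt(a2 * b2)))
}

#' Eigenvalues of a Gram matrix and its geometric rank
#'
#' @param g A `"gram_matrix"`.
#' @return List with `values` (eigenvalues, descending) and `rank` (number of
#'   eigenvalues above the rank tolerance times the largest eigenvalue).
#' @export
gram_rank <- function(g) {
  if (!inherits(g, "gram_matrix")) g <- gram_matrix(g)
  ev <- eigen((unclass(g) + t(unclass(g))) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  lmax <- max(ev, 0)
  list(values = ev, rank = sum(ev > .tol$rank * max(lmax, 1e-300)))
}

#' Reconstruct coordinates from a Gram matrix (classical MDS)
#'
#' Symmetric eigendecomposition G = Q L Q^T; the three largest eigenvalues
#' and their eigenvectors give the coordinates x_ik = sqrt(l_k) Q_ik
#' (k = 1, 2, 3). For an exact Gram matrix of a 3D structure all remaining
#' eigenvalues vanish and the reconstruction is exact up to a rigid motion
#' and reflection; for a noisy (e.g. predicted) matrix the top-3 truncation
#' is the least-squares rank-3 fit, and negative eigenvalues among the top
#' three are clamped to zero.
#'
#' @param g A `"gram_matrix"` or symmetric matrix.
#' @param elements Optional element symbols for the returned conformer
#'   (defaults to the `elements` attribute of `g`, then to carbon).
#' @return A [conformer()], origin-centered.
#' @export
mds_reconstruct <- function(g, elements = NULL) {
  if (!inherits(g, "gram_matrix")) g <- gram_matrix(g)
  gm <- (unclass(g) + t(unclass(g))) / 2
  n <- nrow(gm)
  es <- eigen(gm, symmetric = TRUE)
  # eigen() already sorts descending for symmetric input
  k <- seq_len(min(3L, n))
  lam <- pmax(es$values[k], 0)
  # eigenvalues that are numerically zero relative to the leading one give
  # pure-roundoff coordinates; zero them so planar/linear inputs stay flat
  lam[lam < .tol$rank * max(lam, 1e-300)] <- 0
  x <- es$vectors[, k, drop = FALSE] %*% diag(sqrt(lam), nrow = length(k))
  if (ncol(x) < 3L) x <- cbind(x, matrix(0, n, 3L - ncol(x)))
  # eigenvectors of a centered Gram matrix are centroid-free only up to
  # roundoff; re-center so downstream origin distances are consistent
  x <- sweep(x, 2L, colMeans(x))
  el <- elements %||% attr(g, "elements") %||% rep("C", n)
  conformer(x, elements = el)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add symmetric Gaussian noise to a Gram matrix
#'
#' Adds zero-mean i.i.d. Gaussian noise with standard deviation `sigma` to
#' each unordered pair (the perturbation is symmetrized so the result remains
#' a valid symmetric matrix). Used to study how tolerant MDS reconstruction
#' is to noise in the Gram matrix.
#'
#' @param g A `"gram_matrix"`.
#' @param sigma Standard deviation of the noise (Angstrom^2), `>= 0`.
#' @param seed Optional integer seed; with a fixed seed the output is
#'   deterministic.
#' @return A `"gram_matrix"`.
#' @export
add_gram_noise <- function(g, sigma, seed = NULL) {
  if (!inherits(g, "gram_matrix")) g <- gram_matrix(g)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    stop("sigma must be a single non-negative number")
  }
  if (sigma == 0) return(g)
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  n <- nrow(g)
  noise <- matrix(stats::rnorm(n * n, 0, sigma), n, n)
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  out <- unclass(g) + noise
  structure(out, class = "gram_matrix", elements = attr(g, "elements"))
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
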