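# Supervision targets from conformers and the four variant losses.
# Variant-to-term mapping:
#   a: distance matrix           b: distance matrix + origin distances
#   c: Gram matrix               d: Gram matrix + bond lengths + bond angles

#' Build supervision targets from a conformer and its molecular graph
#'
#' Centers the conformer, computes the Gram and distance matrices (with
#' origin distances), collects every bond with its true length, and every
#' canonical angle triple (i, j, k) with bonds (i, j) and (j, k) sharing
#' vertex j and i < k, with its true angle in radians.
#'
#' @param conf A [conformer()]; defaults to the conformer attached to
#'   `graph`.
#' @param graph A [molecular_graph()] with matching atom count.
#' @return A `"supervision_targets"` list: `G`, `D` (with origin distances),
#'   `bonds` (data frame `u`, `v`, `length`), `angles` (data frame `i`, `j`,
#'   `k`, `angle`).
#' @export
build_targets <- function(graph, conf = graph$conformer) {
  if (is.null(conf)) stop("molecule has no conformer to build targets from")
  if (nrow(conf$coords) != n_atoms(graph)) {
    stop("conformer and graph atom counts differ")
  }
  conf <- center_coordinates(conf)
  G <- gram_from_coords(conf)
  D <- distance_from_coords(conf)
  bonds <- graph$bonds[, c("u", "v")]
  bonds$length <- if (nrow(bonds)) unclass(D)[cbind(bonds$u, bonds$v)] else numeric(0)
  adj <- .adjacency_list(graph)
  tri <- list()
  for (j in seq_len(n_atoms(graph))) {
    nbr <- adj[[j]][, 1]
    if (length(nbr) < 2L) next
    cmb <- utils::combn(sort(nbr), 2L)
    for (cc in seq_len(ncol(cmb))) {
      tri[[length(tri) + 1L]] <- c(cmb[1, cc], j, cmb[2, cc])
    }
  }
  angles <- if (length(tri)) {
    m <- do.call(rbind, tri)
    ang <- vapply(seq_len(nrow(m)), function(r) {
      acos(angle_cosine_from_gram(G, m[r, 1], m[r, 2], m[r, 3]))
    }, numeric(1))
    data.frame(i = m[, 1], j = m[, 2], k = m[, 3], angle = ang)
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    angle = numeric())
  structure(list(G = G, D = D, bonds = bonds, angles = angles),
            class = "supervision_targets")
}

#' @export
print.supervision_targets <- function(x, ...) {
  cat(sprintf("<supervision_targets: N=%d, |bonds|=%d, |angles|=%d>\n",
              nrow(x$G), nrow(x$bonds), nrow(x$angles)))
  invisible(x)
}

.variant_terms <- list(
  a = "distance",
  b = c("distance", "origin_distance"),
  c = "gram",
  d = c("gram", "bond_length", "bond_angle")
)

#' Variant loss on explicit predictions
#'
#' Pure computation of the supervised loss for one molecule, given numeric
#' predictions and targets. Per-term normalizers are per-molecule means:
#' 1/N^2 over all ordered pairs (diagonal included) for the distance and
#' Gram terms, 1/N over atoms for origin distances, 1/|bonds| and 1/|angles|
#' for the auxiliary terms. Inactive terms are absent from the breakdown,
#' not zero.
#'
#' @param predictions List with the heads the variant requires: `Dhat`
#'   (N x N), `d0hat` (length N), `Ghat` (N x N), `lengths` (per bond),
#'   `angles` (radians, per angle triple).
#' @param targets A [build_targets()] result.
#' @param variant One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param loss_weights Optional named weights (default 1 each).
#' @param angle_squared Use squared angle error (default `TRUE`); `FALSE`
#'   gives the literal linear form of the printed angle term.
#' @return A `"loss_breakdown"` list: `total`, `terms` (named list of active
#'   term values), `normalizers`.
#' @export
loss_variant <- function(predictions, targets, variant = "d",
                         loss_weights = NULL, angle_squared = TRUE) {
  variant <- match.arg(variant, c("a", "b", "c", "d"))
  w <- .full_weights(loss_weights)
  n <- nrow(targets$G)
  need <- .variant_terms[[variant]]
  terms <- list(); norms <- list()
  req <- function(field, term) {
    if (is.null(predictions[[field]])) {
      stop(sprintf("variant '%s' requires prediction '%s'", variant, field))
    }
    predictions[[field]]
  }
  if ("distance" %in% need) {
    Dhat <- req("Dhat")
    terms$distance <- w$distance * mean((unclass(targets$D) - Dhat)^2)
    norms$distance <- n^2
  }
  if ("origin_distance" %in% need) {
    d0hat <- req("d0hat")
    d0 <- attr(targets$D, "origin_distances")
    terms$origin_distance <- w$origin * mean((d0 - d0hat)^2)
    norms$origin_distance <- n
  }
  if ("gram" %in% need) {
    Ghat <- req("Ghat")
    terms$gram <- w$gram * mean((unclass(targets$G) - unclass(Ghat))^2)
    norms$gram <- n^2
  }
  if ("bond_length" %in% need && nrow(targets$bonds) > 0L) {
    lhat <- req("lengths")
    terms$bond_length <- w$length * mean((targets$bonds$length - lhat)^2)
    norms$bond_length <- nrow(targets$bonds)
  }
  if ("bond_angle" %in% need && nrow(targets$angles) > 0L) {
    ahat <- req("angles")
    terms$bond_angle <- if (angle_squared) {
      w$angle * mean((targets$angles$angle - ahat)^2)
    } else {
      w$angle * mean(targets$angles$angle - ahat)
    }
    norms$bond_angle <- nrow(targets$angles)
  }
  structure(list(total = sum(unlist(terms)), terms = terms,
                 normalizers = norms, variant = variant),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss_breakdown variant %s: total = %.6g>\n", x$variant,
              x$total))
  for (nm in names(x$terms)) cat(sprintf("  %-16s %.6g\n", nm, x$terms[[nm]]))
  invisible(x)
}
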