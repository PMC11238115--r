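# Molecular graph container, sanitization, featurization and topology tables.

.hybridizations <- c("sp", "sp2", "sp3", "sp3d", "sp3d2")
.bond_orders <- c("1", "2", "3", "ar")

#' Construct a molecular graph
#'
#' Topology plus per-atom chemistry, the input object of the encoder. Bonds
#' are stored once with `u < v` (undirected graph). A conformer may be
#' attached when 3D coordinates are known.
#'
#' @param elements Character vector of element symbols (explicit hydrogens
#'   included as `"H"` atoms).
#' @param bonds Data frame with integer columns `u`, `v` and character column
#'   `order` (one of `"1"`, `"2"`, `"3"`, `"ar"`).
#' @param conformer Optional [conformer()] with matching atom count.
#' @param id Molecule identifier string.
#' @param formal_charge,radical_electrons Optional integer vectors per atom
#'   (default 0).
#' @param chirality Optional character vector per atom, `"unspecified"` or
#'   `"specified"`.
#' @param implicit_h Optional integer vector of implicit hydrogen counts per
#'   atom (default 0: explicit-hydrogen graphs carry no implicit H).
#' @return An object of class `"molecular_graph"`.
#' @export
molecular_graph <- function(elements, bonds, conformer = NULL, id = "mol",
                            formal_charge = NULL, radical_electrons = NULL,
                            chirality = NULL, implicit_h = NULL) {
  n <- length(elements)
  if (n < 1L) stop("molecule must contain at least one atom")
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(u = integer(), v = integer(), order = character())
  }
  bonds$u <- as.integer(bonds$u); bonds$v <- as.integer(bonds$v)
  swap <- bonds$u > bonds$v
  tmp <- bonds$u[swap]; bonds$u[swap] <- bonds$v[swap]; bonds$v[swap] <- tmp
  if (any(bonds$u == bonds$v)) stop("self-bonds are not allowed")
  if (nrow(bonds) > 0L &&
      (min(bonds$u) < 1L || max(bonds$v) > n)) {
    stop("bond endpoints must be valid atom indices")
  }
  if (anyDuplicated(bonds[c("u", "v")])) stop("duplicate bonds")
  if (!all(bonds$order %in% .bond_orders)) stop("unknown bond order")
  if (!is.null(conformer)) {
    if (nrow(conformer$coords) != n) {
      stop("conformer atom count does not match graph")
    }
  }
  structure(list(
    elements = as.character(elements),
    bonds = bonds[order(bonds$u, bonds$v), , drop = FALSE],
    conformer = conformer,
    id = as.character(id),
    formal_charge = as.integer(formal_charge %||% rep(0L, n)),
    radical_electrons = as.integer(radical_electrons %||% rep(0L, n)),
    chirality = as.character(chirality %||% rep("unspecified", n)),
    implicit_h = as.integer(implicit_h %||% rep(0L, n))
  ), class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph '%s': %d atoms, %d bonds%s>\n", x$id,
              length(x$elements), nrow(x$bonds),
              if (is.null(x$conformer)) "" else ", 3D"))
  invisible(x)
}

n_atoms <- function(graph) length(graph$elements)

.adjacency_list <- function(graph) {
  n <- n_atoms(graph)
  adj <- vector("list", n)
  for (b in seq_len(nrow(graph$bonds))) {
    u <- graph$bonds$u[b]; v <- graph$bonds$v[b]
    adj[[u]] <- rbind(adj[[u]], c(v, b))
    adj[[v]] <- rbind(adj[[v]], c(u, b))
  }
  lapply(adj, function(a) {
    if (is.null(a)) matrix(integer(), 0, 2) else a[order(a[, 1]), , drop = FALSE]
  })
}

.degrees <- function(graph) {
  n <- n_atoms(graph)
  tabulate(c(graph$bonds$u, graph$bonds$v), nbins = n)
}

# A bond is in a ring iff it is not a bridge (removing it keeps its endpoints
# connected). Molecules are small, so a BFS per bond is fine.
.ring_bonds <- function(graph) {
  nb <- nrow(graph$bonds)
  if (nb == 0L) return(logical(0))
  adj <- .adjacency_list(graph)
  vapply(seq_len(nb), function(b) {
    u <- graph$bonds$u[b]; v <- graph$bonds$v[b]
    seen <- rep(FALSE, n_atoms(graph)); seen[u] <- TRUE
    queue <- u
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nbrs <- adj[[cur]]
      for (r in seq_len(nrow(nbrs))) {
        if (nbrs[r, 2] == b) next
        w <- nbrs[r, 1]
        if (!seen[w]) {
          if (w == v) return(TRUE)
          seen[w] <- TRUE; queue <- c(queue, w)
        }
      }
    }
    FALSE
  }, logical(1))
}

.pi_atoms <- function(graph) {
  n <- n_atoms(graph)
  pi <- rep(FALSE, n)
  mult <- graph$bonds$order %in% c("2", "3", "ar")
  pi[unique(c(graph$bonds$u[mult], graph$bonds$v[mult]))] <- TRUE
  pi
}

.aromatic_atoms <- function(graph) {
  n <- n_atoms(graph)
  ar <- rep(FALSE, n)
  arb <- graph$bonds$order == "ar"
  ar[unique(c(graph$bonds$u[arb], graph$bonds$v[arb]))] <- TRUE
  ar
}

# Hybridization heuristic from incident bond orders: a triple bond or two
# double bonds -> sp; any double/aromatic bond -> sp2; otherwise sp3 for
# heavy atoms. Hydrogen has no hybridization (all-zero one-hot block).
.hybridization <- function(graph) {
  n <- n_atoms(graph)
  out <- character(n)
  for (a in seq_len(n)) {
    if (graph$elements[a] == "H") { out[a] <- "none"; next }
    inc <- graph$bonds$order[graph$bonds$u == a | graph$bonds$v == a]
    if (any(inc == "3") || sum(inc == "2") >= 2L) out[a] <- "sp"
    else if (any(inc %in% c("2", "ar"))) out[a] <- "sp2"
    else out[a] <- "sp3"
  }
  out
}

# Conjugation heuristic: aromatic bonds are conjugated; a single bond is
# conjugated when both endpoints carry a multiple/aromatic bond; a multiple
# bond is conjugated when some third atom adjacent to either endpoint is a
# pi atom (e.g. the double bonds of butadiene, but not an isolated C=O).
.conjugated_bonds <- function(graph) {
  nb <- nrow(graph$bonds)
  if (nb == 0L) return(logical(0))
  pi <- .pi_atoms(graph)
  adj <- .adjacency_list(graph)
  vapply(seq_len(nb), function(b) {
    u <- graph$bonds$u[b]; v <- graph$bonds$v[b]
    ord <- graph$bonds$order[b]
    if (ord == "ar") return(TRUE)
    if (ord == "1") return(pi[u] && pi[v])
    others <- setdiff(c(adj[[u]][, 1], adj[[v]][, 1]), c(u, v))
    any(pi[others])
  }, logical(1))
}

#' Explicit valence (sum of bond orders) per atom
#' @param graph A [molecular_graph()].
#' @return Numeric vector; aromatic bonds count 1.5.
#' @export
explicit_valence <- function(graph) {
  n <- n_atoms(graph)
  w <- c("1" = 1, "2" = 2, "3" = 3, "ar" = 1.5)[graph$bonds$order]
  out <- numeric(n)
  for (b in seq_len(nrow(graph$bonds))) {
    out[graph$bonds$u[b]] <- out[graph$bonds$u[b]] + w[b]
    out[graph$bonds$v[b]] <- out[graph$bonds$v[b]] + w[b]
  }
  out
}

#' Sanitize a molecular graph
#'
#' Checks element symbols, connectivity bookkeeping and valence limits
#' (explicit valence plus implicit hydrogens must not exceed the default
#' valence for H/C/N/O/F, adjusted by formal charge). Returns the graph
#' invisibly on success and throws on failure.
#'
#' @param graph A [molecular_graph()].
#' @return The graph, invisibly.
#' @export
sanitize_graph <- function(graph) {
  if (!all(graph$elements %in% names(.atomic_number))) {
    bad <- setdiff(unique(graph$elements), names(.atomic_number))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  ev <- explicit_valence(graph) + graph$implicit_h
  lim <- .default_valence[graph$elements]
  known <- !is.na(lim)
  lim <- lim + graph$formal_charge * ifelse(graph$elements %in% c("N", "C"), 1, -1)
  over <- known & (ev > lim + 0.5 + 1e-9)  # 0.5 slack for Kekule/aromatic
  if (any(over)) {
    stop(sprintf("valence violation at atom(s) %s of '%s'",
                 paste(which(over), collapse = ", "), graph$id))
  }
  invisible(graph)
}

#' Featurize a molecular graph
#'
#' Encodes each atom as a 17-dimensional vector and each bond as a
#' 7-dimensional vector in a fixed documented column order.
#'
#' Atom columns: atomic number (1); hybridization one-hot over
#' sp/sp2/sp3/sp3d/sp3d2 (5; out-of-vocabulary, e.g. hydrogen, is an
#' all-zero block); formal charge (1); radical electrons (1); van der Waals
#' radius in Angstrom (1); aromatic flag (1); implicit hydrogens (1);
#' explicit hydrogens (1); explicit valence (1); implicit valence (1);
#' degree (1); chirality one-hot unspecified/specified (2).
#'
#' Bond columns: conjugated (1); aromatic (1); in-ring (1); bond type
#' one-hot single/double/triple/aromatic (4).
#'
#' @param graph A sanitized [molecular_graph()].
#' @return List with `atoms` (N x 17 matrix) and `bonds` (|E| x 7 matrix),
#'   both with informative column names.
#' @export
featurize <- function(graph) {
  n <- n_atoms(graph)
  hyb <- .hybridization(graph)
  hyb_oh <- t(vapply(hyb, function(h) as.numeric(.hybridizations == h),
                     numeric(5)))
  arom <- .aromatic_atoms(graph)
  deg <- .degrees(graph)
  expl_h <- vapply(seq_len(n), function(a) {
    nbr <- c(graph$bonds$v[graph$bonds$u == a], graph$bonds$u[graph$bonds$v == a])
    sum(graph$elements[nbr] == "H")
  }, numeric(1))
  chir_oh <- cbind(as.numeric(graph$chirality == "unspecified"),
                   as.numeric(graph$chirality == "specified"))
  atoms <- cbind(
    atom_number = .atomic_number[graph$elements],
    hyb_oh,
    formal_charge = graph$formal_charge,
    radical_electrons = graph$radical_electrons,
    vdw_radius = .vdw_radius[graph$elements],
    aromatic = as.numeric(arom),
    implicit_h = graph$implicit_h,
    explicit_h = expl_h,
    explicit_valence = explicit_valence(graph),
    implicit_valence = graph$implicit_h,
    degree = deg,
    chir_oh
  )
  colnames(atoms) <- c("atom_number", paste0("hyb_", .hybridizations),
                       "formal_charge", "radical_electrons", "vdw_radius",
                       "aromatic", "implicit_h", "explicit_h",
                       "explicit_valence", "implicit_valence", "degree",
                       "chir_unspecified", "chir_specified")
  rownames(atoms) <- NULL
  nb <- nrow(graph$bonds)
  type_oh <- matrix(0, nb, 4,
                    dimnames = list(NULL, c("single", "double", "triple",
                                            "aromatic_type")))
  if (nb > 0L) {
    type_oh[cbind(seq_len(nb), match(graph$bonds$order, .bond_orders))] <- 1
  }
  bonds <- cbind(
    conjugated = as.numeric(.conjugated_bonds(graph)),
    aromatic = as.numeric(graph$bonds$order == "ar"),
    in_ring = as.numeric(.ring_bonds(graph)),
    type_oh
  )
  rownames(bonds) <- NULL
  list(atoms = unname(atoms) * 1.0, bonds = unname(bonds) * 1.0,
       atom_names = colnames(atoms), bond_names = colnames(bonds))
}

#' Shortest-path topology tables
#'
#' Breadth-first unweighted shortest hop counts between all atom pairs, one
#' deterministic shortest path's edge-index sequence per pair (ties broken by
#' always expanding the lexicographically smallest neighbor first), and atom
#' degrees. Disconnected pairs carry the sentinel hop value `-1` and an empty
#' path.
#'
#' @param graph A [molecular_graph()].
#' @return List with `shortest_hops` (N x N integer matrix), `path_edges`
#'   (list of lists of integer edge-index vectors), `degrees`.
#' @export
topology_tables <- function(graph) {
  n <- n_atoms(graph)
  adj <- .adjacency_list(graph)
  hops <- matrix(-1L, n, n)
  diag(hops) <- 0L
  path_edges <- vector("list", n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L
    par_edge <- rep(NA_integer_, n); par_node <- rep(NA_integer_, n)
    queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nbrs <- adj[[cur]]           # already sorted by neighbor index
      for (r in seq_len(nrow(nbrs))) {
        w <- nbrs[r, 1]
        if (dist[w] < 0L) {
          dist[w] <- dist[cur] + 1L
          par_edge[w] <- nbrs[r, 2]; par_node[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
    hops[s, ] <- dist
    paths <- vector("list", n)
    for (t in seq_len(n)) {
      if (dist[t] <= 0L) { paths[[t]] <- integer(0); next }
      seq_e <- integer(dist[t]); cur <- t
      for (step in seq(dist[t], 1L)) {
        seq_e[step] <- par_edge[cur]; cur <- par_node[cur]
      }
      paths[[t]] <- seq_e
    }
    path_edges[[s]] <- paths
  }
  list(shortest_hops = hops, path_edges = path_edges,
       degrees = .degrees(graph))
}
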