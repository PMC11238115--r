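# Dataset partitioning: seeded random splits, Bemis-Murcko scaffold splits,
# and pretraining-set deduplication against downstream sets.

.check_ratios <- function(ratios) {
  if (length(ratios) != 3L || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-6) {
    stop("ratios must be three positive numbers summing to 1")
  }
  ratios
}

#' Random train/validation/test split
#'
#' Deterministic under `seed`; split sizes are `floor(ratio * N)` with the
#' remainder assigned to training (so an 8:1:1 split of 1000 molecules gives
#' 800/100/100).
#'
#' @param graphs List of molecules (only its length is used) or an integer N.
#' @param ratios Numeric length-3 vector (train, validation, test).
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
random_split <- function(graphs, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  .check_ratios(ratios)
  n <- if (is.numeric(graphs) && length(graphs) == 1L) as.integer(graphs)
       else length(graphs)
  if (n < 3L) stop("need at least as many molecules as splits")
  old <- .save_rng_state(); on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  n_val <- floor(ratios[2] * n); n_test <- floor(ratios[3] * n)
  n_train <- n - n_val - n_test
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' Bemis-Murcko scaffold of a molecule
#'
#' The ring-and-linker framework: hydrogens and all terminal (acyclic
#' side-chain) atoms are pruned iteratively until only ring systems and the
#' linkers between them remain. Acyclic molecules have an empty scaffold,
#' returned as `""`. The scaffold is canonicalized to a SMILES string via
#' Open Babel so it can serve as a grouping key.
#'
#' @param graph A [molecular_graph()] or SMILES string.
#' @return Canonical scaffold SMILES (possibly `""`).
#' @export
murcko_scaffold <- function(graph) {
  if (is.character(graph)) graph <- parse_smiles(graph)
  keep <- graph$elements != "H"
  bonds <- graph$bonds
  repeat {
    idx <- which(keep)
    deg <- integer(length(graph$elements))
    sel <- bonds$u %in% idx & bonds$v %in% idx
    for (b in which(sel)) {
      deg[bonds$u[b]] <- deg[bonds$u[b]] + 1L
      deg[bonds$v[b]] <- deg[bonds$v[b]] + 1L
    }
    drop <- keep & deg <= 1L
    # keep single-atom molecules out: terminal atoms leave until none remain
    if (!any(drop[idx])) break
    keep[drop] <- FALSE
    if (!any(keep)) break
  }
  idx <- which(keep)
  if (!length(idx)) return("")
  remap <- match(seq_along(graph$elements), idx)
  sel <- bonds$u %in% idx & bonds$v %in% idx
  sub <- molecular_graph(
    graph$elements[idx],
    data.frame(u = remap[bonds$u[sel]], v = remap[bonds$v[sel]],
               order = bonds$order[sel]),
    id = paste0(graph$id, "_scaffold"),
    formal_charge = graph$formal_charge[idx]
  )
  canonical_smiles(sub)
}

#' Scaffold-based train/validation/test split
#'
#' Molecules are grouped by Bemis-Murcko scaffold; groups are sorted by size
#' (descending) then scaffold string (ascending) and assigned greedily to the
#' first split not yet at its capacity, training first, so a scaffold group
#' never straddles two splits.
#'
#' @param graphs List of [molecular_graph()] (or SMILES strings).
#' @param ratios Numeric length-3 vector (train, validation, test).
#' @return List with `train`, `val`, `test` index vectors and the
#'   `scaffolds` character vector used.
#' @export
scaffold_split <- function(graphs, ratios = c(0.8, 0.1, 0.1)) {
  .check_ratios(ratios)
  scaf <- vapply(graphs, murcko_scaffold, character(1))
  groups <- split(seq_along(graphs), scaf)
  ord <- order(-lengths(groups), names(groups))
  groups <- groups[ord]
  n <- length(graphs)
  cap <- c(train = ratios[1] * n, val = ratios[2] * n, test = ratios[3] * n)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (g in groups) {
    placed <- FALSE
    # first split still below its capacity takes the whole group
    for (s in c("train", "val", "test")) {
      if (length(out[[s]]) < cap[[s]] - 1e-9) {
        out[[s]] <- c(out[[s]], g); placed <- TRUE; break
      }
    }
    if (!placed) out$train <- c(out$train, g)
  }
  list(train = sort(out$train), val = sort(out$val), test = sort(out$test),
       scaffolds = scaf)
}

#' Remove pretraining molecules duplicated in a downstream set
#'
#' Identity is canonical SMILES (stereochemistry retained where present).
#'
#' @param pretrain_set,downstream_set Lists of [molecular_graph()] (or SMILES
#'   strings).
#' @return Filtered pretraining list; attribute `removed` counts removals.
#' @export
deduplicate_against <- function(pretrain_set, downstream_set) {
  can_pre <- vapply(pretrain_set, canonical_smiles, character(1))
  can_down <- unique(vapply(downstream_set, canonical_smiles, character(1)))
  keep <- !(can_pre %in% can_down)
  out <- pretrain_set[keep]
  attr(out, "removed") <- sum(!keep)
  message(sprintf("deduplicate_against: removed %d of %d molecules",
                  sum(!keep), length(pretrain_set)))
  out
}
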