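# Reading and writing molecules: SDF (via ChemmineR), XYZ, SMILES (via
# Open Babel through ChemmineOB, with a CLI fallback), plus aromatic-ring
# perception for Kekule-form inputs.

.require_chemmine <- function() {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("ChemmineR is required for SDF parsing")
  }
}

.ob_convert <- function(from, to, source) {
  if (requireNamespace("ChemmineOB", quietly = TRUE)) {
    return(ChemmineOB::convertFormat(from, to, source = source))
  }
  inf <- tempfile(fileext = paste0(".", tolower(from)))
  ouf <- tempfile(fileext = paste0(".", tolower(to)))
  writeLines(source, inf)
  status <- system2("obabel", c(inf, "-O", ouf), stdout = FALSE, stderr = FALSE)
  on.exit(unlink(c(inf, ouf)))
  if (status != 0L || !file.exists(ouf)) stop("Open Babel conversion failed")
  paste(readLines(ouf), collapse = "\n")
}

# Mark six-membered rings with alternating single/double carbon (or ring N)
# bonds as aromatic, so Kekule-form inputs featurize like aromatic ones.
.perceive_aromatic <- function(graph) {
  nb <- nrow(graph$bonds)
  if (nb == 0L) return(graph)
  ring <- .ring_bonds(graph)
  if (!any(ring)) return(graph)
  adj <- .adjacency_list(graph)
  n <- n_atoms(graph)
  # enumerate 6-cycles by DFS from each atom (small molecules only)
  seen_cycles <- list()
  paths <- function(start) {
    out <- list()
    walk <- function(path, edges) {
      cur <- path[length(path)]
      nbrs <- adj[[cur]]
      for (r in seq_len(nrow(nbrs))) {
        w <- nbrs[r, 1]; e <- nbrs[r, 2]
        if (length(path) == 6L && w == start) {
          out[[length(out) + 1L]] <<- list(atoms = path, edges = c(edges, e))
        } else if (length(path) < 6L && !(w %in% path) && w > start) {
          walk(c(path, w), c(edges, e))
        }
      }
    }
    walk(start, integer(0))
    out
  }
  make_ar <- integer(0)
  for (s in seq_len(n)) {
    for (cyc in paths(s)) {
      ords <- graph$bonds$order[cyc$edges]
      els <- graph$elements[cyc$atoms]
      ok_el <- all(els %in% c("C", "N"))
      alternating <- sum(ords == "2") == 3L && sum(ords == "1") == 3L &&
        all(abs(diff(c(ords, ords[1]) == "2")) == 1)
      if (ok_el && (alternating || all(ords == "ar"))) {
        make_ar <- c(make_ar, cyc$edges)
      }
    }
  }
  if (length(make_ar)) graph$bonds$order[unique(make_ar)] <- "ar"
  graph
}

.sdf_order_to_code <- c("1" = "1", "2" = "2", "3" = "3", "ar" = "4")
.sdf_code_to_order <- c("1" = "1", "2" = "2", "3" = "3", "4" = "ar")

#' Read molecules from an SDF file
#'
#' Parses a V2000 SDF through ChemmineR; records that fail sanitization
#' (unknown elements, valence violations) are skipped with a warning and
#' counted in the `skipped` attribute. 3D coordinates are attached as a
#' conformer when the atom block carries a non-flat coordinate set (any
#' nonzero z), or always when `keep_2d = TRUE`.
#'
#' @param path Path to an SDF file.
#' @param keep_2d Attach coordinates even for records flagged as 2D layouts
#'   in the counts-line dimension field.
#' @return List of [molecular_graph()]; attribute `skipped` gives the number
#'   of records dropped.
#' @export
read_sdf <- function(path, keep_2d = FALSE) {
  .require_chemmine()
  if (!file.exists(path)) stop("cannot read SDF file: ", path)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  ok <- ChemmineR::validSDF(sdfs)
  raw_sets <- methods::as(sdfs, "SDFstr")
  out <- list(); skipped <- 0L
  for (m in seq_along(sdfs@SDF)) {
    if (!ok[m]) { skipped <- skipped + 1L; next }
    g <- tryCatch({
      sdf <- sdfs@SDF[[m]]
      ab <- ChemmineR::atomblock(sdf)
      bb <- ChemmineR::bondblock(sdf)
      elements <- gsub("_.*$", "", rownames(ab))
      coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
      bonds <- if (is.null(bb) || nrow(bb) == 0L) NULL else data.frame(
        u = as.integer(bb[, 1]), v = as.integer(bb[, 2]),
        order = unname(.sdf_code_to_order[as.character(as.integer(bb[, 3]))])
      )
      # formal charges from M CHG lines of the raw record
      n <- length(elements)
      charge <- rep(0L, n)
      raw <- raw_sets@a[[m]]
      for (line in grep("^M  CHG", raw, value = TRUE)) {
        toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", line)),
                                    "\\s+")[[1]])
        k <- toks[1]
        for (p in seq_len(k)) {
          charge[toks[2 * p]] <- toks[2 * p + 1]
        }
      }
      id <- trimws(raw[1])
      if (!nzchar(id)) id <- sprintf("mol_%d", m)
      gg <- molecular_graph(elements, bonds, id = id, formal_charge = charge)
      gg <- .perceive_aromatic(gg)
      # the program/dimension header line marks 2D layouts (e.g. SMILES
      # depictions); their fake coordinates are dropped unless keep_2d
      is2d <- length(raw) >= 2L && grepl("2D", raw[2], fixed = TRUE) &&
        all(abs(coords[, 3]) < 1e-8)
      has3d <- !is2d || keep_2d
      if (has3d) gg$conformer <- conformer(coords, elements = elements)
      sanitize_graph(gg)
      gg
    }, error = function(e) {
      warning(sprintf("skipping SDF record %d: %s", m, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(g)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- g
  }
  if (!length(out)) stop("no parsable records in ", path)
  attr(out, "skipped") <- skipped
  out
}

#' Write molecules to an SDF file (V2000)
#'
#' Emits one V2000 record per graph: coordinates from the attached conformer
#' (zeros when absent), bond orders with aromatic bonds as type 4, formal
#' charges as `M CHG` lines.
#'
#' @param graphs List of [molecular_graph()] (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(graphs, path) {
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  con <- file(path, "w"); on.exit(close(con))
  for (g in graphs) {
    n <- n_atoms(g); nb <- nrow(g$bonds)
    coords <- if (is.null(g$conformer)) matrix(0, n, 3) else g$conformer$coords
    writeLines(c(g$id, "  gramconf          3D", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    for (a in seq_len(n)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         coords[a, 1], coords[a, 2], coords[a, 3],
                         g$elements[a]), con)
    }
    for (b in seq_len(nb)) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", g$bonds$u[b], g$bonds$v[b],
                         as.integer(.sdf_order_to_code[g$bonds$order[b]])), con)
    }
    chg <- which(g$formal_charge != 0L)
    for (a in chg) {
      writeLines(sprintf("M  CHG  1 %3d %3d", a, g$formal_charge[a]), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read an XYZ file
#'
#' Parses standard multi-block XYZ (atom count line, comment line, then one
#' `element x y z` line per atom). Bonds are inferred from covalent radii
#' only when `bond_inference = TRUE`: atoms closer than
#' `scale * (r_cov_i + r_cov_j)` are bonded (single bonds).
#'
#' @param path Path to an XYZ file.
#' @param bond_inference Infer single bonds from covalent radii.
#' @param scale Covalent-radius scale factor for bond inference.
#' @return List of [molecular_graph()] with conformers attached.
#' @export
read_xyz <- function(path, bond_inference = FALSE, scale = 1.2) {
  if (!file.exists(path)) stop("cannot read XYZ file: ", path)
  lines <- readLines(path)
  out <- list(); i <- 1L; m <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed XYZ atom-count line ", i)
    if (i + 1L + n > length(lines)) stop("truncated XYZ block at line ", i)
    comment <- trimws(lines[i + 1L])
    elements <- character(n); coords <- matrix(NA_real_, n, 3)
    for (a in seq_len(n)) {
      toks <- strsplit(trimws(lines[i + 1L + a]), "\\s+")[[1]]
      if (length(toks) < 4L) {
        stop("malformed XYZ atom line ", i + 1L + a)
      }
      elements[a] <- toks[1]
      xyz <- suppressWarnings(as.numeric(toks[2:4]))
      if (any(is.na(xyz))) stop("malformed XYZ atom line ", i + 1L + a)
      coords[a, ] <- xyz
    }
    m <- m + 1L
    bonds <- NULL
    if (bond_inference) {
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      d <- sqrt(rowSums((coords[pairs[, 1], , drop = FALSE] -
                           coords[pairs[, 2], , drop = FALSE])^2))
      lim <- scale * (.cov_radius[elements[pairs[, 1]]] +
                        .cov_radius[elements[pairs[, 2]]])
      keep <- which(d <= lim)
      if (length(keep)) {
        bonds <- data.frame(u = pairs[keep, 1], v = pairs[keep, 2],
                            order = "1")
      }
    }
    id <- if (nzchar(comment)) comment else sprintf("xyz_%d", m)
    g <- molecular_graph(elements, bonds, id = id)
    g$conformer <- conformer(coords, elements = elements)
    out[[m]] <- g
    i <- i + 2L + n
  }
  if (!length(out)) stop("no XYZ blocks found in ", path)
  out
}

#' Write an XYZ file
#' @param graphs List of [molecular_graph()] with conformers (or conformers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(graphs, path) {
  if (inherits(graphs, "molecular_graph") || inherits(graphs, "conformer")) {
    graphs <- list(graphs)
  }
  con <- file(path, "w"); on.exit(close(con))
  for (g in graphs) {
    conf <- if (inherits(g, "conformer")) g else g$conformer
    if (is.null(conf)) stop("molecule has no conformer to write")
    id <- if (inherits(g, "conformer")) "conformer" else g$id
    writeLines(as.character(nrow(conf$coords)), con)
    writeLines(id, con)
    for (a in seq_len(nrow(conf$coords))) {
      writeLines(sprintf("%-3s %12.6f %12.6f %12.6f", conf$elements[a],
                         conf$coords[a, 1], conf$coords[a, 2],
                         conf$coords[a, 3]), con)
    }
  }
  invisible(path)
}

.check_smiles_syntax <- function(smiles) {
  if (!nzchar(smiles)) stop("empty SMILES")
  chars <- strsplit(smiles, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0) {
    pos <- if (any(depth < 0)) which(depth < 0)[1] else length(chars)
    stop("unparsable SMILES '", smiles,
         "': unbalanced parentheses at position ", pos)
  }
  if (sum(chars == "[") != sum(chars == "]")) {
    stop("unparsable SMILES '", smiles, "': unbalanced brackets")
  }
  invisible(TRUE)
}

#' Parse a SMILES string
#'
#' Converts through Open Babel to obtain topology; no conformer is attached
#' (downstream geometry, if needed, comes from files or fixtures). Implicit
#' hydrogen counts are derived from default valences; with
#' `explicit_h = TRUE` they are materialized as explicit hydrogen atoms
#' instead.
#'
#' @param smiles A SMILES string.
#' @param explicit_h Add hydrogens as explicit atoms.
#' @param id Molecule identifier.
#' @return A [molecular_graph()] without a conformer.
#' @export
parse_smiles <- function(smiles, explicit_h = FALSE, id = smiles) {
  .check_smiles_syntax(smiles)
  sdf <- tryCatch(.ob_convert("SMI", "SDF", paste0(smiles, "\n")),
                  error = function(e) stop("unparsable SMILES '", smiles, "'"))
  tmp <- tempfile(fileext = ".sdf")
  writeLines(sdf, tmp); on.exit(unlink(tmp))
  g <- read_sdf(tmp, keep_2d = TRUE)[[1]]
  g$conformer <- NULL
  g$id <- id
  # implicit hydrogens from default valences (H/C/N/O/F palette)
  ev <- explicit_valence(g)
  lim <- .default_valence[g$elements]
  imp <- ifelse(is.na(lim), 0, pmax(0, round(lim + g$formal_charge *
    ifelse(g$elements %in% c("N", "C"), 1, -1) - ev)))
  g$implicit_h <- as.integer(imp)
  if (explicit_h) {
    withh <- .add_hydrogens_implicit(g)
    g <- withh
  }
  g
}

.add_hydrogens_implicit <- function(g) {
  elements <- g$elements; bonds <- g$bonds
  fc <- g$formal_charge; rad <- g$radical_electrons; chir <- g$chirality
  for (a in seq_along(g$elements)) {
    for (h in seq_len(g$implicit_h[a])) {
      elements <- c(elements, "H")
      bonds <- rbind(bonds, data.frame(u = a, v = length(elements),
                                       order = "1"))
      fc <- c(fc, 0L); rad <- c(rad, 0L); chir <- c(chir, "unspecified")
    }
  }
  molecular_graph(elements, bonds, conformer = NULL, id = g$id,
                  formal_charge = fc, radical_electrons = rad,
                  chirality = chir)
}

#' Canonical SMILES of a molecular graph
#'
#' Canonicalization goes through Open Babel (stereochemistry retained when
#' present); used for deduplication and scaffold keys.
#'
#' @param graph A [molecular_graph()] or SMILES string.
#' @return Canonical SMILES string.
#' @export
canonical_smiles <- function(graph) {
  src <- if (is.character(graph)) {
    .check_smiles_syntax(graph)
    list(from = "SMI", text = paste0(graph, "\n"))
  } else {
    tmp <- tempfile(fileext = ".sdf")
    write_sdf(graph, tmp)
    txt <- paste(readLines(tmp), collapse = "\n")
    unlink(tmp)
    list(from = "SDF", text = txt)
  }
  out <- .ob_convert(src$from, "CAN", src$text)
  trimws(strsplit(out, "[\t\n]")[[1]][1])
}
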