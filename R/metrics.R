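# Evaluation metrics: elementwise R^2 / RMSE / MAE, Kabsch-aligned RMSD
# between conformers, and ensemble coverage (COV) / matching (MAT).

#' Coefficient of determination
#'
#' R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2) over flattened
#' elements.
#'
#' @param truth,pred Numeric vectors/matrices of equal shape (>= 2 elements).
#' @return R^2 (at most 1; undefined for constant truth).
#' @export
r_squared <- function(truth, pred) {
  y <- as.numeric(truth); yh <- as.numeric(pred)
  if (length(y) != length(yh)) stop("shapes differ")
  if (length(y) < 2L) stop("need at least 2 elements")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("R^2 undefined: truth has zero variance")
  1 - sum((y - yh)^2) / ss_tot
}

#' Root mean-squared error
#' @param truth,pred Numeric vectors/matrices of equal shape.
#' @return RMSE.
#' @export
rmse <- function(truth, pred) {
  y <- as.numeric(truth); yh <- as.numeric(pred)
  if (length(y) != length(yh)) stop("shapes differ")
  sqrt(mean((y - yh)^2))
}

#' Mean absolute error
#' @param truth,pred Numeric vectors/matrices of equal shape.
#' @return MAE.
#' @export
mae <- function(truth, pred) {
  y <- as.numeric(truth); yh <- as.numeric(pred)
  if (length(y) != length(yh)) stop("shapes differ")
  mean(abs(y - yh))
}

# Optimal superposition of candidate onto reference (both centered) by the
# Kabsch procedure. Returns the rotation with det +1; if allow_reflection,
# also considers the improper solution and keeps the better one.
.kabsch_rmsd <- function(ref, cand, allow_reflection = FALSE, align = TRUE,
                         weights_mask = NULL) {
  if (!is.null(weights_mask)) {
    ref <- ref[weights_mask, , drop = FALSE]
    cand <- cand[weights_mask, , drop = FALSE]
  }
  if (!align) return(sqrt(mean(rowSums((cand - ref)^2))))
  ref <- sweep(ref, 2L, colMeans(ref))
  cand <- sweep(cand, 2L, colMeans(cand))
  co <- crossprod(cand, ref)       # 3x3 covariance
  sv <- svd(co)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot_proper <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rmsd_of <- function(R) sqrt(mean(rowSums((cand %*% t(R) - ref)^2)))
  r1 <- rmsd_of(rot_proper)
  if (!allow_reflection || d == 1) return(r1)
  rot_improper <- sv$v %*% t(sv$u)
  min(r1, rmsd_of(rot_improper))
}

#' Aligned RMSD between two conformers
#'
#' Both conformers are centered and the candidate is optimally superposed
#' onto the reference by the Kabsch procedure (proper rotations; with
#' `allow_reflection = TRUE` the mirror image is also tried and the minimum
#' returned, appropriate when scoring reconstructions from a Gram matrix,
#' which cannot distinguish enantiomers). RMSD is the square root of the
#' mean squared deviation over heavy atoms (all atoms with
#' `heavy_only = FALSE`).
#'
#' @param reference,candidate [conformer()] objects with the same atom count
#'   and element order.
#' @param allow_reflection Also allow improper rotations in the alignment.
#' @param heavy_only Restrict to heavy atoms (default `TRUE`).
#' @param align Set `FALSE` to skip centering and superposition entirely
#'   (coordinates compared as given).
#' @return RMSD in Angstrom.
#' @export
aligned_rmsd <- function(reference, candidate, allow_reflection = FALSE,
                         heavy_only = TRUE, align = TRUE) {
  reference <- .check_conformer(reference)
  candidate <- .check_conformer(candidate)
  if (nrow(reference$coords) != nrow(candidate$coords)) {
    stop("conformers have different atom counts")
  }
  if (!identical(reference$elements, candidate$elements)) {
    stop("element order mismatch between conformers")
  }
  mask <- if (heavy_only && any(reference$heavy_mask)) {
    reference$heavy_mask
  } else rep(TRUE, nrow(reference$coords))
  .kabsch_rmsd(reference$coords, candidate$coords,
               allow_reflection = allow_reflection, align = align,
               weights_mask = mask)
}

#' Coverage and matching of a generated conformer ensemble
#'
#' COV is the fraction of reference conformers lying within RMSD `delta` of
#' at least one generated conformer; MAT is the mean over references of the
#' minimum RMSD to the generated set. Ensembles are truncated to
#' `max_ensemble` members (default 1, the single minimum-energy-conformer
#' evaluation regime).
#'
#' @param generated,reference Lists of [conformer()] objects (nonempty).
#' @param delta RMSD threshold in Angstrom (> 0).
#' @param max_ensemble Maximum ensemble size considered.
#' @param allow_reflection Passed to [aligned_rmsd()].
#' @return List with `COV` (in `[0, 1]`) and `MAT` (Angstrom).
#' @export
coverage_and_matching <- function(generated, reference, delta = 2.0,
                                  max_ensemble = 1L,
                                  allow_reflection = FALSE) {
  if (!length(reference)) stop("reference ensemble is empty")
  if (!length(generated)) stop("generated ensemble is empty")
  if (delta <= 0) stop("delta must be positive")
  generated <- generated[seq_len(min(max_ensemble, length(generated)))]
  reference <- reference[seq_len(min(max_ensemble, length(reference)))]
  min_rmsd <- vapply(reference, function(ref) {
    min(vapply(generated, function(gen) {
      aligned_rmsd(ref, gen, allow_reflection = allow_reflection)
    }, numeric(1)))
  }, numeric(1))
  list(COV = mean(min_rmsd < delta), MAT = mean(min_rmsd))
}

#' Full evaluation panel for a trained model
#'
#' For each test molecule with a reference conformer: predicts the Gram
#' matrix, derives the distance matrix, bond lengths and angles (MLP heads
#' where the variant has them, Gram-derived otherwise), reconstructs the
#' conformer by eigendecomposition and computes the aligned RMSD. Pools
#' matrix entries across molecules for R^2/RMSE/MAE and aggregates RMSD,
#' COV and MAT.
#'
#' @param object A fitted [pregtm()] model.
#' @param molecules Test molecules; those without conformers are skipped
#'   (and counted).
#' @param delta COV threshold in Angstrom.
#' @param allow_reflection Allow mirror alignment when scoring
#'   reconstructions (default `TRUE`: the Gram matrix is
#'   reflection-invariant).
#' @param use_stored_noise Replay training noise for training molecules.
#' @return A `"metric_report"` list: `per_molecule` data frame, `summary`
#'   list with per-target MAE/RMSE/R^2 (Gram, distance, lengths, angles in
#'   rad and degrees), RMSD mean/median, COV, MAT, and `skipped`.
#' @export
evaluation_report <- function(object, molecules, delta = 2.0,
                              allow_reflection = TRUE,
                              use_stored_noise = TRUE) {
  has_conf <- vapply(molecules, function(g) !is.null(g$conformer), logical(1))
  skipped <- sum(!has_conf)
  molecules <- molecules[has_conf]
  if (!length(molecules)) stop("no molecules with reference conformers")
  pool <- list(G = list(), Ghat = list(), D = list(), Dhat = list(),
               len = list(), lenhat = list(), ang = list(), anghat = list())
  rows <- list()
  for (g in molecules) {
    tg <- build_targets(g)
    Ghat <- predict(object, g, type = "gram",
                    use_stored_noise = use_stored_noise)
    Dhat <- gram_to_distance(gram_matrix(pmin(unclass(Ghat), 1e6)))
    lhat <- predict(object, g, type = "lengths",
                    use_stored_noise = use_stored_noise)
    ahat <- predict(object, g, type = "angles",
                    use_stored_noise = use_stored_noise)
    rec <- mds_reconstruct(Ghat, elements = g$elements)
    rmsd <- aligned_rmsd(g$conformer, rec,
                         allow_reflection = allow_reflection)
    pool$G[[g$id]] <- as.numeric(unclass(tg$G))
    pool$Ghat[[g$id]] <- as.numeric(unclass(Ghat))
    pool$D[[g$id]] <- as.numeric(unclass(tg$D))
    pool$Dhat[[g$id]] <- as.numeric(unclass(Dhat))
    pool$len[[g$id]] <- tg$bonds$length
    pool$lenhat[[g$id]] <- lhat
    pool$ang[[g$id]] <- tg$angles$angle
    pool$anghat[[g$id]] <- ahat
    rows[[g$id]] <- data.frame(
      id = g$id, n_atoms = n_atoms(g),
      gram_mae = mae(tg$G, Ghat), dist_mae = mae(tg$D, Dhat),
      rmsd = rmsd
    )
  }
  cat_pool <- function(nm) unlist(pool[[nm]], use.names = FALSE)
  per_mol <- do.call(rbind, rows)
  rownames(per_mol) <- NULL
  # ensemble metrics across the whole set: one generated conformer per
  # molecule against its one reference (the max_ensemble = 1 regime, where
  # COV reduces to the indicator mean of RMSD < delta and MAT to mean RMSD)
  min_rmsd <- per_mol$rmsd
  summary <- list(
    gram = list(MAE = mae(cat_pool("G"), cat_pool("Ghat")),
                RMSE = rmse(cat_pool("G"), cat_pool("Ghat")),
                R2 = r_squared(cat_pool("G"), cat_pool("Ghat"))),
    distance = list(MAE = mae(cat_pool("D"), cat_pool("Dhat")),
                    RMSE = rmse(cat_pool("D"), cat_pool("Dhat")),
                    R2 = r_squared(cat_pool("D"), cat_pool("Dhat"))),
    bond_length = list(MAE = mae(cat_pool("len"), cat_pool("lenhat")),
                       RMSE = rmse(cat_pool("len"), cat_pool("lenhat"))),
    bond_angle_rad = list(MAE = mae(cat_pool("ang"), cat_pool("anghat")),
                          RMSE = rmse(cat_pool("ang"), cat_pool("anghat"))),
    bond_angle_deg = list(MAE = mae(cat_pool("ang"), cat_pool("anghat")) *
                            180 / pi),
    rmsd = list(mean = mean(per_mol$rmsd), median = stats::median(per_mol$rmsd)),
    COV = mean(min_rmsd < delta), MAT = mean(min_rmsd),
    delta = delta
  )
  structure(list(per_molecule = per_mol, summary = summary,
                 skipped = skipped), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<metric_report: %d molecules (%d skipped)>\n",
              nrow(x$per_molecule), x$skipped))
  cat(sprintf("  Gram    MAE %.4g  RMSE %.4g  R2 %.4g\n",
              s$gram$MAE, s$gram$RMSE, s$gram$R2))
  cat(sprintf("  Dist    MAE %.4g  RMSE %.4g  R2 %.4g\n",
              s$distance$MAE, s$distance$RMSE, s$distance$R2))
  cat(sprintf("  Length  MAE %.4g A; Angle MAE %.4g rad (%.3g deg)\n",
              s$bond_length$MAE, s$bond_angle_rad$MAE, s$bond_angle_deg$MAE))
  cat(sprintf("  RMSD mean %.4g A (median %.4g); COV(%.2f A) %.3f; MAT %.4g A\n",
              s$rmsd$mean, s$rmsd$median, s$delta, s$COV, s$MAT))
  invisible(x)
}

#' Write a metric report to CSV + JSON
#'
#' @param report A `"metric_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_metric_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_molecule, file.path(dir, "per_molecule.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
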