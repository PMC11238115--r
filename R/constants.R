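# Numerical tolerances used across the package, kept in one place.
# - symmetry: relative tolerance for accepting a matrix as symmetric
# - radicand: relative clamp for negative squared distances derived from a
#   Gram matrix (scaled by max |G|)
# - rank: relative eigenvalue threshold (scaled by the largest eigenvalue)
#   separating "geometric" from "numerically zero" eigenvalues
.tol <- list(
  symmetry = 1e-9,
  radicand = 1e-6,
  rank     = 1e-9,
  centering = 1e-12
)

#' Numerical tolerances
#'
#' Returns the package-wide numerical tolerances: `symmetry` (relative
#' tolerance under which a matrix is accepted as symmetric), `radicand`
#' (relative clamp, scaled by `max(abs(G))`, below which a negative squared
#' distance derived from a Gram matrix is treated as roundoff and clamped to
#' zero), `rank` (relative eigenvalue cutoff, scaled by the largest
#' eigenvalue, separating geometric from numerically-zero eigenvalues) and
#' `centering` (absolute tolerance on centroid components of centered
#' coordinates).
#'
#' @return Named list of tolerances.
#' @export
gram_tolerances <- function() .tol

# Bondi van der Waals radii (Angstrom) for the elements the toolkit meets.
.vdw_radius <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98
)

# Covalent radii (Angstrom), used for bond inference from XYZ coordinates.
.cov_radius <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39
)

.atomic_number <- c(
  H = 1, C = 6, N = 7, O = 8, F = 9,
  P = 15, S = 16, Cl = 17, Br = 35, I = 53
)

# Default valences used by the sanitizer and the toy-molecule generator.
.default_valence <- c(H = 1, C = 4, N = 3, O = 2, F = 1)

# Idealized equilibrium bond lengths (Angstrom) by element pair and order,
# used only by the synthetic fixture generator.
.ideal_bond_length <- list(
  "C-C"  = c("1" = 1.54, "2" = 1.34, "3" = 1.20, "ar" = 1.39),
  "C-N"  = c("1" = 1.47, "2" = 1.28, "3" = 1.16, "ar" = 1.34),
  "C-O"  = c("1" = 1.43, "2" = 1.21),
  "C-F"  = c("1" = 1.35),
  "N-N"  = c("1" = 1.45, "2" = 1.25),
  "N-O"  = c("1" = 1.40, "2" = 1.21),
  "O-O"  = c("1" = 1.48),
  "C-H"  = c("1" = 1.09),
  "N-H"  = c("1" = 1.01),
  "O-H"  = c("1" = 0.96),
  "N-F"  = c("1" = 1.36),
  "O-F"  = c("1" = 1.42),
  "F-H"  = c("1" = 0.92)
)

.lookup_bond_length <- function(el1, el2, order = "1") {
  key <- paste(sort(c(el1, el2))[c(1, 2)], collapse = "-")
  # table keys are stored with the alphabetically first element first
  tab <- .ideal_bond_length[[key]]
  if (is.null(tab)) {
    tab <- .ideal_bond_length[[paste(rev(sort(c(el1, el2))), collapse = "-")]]
  }
  if (is.null(tab) || is.na(tab[order])) {
    return(sum(.cov_radius[c(el1, el2)]))
  }
  unname(tab[order])
}
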