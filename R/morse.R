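#' 3D-MoRSE scattering signal
#'
#' The electron-diffraction (3D-MoRSE) descriptor at scattering parameter `s`
#' (in reciprocal Angstroms),
#' \deqn{Mor(s) = \sum_{i<j} w_i w_j \frac{\sin(s\,r_{ij})}{s\,r_{ij}},}
#' summed over all atom pairs (hydrogens included), with the \eqn{s = 0} and
#' coincident-atom terms defined by the limit \eqn{\sin(x)/x \to 1}. Weights
#' are 1 (`"unit"`) or relative atomic mass scaled by carbon (`"mass"`), so
#' that the two schemes agree for pure-carbon skeletons.
#'
#' Descriptor names follow the MorNN convention: `MorNN` is the signal at
#' `s = NN - 1`, so `Mor29m` is the mass-weighted value at 28 reciprocal
#' Angstroms.
#'
#' @param mol a `mol_graph` with coordinates (see [embed_mol()]).
#' @param s scattering parameter, an integer in 0..31.
#' @param weighting `"unit"` or `"mass"`.
#' @return A single finite number, invariant to rigid motion of the molecule.
#' @export
morse_signal <- function(mol, s, weighting = c("unit", "mass")) {
  weighting <- match.arg(weighting)
  stopifnot(length(s) == 1L, s >= 0, s <= 31)
  if (!mol_has_coords(mol)) {
    stop("molecule has no 3D coordinates; call embed_mol() first")
  }
  w <- morse_weights(mol$atoms$element, weighting)
  r <- as.matrix(stats::dist(mol$atoms[, c("x", "y", "z")]))
  ut <- upper.tri(r)
  sr <- s * r[ut]
  f <- ifelse(sr == 0, 1, sin(sr) / sr)
  sum((w %o% w)[ut] * f)
}

morse_weights <- function(element, weighting) {
  if (weighting == "unit") rep(1, length(element))
  else element_property(element, "mass") / 12.011
}

#' Full 3D-MoRSE profile (both weighting schemes)
#'
#' @param mol a `mol_graph` with coordinates.
#' @return A named numeric vector `Mor01u`..`Mor32u`, `Mor01m`..`Mor32m`.
#' @export
morse_profile <- function(mol) {
  out <- c(
    vapply(0:31, function(s) morse_signal(mol, s, "unit"), numeric(1)),
    vapply(0:31, function(s) morse_signal(mol, s, "mass"), numeric(1))
  )
  names(out) <- c(sprintf("Mor%02du", 1:32), sprintf("Mor%02dm", 1:32))
  out
}
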