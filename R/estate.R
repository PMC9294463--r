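#' Kier-Hall intrinsic states
#'
#' The intrinsic state of a heavy atom is
#' \deqn{I = \frac{(2/L)^2 \delta_v + 1}{\delta}}
#' where \eqn{L} is the principal quantum number of the valence shell,
#' \eqn{\delta} the number of bonded heavy-atom neighbours and
#' \eqn{\delta_v} the valence delta. Two valence-delta conventions are in
#' circulation and descriptor packages differ silently in which they use:
#' the classic count \eqn{\delta_v = Z_v - h} and the screened (general
#' Kier-Hall) form \eqn{\delta_v = (Z_v - h)/(Z - Z_v - 1)} that accounts for
#' core electrons of higher-row atoms. They coincide for second-row elements;
#' for sulfur and the halogens they differ. The screened form is the package
#' default as it tracks the descriptor catalogue used for the lipoxygenase
#' models most closely; the classic form is available via `delta_v`.
#'
#' @param mol a `mol_graph`.
#' @param delta_v `"screened"` (default) or `"classic"` valence-delta
#'   convention.
#' @return A tibble with one row per heavy atom: `atom` (index into the
#'   molecule's atom list), `element`, `degree`, `n_h`, `delta_v`, `I`.
#' @export
intrinsic_states <- function(mol, delta_v = c("screened", "classic")) {
  delta_v <- match.arg(delta_v)
  hv <- heavy_atoms(mol)
  d <- mol_distances(mol)
  degree <- rowSums(d == 1L)
  if (any(degree == 0L) && length(hv) > 1L) {
    stop("isolated heavy atom: intrinsic state undefined for degree 0")
  }
  if (length(hv) == 1L) stop("intrinsic state undefined for a single atom")
  el <- mol$atoms$element[hv]
  nh <- heavy_h_counts(mol)
  zv <- element_property(el, "zv")
  z <- element_property(el, "z")
  L <- element_property(el, "period")
  dv <- switch(delta_v,
    classic  = zv - nh,
    screened = (zv - nh) / (z - zv - 1)
  )
  if (any(zv - nh < 0)) stop("more attached hydrogens than valence electrons")
  tibble::tibble(
    atom = hv, element = el, degree = as.integer(degree), n_h = nh,
    delta_v = dv, I = ((2 / L)^2 * dv + 1) / degree
  )
}

#' Electrotopological field perturbations
#'
#' For each heavy atom the perturbation of its intrinsic state by every other
#' heavy atom, \eqn{\Delta I_i = \sum_{j \ne i} (I_i - I_j)/(d_{ij}+1)^2},
#' with \eqn{d_{ij}} the topological (bond-count) distance. The pairwise
#' terms are antisymmetric, so the perturbations always sum to zero.
#'
#' @inheritParams intrinsic_states
#' @return Numeric vector of \eqn{\Delta I_i}, one per heavy atom.
#' @export
estate_variation <- function(mol, delta_v = c("screened", "classic")) {
  st <- intrinsic_states(mol, delta_v)
  d <- mol_distances(mol)
  if (any(!is.finite(d))) stop("disconnected molecular graph")
  Imat <- outer(st$I, st$I, "-") / (d + 1)^2
  diag(Imat) <- 0
  unname(rowSums(Imat))
}

#' MAXDP: maximal electrotopological positive variation
#'
#' The largest positive field perturbation \eqn{\max_i \Delta I_i} over the
#' heavy atoms (0 when no atom is positively perturbed). MAXDP summarises the
#' charge transfer an electrophilic molecule can sustain; in the
#' lipoxygenase models it enters with a negative coefficient.
#'
#' @inheritParams intrinsic_states
#' @return A single non-negative number.
#' @export
#' @examples
#' \dontrun{
#' maxdp(mol_from_smiles("CC"))       # 0: homogeneous graph
#' }
maxdp <- function(mol, delta_v = c("screened", "classic")) {
  max(c(estate_variation(mol, delta_v), 0))
}
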