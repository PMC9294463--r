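#' WHIM directional symmetry
#'
#' Projects the (unit-weighted) atomic coordinates onto their principal axes
#' and scores, per axis, how many atoms have a mirror partner across the
#' orthogonal plane. An atom with axis score \eqn{t} is *symmetric* along
#' axis \eqn{k} when another atom sits at \eqn{-t} within `tolerance` with
#' its remaining-axes scores matching within `tolerance`, or when it lies on
#' the plane itself (\eqn{|t| <} `tolerance`). With \eqn{n_s} symmetric atoms
#' out of \eqn{A}, the axis symmetry is \eqn{\gamma_k = 1/(1+S_k)} with
#' \deqn{S_k = -\left[\frac{n_s}{A}\log_2\frac{n_s}{A} +
#'       (A-n_s)\frac{1}{A}\log_2\frac{1}{A}\right],}
#' so \eqn{\gamma_k = 1} for a fully symmetric axis and
#' \eqn{1/(1+\log_2 A)} when no atom has a partner. `G2u` - the symmetry
#' along the second principal axis - is the WHIM term used in the
#' lipoxygenase models.
#'
#' Axes with null variance (e.g. the third axis of a planar or collinear
#' arrangement) have all scores at zero, every atom is its own mirror
#' partner, and the axis is reported fully symmetric.
#'
#' @param x a `mol_graph` with coordinates, or a numeric matrix of points
#'   (rows) by 3 columns.
#' @param tolerance matching tolerance in Angstroms.
#' @return An object of class `whim_symmetry`: a list with `gamma` (the three
#'   axis symmetries), `g` (their geometric mean), `n_sym`, `n_atoms` and
#'   `eigenvalues`.
#' @export
whim_symmetry <- function(x, tolerance = 0.15) {
  X <- if (inherits(x, "mol_graph")) {
    if (!mol_has_coords(x)) stop("molecule has no 3D coordinates")
    as.matrix(x$atoms[, c("x", "y", "z")])
  } else {
    as.matrix(x)
  }
  stopifnot(ncol(X) == 3L, nrow(X) >= 2L)
  A <- nrow(X)
  Xc <- scale(X, scale = FALSE)
  ev <- eigen(crossprod(Xc) / A, symmetric = TRUE)
  V <- principal_axes(ev)
  S <- Xc %*% V
  n_sym <- integer(3)
  for (k in 1:3) {
    oth <- setdiff(1:3, k)
    for (i in seq_len(A)) {
      if (abs(S[i, k]) < tolerance) {
        n_sym[k] <- n_sym[k] + 1L
        next
      }
      partner <- abs(S[, k] + S[i, k]) < tolerance &
        abs(S[, oth[1]] - S[i, oth[1]]) < tolerance &
        abs(S[, oth[2]] - S[i, oth[2]]) < tolerance
      partner[i] <- FALSE
      if (any(partner)) n_sym[k] <- n_sym[k] + 1L
    }
  }
  gamma <- vapply(n_sym, axis_gamma, numeric(1), A = A)
  structure(
    list(gamma = gamma, g = prod(gamma)^(1 / 3), n_sym = n_sym,
         n_atoms = A, eigenvalues = ev$values),
    class = "whim_symmetry"
  )
}

axis_gamma <- function(ns, A) {
  if (ns == A) return(1)
  p <- ns / A
  Sk <- -((if (p > 0) p * log2(p) else 0) + (A - ns) * (1 / A) * log2(1 / A))
  1 / (1 + Sk)
}

# Deterministic principal axes: eigen() orders by descending eigenvalue; for
# (near-)degenerate eigenvalues columns are re-ordered lexicographically, and
# each axis is signed so its largest-magnitude component is positive, making
# the symmetry scores reproducible.
principal_axes <- function(ev) {
  V <- ev$vectors
  lam <- ev$values
  for (k in 1:2) {
    if (abs(lam[k] - lam[k + 1]) < 1e-10) {
      cols <- V[, c(k, k + 1), drop = FALSE]
      ord <- order(cols[1, ], cols[2, ], cols[3, ])
      V[, c(k, k + 1)] <- cols[, ord]
    }
  }
  for (k in 1:3) {
    piv <- which.max(abs(V[, k]))
    if (V[piv, k] < 0) V[, k] <- -V[, k]
  }
  V
}

#' @export
print.whim_symmetry <- function(x, ...) {
  cat(sprintf("<whim_symmetry: A=%d, gamma=(%.3f, %.3f, %.3f), G=%.3f>\n",
              x$n_atoms, x$gamma[1], x$gamma[2], x$gamma[3], x$g))
  invisible(x)
}

#' Symmetry along the second principal axis (G2u)
#'
#' @inheritParams whim_symmetry
#' @return \eqn{\gamma_2} from [whim_symmetry()] with unit weights.
#' @export
g2u <- function(x, tolerance = 0.15) whim_symmetry(x, tolerance)$gamma[2]
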