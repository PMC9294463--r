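#' Molecular graph objects
#'
#' A `mol_graph` holds an ordered atom list (element symbols plus Cartesian
#' coordinates once embedded), a bond list, and gives access to the
#' topological (bond-count) distance matrix of the hydrogen-suppressed graph.
#' Hydrogens are kept as explicit atoms so that attached-H counts and 3D
#' descriptors can use them; the electrotopological machinery works on the
#' heavy-atom view.
#'
#' @name mol_graph
NULL

new_mol_graph <- function(id, atoms, bonds, smiles = NULL) {
  mol <- structure(
    list(id = id, atoms = atoms, bonds = bonds, smiles = smiles),
    class = "mol_graph"
  )
  g <- mol_igraph(mol)
  if (igraph::components(g)$no > 1L) {
    stop("molecule ", id, " has more than one fragment; ",
         "only single connected molecules are supported")
  }
  mol
}

mol_igraph <- function(mol) {
  igraph::add_edges(
    igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE),
    as.vector(rbind(mol$bonds$i, mol$bonds$j))
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  nh <- sum(x$atoms$element == "H")
  cat(sprintf("<mol_graph %s: %d atoms (%d heavy), %d bonds, %s>\n",
              x$id %||% "?", nrow(x$atoms), nrow(x$atoms) - nh,
              nrow(x$bonds),
              if (mol_has_coords(x)) "3D" else "no coordinates"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mol_has_coords <- function(mol) {
  any(abs(c(mol$atoms$x, mol$atoms$y, mol$atoms$z)) > 1e-8)
}

heavy_atoms <- function(mol) which(mol$atoms$element != "H")

# explicit-H neighbour count for each heavy atom
heavy_h_counts <- function(mol) {
  hv <- heavy_atoms(mol)
  is_h <- mol$atoms$element == "H"
  cnt <- integer(nrow(mol$atoms))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    if (is_h[j]) cnt[i] <- cnt[i] + 1L
    if (is_h[i]) cnt[j] <- cnt[j] + 1L
  }
  cnt[hv]
}

#' Topological distances of the hydrogen-suppressed graph
#'
#' Bond-count shortest-path distances between heavy atoms, computed by
#' breadth-first search on the heavy-atom subgraph.
#'
#' @param mol a `mol_graph`.
#' @return A symmetric integer matrix with zero diagonal, one row per heavy
#'   atom (in atom order).
#' @export
mol_distances <- function(mol) {
  hv <- heavy_atoms(mol)
  g <- igraph::induced_subgraph(mol_igraph(mol), hv)
  d <- igraph::distances(g)
  dimnames(d) <- list(hv, hv)
  d
}

ob_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop("the `obabel` executable is required but was not found on PATH")
  }
  p
}

ob_run <- function(infile, outfile, args) {
  status <- suppressWarnings(
    system2(ob_path(), c(infile, "-osdf", "-O", outfile, args),
            stdout = FALSE, stderr = FALSE)
  )
  if (!identical(status, 0L) || !file.exists(outfile)) {
    stop("OpenBabel conversion failed")
  }
  invisible(outfile)
}

# Read every molecule of an SDF file into mol_graph objects (ChemmineR does
# the V2000 parsing).
sdf_to_mols <- function(path, smiles = NULL) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  ChemmineR::validSDF(sdfs) # drop nothing; errors surface via length check
  if (length(sdfs) == 0L) stop("no molecules could be parsed")
  out <- vector("list", length(sdfs))
  for (m in seq_along(sdfs)) {
    sdf <- sdfs[[m]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    atoms <- tibble::tibble(
      element = sub("_.*$", "", rownames(ab)),
      x = unname(ab[, 1]), y = unname(ab[, 2]), z = unname(ab[, 3])
    )
    bonds <- tibble::tibble(
      i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
      order = as.integer(bb[, 3])
    )
    id <- unname(ChemmineR::sdfid(sdf))
    out[[m]] <- new_mol_graph(
      if (nzchar(id)) id else paste0("mol", m), atoms, bonds,
      smiles = if (length(smiles) >= m) smiles[m] else NULL
    )
  }
  out
}

#' Parse a SMILES string into a molecular graph
#'
#' Uses OpenBabel to interpret the line notation and to make hydrogens
#' explicit; the result carries no coordinates until [embed_mol()] is called.
#'
#' @param smiles a single SMILES string describing one connected molecule.
#' @param id optional identifier attached to the molecule.
#' @return A `mol_graph`.
#' @export
#' @examples
#' \dontrun{
#' mol <- mol_from_smiles("O=C1NC(=O)CS1", id = "tzd")
#' }
mol_from_smiles <- function(smiles, id = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  id <- id %||% "mol1"
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)))
  writeLines(paste(smiles, id, sep = "\t"), fin)
  tryCatch(ob_run(fin, fout, "-h"),
           error = function(e) stop("could not parse SMILES: ", smiles))
  mols <- tryCatch(
    sdf_to_mols(fout, smiles = smiles),
    error = function(e) {
      if (grepl("fragment", conditionMessage(e))) stop(e)
      stop("could not parse SMILES: ", smiles)
    }
  )
  mols[[1]]
}

#' Read a SMILES file (one molecule per line, optional id column)
#'
#' @param path path to a file with one `SMILES[<whitespace>id]` pair per line.
#' @return A list of `mol_graph` objects.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  lapply(seq_along(parts), function(k) {
    mol_from_smiles(parts[[k]][1],
                    id = if (length(parts[[k]]) > 1) parts[[k]][2]
                         else paste0("mol", k))
  })
}

#' Read molecules from an SDF (V2000) file
#'
#' @param path path to an SDF file.
#' @return A list of `mol_graph` objects (coordinates kept when present).
#' @export
read_sdf_mols <- function(path) sdf_to_mols(path)

#' Write molecules to an SDF (V2000) file with embedded coordinates
#'
#' @param mols a `mol_graph` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "mol_graph")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) writeLines(mol_to_sdf_lines(mol), con)
  invisible(path)
}

mol_to_sdf_lines <- function(mol) {
  na <- nrow(mol$atoms); nb <- nrow(mol$bonds)
  fmt10 <- function(v) formatC(v, format = "f", digits = 4, width = 10)
  fmt3 <- function(v) formatC(v, format = "d", width = 3)
  c(
    mol$id %||% "", " tzdqsar", "",
    paste0(fmt3(na), fmt3(nb), "  0  0  0  0  0  0  0  0999 V2000"),
    sprintf("%s%s%s %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            fmt10(mol$atoms$x), fmt10(mol$atoms$y), fmt10(mol$atoms$z),
            mol$atoms$element),
    paste0(fmt3(mol$bonds$i), fmt3(mol$bonds$j), fmt3(mol$bonds$order),
           "  0  0  0  0"),
    "M  END",
    "$$$$"
  )
}
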