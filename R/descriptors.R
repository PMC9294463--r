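#' Compute the descriptor block for a compound table
#'
#' Runs the whole structure-to-descriptor chain for each compound: SMILES
#' parsing, seeded 3D embedding, the 64 3D-MoRSE signals (unit and mass
#' weighted), the WHIM directional symmetries (G1u, G2u, G3u and their
#' geometric mean Gu) and the electrotopological MAXDP.
#'
#' @param compounds a data frame with columns `id` and `smiles`
#'   (e.g. [tzd_compounds()]).
#' @param seed embedding seed, applied per compound.
#' @param tolerance WHIM symmetry-matching tolerance in Angstroms.
#' @param delta_v intrinsic-state valence-delta convention for MAXDP.
#' @return A tibble: `id` plus 69 descriptor columns.
#' @export
compute_descriptors <- function(compounds, seed = 1L, tolerance = 0.15,
                                delta_v = c("screened", "classic")) {
  delta_v <- match.arg(delta_v)
  stopifnot(all(c("id", "smiles") %in% names(compounds)))
  rows <- purrr::map(seq_len(nrow(compounds)), function(k) {
    mol <- mol_from_smiles(compounds$smiles[k], id = compounds$id[k])
    mol <- embed_mol(mol, seed = seed)
    ws <- whim_symmetry(mol, tolerance = tolerance)
    c(morse_profile(mol),
      G1u = ws$gamma[1], G2u = ws$gamma[2], G3u = ws$gamma[3], Gu = ws$g,
      MAXDP = maxdp(mol, delta_v = delta_v))
  })
  dplyr::bind_cols(
    tibble::tibble(id = compounds$id),
    tibble::as_tibble(do.call(rbind, rows))
  )
}

#' Read / write descriptor tables
#'
#' Delimited text with the compound id in the first column and descriptor
#' names in the header, the format produced by [compute_descriptors()] and
#' consumed by the model-search stage.
#'
#' @param path file path.
#' @return `read_descriptor_table()` returns a tibble with an `id` column.
#' @export
read_descriptor_table <- function(path) {
  d <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                  check.names = FALSE))
  names(d)[1] <- "id"
  d$id <- as.character(d$id)
  d
}

#' @param x a descriptor tibble (first column the compound id).
#' @rdname read_descriptor_table
#' @export
write_descriptor_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
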