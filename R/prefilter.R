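#' Descriptor prefiltering
#'
#' Standard QSAR descriptor reduction: drop constant (or near-constant)
#' columns, then break up over-correlated pairs. Pairs are scanned in a
#' deterministic left-to-right column order; whenever two surviving columns
#' have \eqn{|r| >} `corr_threshold`, the member with the *lower* absolute
#' correlation to the response is dropped (the later column when no response
#' is supplied). Survivor sets depend on this order, which is why it is
#' fixed and documented.
#'
#' @param x a descriptor tibble (an `id` column, if present, is carried
#'   through untouched) or numeric matrix.
#' @param y optional numeric response used to arbitrate correlated pairs.
#' @param const_tol variance at or below which a column counts as constant.
#' @param corr_threshold absolute pairwise Pearson correlation above which
#'   one member of a pair is removed (0.85 mirrors the ">85%" rule used for
#'   the lipoxygenase models).
#' @return The filtered tibble; attribute `"dropped"` records removed columns
#'   and the reason.
#' @export
prefilter_descriptors <- function(x, y = NULL, const_tol = 1e-8,
                                  corr_threshold = 0.85) {
  tbl <- tibble::as_tibble(x)
  id <- NULL
  if ("id" %in% names(tbl)) {
    id <- tbl["id"]
    tbl <- dplyr::select(tbl, -"id")
  }
  if (ncol(tbl) == 0L) stop("no descriptor columns to filter")
  if (anyNA(tbl)) stop("descriptor matrix contains missing values")

  dropped <- character(0); reason <- character(0)
  keep <- names(tbl)

  vars <- vapply(tbl, var, numeric(1))
  const <- keep[vars <= const_tol]
  dropped <- c(dropped, const)
  reason <- c(reason, rep("constant", length(const)))
  keep <- setdiff(keep, const)

  alive <- keep
  i1 <- 1L
  while (i1 < length(alive)) {
    a <- alive[i1]
    i2 <- i1 + 1L
    anchor_dropped <- FALSE
    while (i2 <= length(alive)) {
      b <- alive[i2]
      r <- cor(tbl[[a]], tbl[[b]])
      if (abs(r) > corr_threshold) {
        drop <- if (is.null(y)) b else {
          if (abs(cor(tbl[[a]], y)) >= abs(cor(tbl[[b]], y))) b else a
        }
        dropped <- c(dropped, drop)
        reason <- c(reason, sprintf("|r|=%.3f with %s",
                                    abs(r), if (drop == b) a else b))
        alive <- setdiff(alive, drop)
        if (drop == a) {
          anchor_dropped <- TRUE
          break
        }
        # b dropped: alive shrank, the next column now sits at position i2
      } else {
        i2 <- i2 + 1L
      }
    }
    if (!anchor_dropped) i1 <- i1 + 1L
  }

  if (length(alive) == 0L) {
    stop("prefilter removed every descriptor column")
  }
  out <- tbl[alive]
  if (!is.null(id)) out <- dplyr::bind_cols(id, out)
  attr(out, "dropped") <- tibble::tibble(column = dropped, reason = reason)
  out
}
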