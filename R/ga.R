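#' Genetic-algorithm control parameters
#'
#' Defaults follow common practice for small descriptor pools: a population
#' of 100 subsets evolved for up to 300 generations with tournament
#' selection (size 3), uniform crossover, per-gene mutation and elitism;
#' evolution stops early once the best fitness has stalled.
#'
#' @param pop_size population size.
#' @param generations maximum generations.
#' @param tournament tournament size for parent selection.
#' @param p_crossover probability of uniform crossover between two parents.
#' @param p_mutation per-gene mutation probability.
#' @param elitism number of best individuals copied unchanged.
#' @param stall stop after this many generations without improvement.
#' @return A list of class `ga_control`.
#' @export
ga_control <- function(pop_size = 100L, generations = 300L, tournament = 3L,
                       p_crossover = 0.8, p_mutation = 0.05, elitism = 2L,
                       stall = 50L) {
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = as.integer(elitism), stall = as.integer(stall)),
            class = "ga_control")
}

# Subset fitness: Q2_LOO of the OLS fit on those columns (-Inf when the fit
# or its cross-validation is impossible).
subset_fitness <- function(X, y, idx, cache = NULL) {
  key <- paste(idx, collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  val <- tryCatch(q2_loo(X[, idx, drop = FALSE], y)$q2,
                  error = function(e) -Inf)
  if (!is.null(cache)) cache[[key]] <- val
  val
}

strip_id <- function(x) {
  if (is.matrix(x) && is.null(colnames(x))) {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  tbl <- tibble::as_tibble(x, .name_repair = "minimal")
  if ("id" %in% names(tbl)) tbl <- dplyr::select(tbl, -"id")
  as.matrix(tbl)
}

#' Genetic-algorithm descriptor-subset selection
#'
#' Evolves descriptor subsets of at most `max_size` columns, scoring each by
#' the leave-one-out cross-validated \eqn{Q^2} of its OLS fit - the
#' orientation used when the lipoxygenase models were generated, where the
#' subset size was capped at three. Chromosomes are fixed-length index sets;
#' selection is by tournament, recombination by uniform crossover and
#' mutation re-draws single genes. The run is reproducible for a fixed seed.
#'
#' @param x descriptor tibble (optionally with an `id` column) or matrix,
#'   already prefiltered.
#' @param y numeric response.
#' @param max_size maximum subset size (3 for the paper-style runs).
#' @param control a [ga_control()] list.
#' @param seed integer seed.
#' @return A tibble of class `subset_ranking` - one row per distinct subset
#'   evaluated, ranked by fitness: `rank`, `fitness` (\eqn{Q^2_{LOO}}),
#'   `subset` (list of column-name vectors), `model` (list of `mlr_model`).
#' @export
ga_select <- function(x, y, max_size = 3L, control = ga_control(),
                      seed = 1L) {
  X <- strip_id(x)
  p <- ncol(X)
  if (max_size >= p) {
    warning("max_size >= number of descriptors; returning the full model")
    return(rank_subsets(X, y, list(seq_len(p))))
  }
  set.seed(as.integer(seed))
  cache <- new.env(parent = emptyenv())

  chrom <- replicate(control$pop_size, sample.int(p, max_size),
                     simplify = FALSE)
  fit <- vapply(chrom, function(g) subset_fitness(X, y, sort(unique(g)),
                                                  cache),
                numeric(1))
  best <- max(fit); since_improved <- 0L
  for (gen in seq_len(control$generations)) {
    ord <- order(fit, decreasing = TRUE)
    nextgen <- chrom[ord[seq_len(control$elitism)]]
    while (length(nextgen) < control$pop_size) {
      pa <- chrom[[tournament_pick(fit, control$tournament)]]
      pb <- chrom[[tournament_pick(fit, control$tournament)]]
      child <- pa
      if (runif(1) < control$p_crossover) {
        take <- runif(max_size) < 0.5
        child[take] <- pb[take]
      }
      mut <- runif(max_size) < control$p_mutation
      if (any(mut)) child[mut] <- sample.int(p, sum(mut), replace = TRUE)
      nextgen[[length(nextgen) + 1L]] <- child
    }
    chrom <- nextgen
    fit <- vapply(chrom, function(g) subset_fitness(X, y, sort(unique(g)),
                                                    cache),
                  numeric(1))
    if (max(fit) > best + 1e-12) {
      best <- max(fit); since_improved <- 0L
    } else {
      since_improved <- since_improved + 1L
      if (since_improved >= control$stall) break
    }
  }

  evaluated <- lapply(ls(cache), function(k)
    as.integer(strsplit(k, ",")[[1]]))
  rank_subsets(X, y, evaluated, cache = cache, seed = seed)
}

tournament_pick <- function(fit, k) {
  cand <- sample.int(length(fit), k)
  cand[which.max(fit[cand])]
}

#' Exhaustive descriptor-subset search
#'
#' Evaluates every non-empty subset of up to `max_size` columns with the same
#' fitness as [ga_select()]; the exact ranking serves as the oracle the
#' genetic search is checked against.
#'
#' @inheritParams ga_select
#' @param cap refuse to enumerate more than this many subsets.
#' @return A `subset_ranking` tibble (see [ga_select()]).
#' @export
exhaustive_select <- function(x, y, max_size = 3L, cap = 10000L) {
  X <- strip_id(x)
  p <- ncol(X)
  max_size <- min(max_size, p)
  n_subsets <- sum(choose(p, seq_len(max_size)))
  if (n_subsets > cap) {
    stop("exhaustive search would evaluate ", n_subsets,
         " subsets (cap ", cap, ")")
  }
  subsets <- unlist(
    lapply(seq_len(max_size), function(k)
      utils::combn(p, k, simplify = FALSE)),
    recursive = FALSE
  )
  rank_subsets(X, y, subsets)
}

rank_subsets <- function(X, y, subsets, cache = NULL, seed = NULL) {
  keys <- vapply(subsets, paste, character(1), collapse = ",")
  keep <- !duplicated(keys)
  subsets <- subsets[keep]
  fit <- vapply(subsets, function(idx) subset_fitness(X, y, idx, cache),
                numeric(1))
  ord <- order(fit, decreasing = TRUE)
  subsets <- subsets[ord]; fit <- fit[ord]
  nm <- colnames(X)
  d <- tibble::as_tibble(cbind(id = seq_along(y), as.data.frame(X)))
  models <- lapply(subsets, function(idx) {
    df <- d[c("id", nm[idx])]
    df$.y <- y
    tryCatch(fit_mlr(df, response = ".y", descriptors = nm[idx]),
             error = function(e) NULL)
  })
  out <- tibble::tibble(
    rank = seq_along(subsets),
    fitness = fit,
    subset = lapply(subsets, function(idx) nm[idx]),
    model = models
  )
  class(out) <- c("subset_ranking", class(out))
  attr(out, "seed") <- seed
  out
}
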