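#' Reproduce the full lipoxygenase QSAR analysis path
#'
#' Runs the complete analysis on the packaged 19-compound set: fit the
#' three-descriptor model (`Mor29m`, `G2u`, `MAXDP` by default) on the
#' decimal-log LOX inhibition of all compounds, validate it, inspect the
#' Williams applicability domain, exclude the flagged response outliers and
#' refit on the remaining compounds, validating again. Descriptors are
#' computed from structure by default; a pre-computed descriptor table (for
#' example the published supplementary values) can be supplied for
#' bit-faithful reproduction and is matched by compound id and descriptor
#' name, tolerant of column order.
#'
#' @param descriptors `NULL` (compute from structures), a path to a
#'   descriptor CSV, or a descriptor tibble with an `id` column.
#' @param descriptor_set names of the model descriptors.
#' @param seed seed applied to embedding, LMO and Y-scrambling.
#' @param exclude_outliers refit after removing |std. residual| > 2
#'   compounds (the published path)?
#' @param lmo_fraction,lmo_iterations,n_perm validation settings.
#' @param output_dir optional directory; when given, all tables and a run
#'   manifest are written there as CSV/JSON.
#' @return A list of class `qsar_run`: `model_full`, `validation_full`,
#'   `domain`, `outliers`, `model_reduced`, `validation_reduced`,
#'   `correlations`, `thresholds_full`, `thresholds_reduced`, `manifest`.
#' @export
qsar_reproduce <- function(descriptors = NULL,
                           descriptor_set = c("Mor29m", "G2u", "MAXDP"),
                           seed = 1L, exclude_outliers = TRUE,
                           lmo_fraction = 0.3, lmo_iterations = 1000L,
                           n_perm = 2000L, output_dir = NULL) {
  compounds <- tzd_compounds()
  desc <- resolve_descriptors(descriptors, compounds, seed)
  missing <- setdiff(descriptor_set, names(desc))
  if (length(missing)) {
    stop("descriptor table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  d <- dplyr::inner_join(compounds[c("id", "log_lox")], desc, by = "id")
  if (nrow(d) != nrow(compounds)) {
    stop("descriptor table does not cover every compound id")
  }

  model1 <- fit_mlr(d, response = "log_lox", descriptors = descriptor_set)
  val1 <- validate_model(model1, lmo_fraction = lmo_fraction,
                         lmo_iterations = lmo_iterations, n_perm = n_perm,
                         seed = seed)
  ad <- williams_domain(model1)
  outliers <- ad$id[ad$outlier]

  model2 <- NULL; val2 <- NULL; thr2 <- NULL
  if (exclude_outliers && length(outliers)) {
    d2 <- dplyr::filter(d, !.data$id %in% outliers)
    model2 <- fit_mlr(d2, response = "log_lox",
                      descriptors = descriptor_set)
    val2 <- validate_model(model2, lmo_fraction = lmo_fraction,
                           lmo_iterations = lmo_iterations,
                           n_perm = n_perm, seed = seed)
    thr2 <- check_thresholds(val2)
  }

  run <- structure(
    list(
      model_full = model1,
      validation_full = val1,
      thresholds_full = check_thresholds(val1),
      domain = ad,
      outliers = outliers,
      model_reduced = model2,
      validation_reduced = val2,
      thresholds_reduced = thr2,
      correlations = correlation_matrix(d, "log_lox", descriptor_set),
      manifest = list(
        descriptor_source = if (is.null(descriptors)) "computed"
                            else "external",
        descriptor_set = descriptor_set,
        descriptor_md5 = table_md5(desc),
        seed = seed,
        lmo_fraction = lmo_fraction, lmo_iterations = lmo_iterations,
        n_perm = n_perm,
        package_version = as.character(utils::packageVersion("tzdqsar"))
      )
    ),
    class = "qsar_run"
  )
  if (!is.null(output_dir)) write_run(run, desc, output_dir)
  run
}

resolve_descriptors <- function(descriptors, compounds, seed) {
  if (is.null(descriptors)) {
    compute_descriptors(compounds, seed = seed)
  } else if (is.character(descriptors) && length(descriptors) == 1L) {
    read_descriptor_table(descriptors)
  } else {
    d <- tibble::as_tibble(descriptors)
    if (!"id" %in% names(d)) stop("descriptor table needs an `id` column")
    d
  }
}

table_md5 <- function(x) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  write.csv(x, tf, row.names = FALSE)
  unname(tools::md5sum(tf))
}

write_run <- function(run, desc, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(output_dir, f)
  write_descriptor_table(desc, fp("descriptors.csv"))
  write.csv(run$validation_full, fp("validation_full.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(run$domain), fp("applicability_domain.csv"),
            row.names = FALSE)
  write.csv(run$correlations, fp("correlation_matrix.csv"))
  write_model_json(run$model_full, fp("model_full.json"),
                   seed = run$manifest$seed)
  if (!is.null(run$model_reduced)) {
    write.csv(run$validation_reduced, fp("validation_reduced.csv"),
              row.names = FALSE)
    write_model_json(run$model_reduced, fp("model_reduced.json"),
                     seed = run$manifest$seed)
  }
  jsonlite::write_json(run$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' @export
print.qsar_run <- function(x, ...) {
  cat("QSAR run (", x$manifest$descriptor_source, " descriptors)\n",
      sep = "")
  cat("\nFull-set model:\n"); print(x$model_full)
  if (length(x$outliers)) {
    cat("\nResponse outliers (|std. residual| > 2): ",
        paste(x$outliers, collapse = ", "), "\n", sep = "")
  } else {
    cat("\nNo response outliers flagged.\n")
  }
  if (!is.null(x$model_reduced)) {
    cat("\nOutlier-excluded model:\n"); print(x$model_reduced)
  }
  invisible(x)
}

#' Run one pipeline stage with file- or object-based inputs
#'
#' Thin dispatcher over the package's stages so that each step can be driven
#' independently and composed into the full analysis: `"descriptors"`,
#' `"prefilter"`, `"select"`, `"fit"`, `"validate"`, `"domain"`,
#' `"reproduce"`, `"simulate"`.
#'
#' @param stage stage name.
#' @param inputs named list of stage inputs; tibbles or file paths
#'   (`descriptors` entries may be CSV paths; `compounds` may be a SMILES
#'   table).
#' @param config named list of stage options (seeds, thresholds, GA and
#'   validation settings, `output_dir`).
#' @return The stage artifact (tibble, model, report or run object).
#' @export
run_stage <- function(stage, inputs = list(), config = list()) {
  cfg <- function(nm, default) config[[nm]] %||% default
  get_desc <- function() {
    d <- inputs$descriptors
    if (is.character(d)) read_descriptor_table(d) else tibble::as_tibble(d)
  }
  get_response <- function(d) {
    if (!is.null(inputs$response)) return(inputs$response)
    compounds <- tzd_compounds()
    m <- dplyr::inner_join(compounds[c("id", "log_lox")], d, by = "id")
    if (nrow(m) != nrow(d)) stop("response not resolvable for every row")
    m$log_lox
  }
  switch(match.arg(stage, c("descriptors", "prefilter", "select", "fit",
                            "validate", "domain", "reproduce",
                            "simulate")),
    descriptors = {
      compounds <- inputs$compounds %||% tzd_compounds()
      if (is.character(compounds)) {
        compounds <- tibble::as_tibble(read.csv(compounds,
                                                stringsAsFactors = FALSE))
      }
      compute_descriptors(compounds, seed = cfg("seed", 1L),
                          tolerance = cfg("tolerance", 0.15))
    },
    prefilter = {
      d <- get_desc()
      prefilter_descriptors(d, y = inputs$response,
                            const_tol = cfg("const_tol", 1e-8),
                            corr_threshold = cfg("corr_threshold", 0.85))
    },
    select = {
      d <- get_desc()
      ga_select(d, get_response(d), max_size = cfg("max_size", 3L),
                control = cfg("control", ga_control()),
                seed = cfg("seed", 1L))
    },
    fit = {
      d <- get_desc()
      y <- get_response(d)
      df <- dplyr::mutate(d, .y = y)
      fit_mlr(df, response = ".y",
              descriptors = cfg("descriptor_set",
                                c("Mor29m", "G2u", "MAXDP")))
    },
    validate = {
      validate_model(inputs$model,
                     lmo_fraction = cfg("lmo_fraction", 0.3),
                     lmo_iterations = cfg("lmo_iterations", 1000L),
                     n_perm = cfg("n_perm", 2000L),
                     seed = cfg("seed", 1L))
    },
    domain = {
      if (!is.null(inputs$model)) {
        williams_domain(inputs$model,
                        res_threshold = cfg("res_threshold", 2))
      } else {
        h_star <- warning_leverage(cfg("n", 19L), cfg("p_prime", 4L))
        tibble::tibble(n = cfg("n", 19L), p_prime = cfg("p_prime", 4L),
                       h_star = h_star)
      }
    },
    reproduce = {
      qsar_reproduce(descriptors = inputs$descriptors,
                     descriptor_set = cfg("descriptor_set",
                                          c("Mor29m", "G2u", "MAXDP")),
                     seed = cfg("seed", 1L),
                     lmo_fraction = cfg("lmo_fraction", 0.3),
                     lmo_iterations = cfg("lmo_iterations", 1000L),
                     n_perm = cfg("n_perm", 2000L),
                     output_dir = cfg("output_dir", NULL))
    },
    simulate = {
      synth_generate(inputs$spec %||% synth_spec(seed = cfg("seed", 1L)))
    }
  )
}
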