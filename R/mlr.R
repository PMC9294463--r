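#' Fit an ordinary-least-squares multi-linear QSAR model
#'
#' Least-squares fit of `response ~ descriptors` with an intercept, the model
#' form of the lipoxygenase equations (at most three descriptors there). The
#' design must be full column rank; collinear columns are reported by name.
#'
#' @param data a data frame holding the response and descriptor columns (an
#'   `id` column, if present, is used to label observations).
#' @param response name of the response column.
#' @param descriptors character vector of descriptor column names; defaults
#'   to every numeric column except the response.
#' @return An object of class `mlr_model` with coefficients, fitted values,
#'   residuals and the training design; supports [coef()], [predict()],
#'   [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 4.1, 5, 5.9), x = 1:6)
#' fit_mlr(d, response = "y", descriptors = "x")
fit_mlr <- function(data, response, descriptors = NULL) {
  data <- tibble::as_tibble(data)
  if (!response %in% names(data)) {
    stop("response column `", response, "` not found")
  }
  if (is.null(descriptors)) {
    descriptors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                           c(response, "id"))
  }
  missing <- setdiff(descriptors, names(data))
  if (length(missing)) {
    stop("descriptor column(s) not found: ", paste(missing, collapse = ", "))
  }
  y <- data[[response]]
  X <- as.matrix(data[descriptors])
  storage.mode(X) <- "double"
  n <- length(y); p <- ncol(X)
  if (n <= p + 1L) stop("need n > p + 1 observations for an OLS fit")

  Xa <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xa)
  if (qx$rank < ncol(Xa)) {
    bad <- colnames(Xa)[qx$pivot[(qx$rank + 1L):ncol(Xa)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, y)
  fitted <- drop(Xa %*% coefs)
  res <- y - fitted

  structure(
    list(
      coefficients = coefs,
      descriptors = descriptors,
      response = response,
      n = n, p = p,
      fitted = fitted,
      residuals = res,
      y = y,
      X = X,
      qr = qx,
      ids = if ("id" %in% names(data)) as.character(data$id)
            else as.character(seq_len(n))
    ),
    class = "mlr_model"
  )
}

#' @export
print.mlr_model <- function(x, ...) {
  eq <- paste0(
    format(round(x$coefficients[1], 3)),
    paste0(sprintf(" %+.3f*%s", x$coefficients[-1], x$descriptors),
           collapse = "")
  )
  cat(sprintf("<mlr_model: %s = %s  (n = %d)>\n", x$response, eq, x$n))
  invisible(x)
}

#' @export
coef.mlr_model <- function(object, ...) object$coefficients

#' @export
fitted.mlr_model <- function(object, ...) object$fitted

#' @export
residuals.mlr_model <- function(object, ...) object$residuals

#' Predict from a fitted QSAR model
#'
#' @param object an `mlr_model`.
#' @param newdata data frame containing (at least) the model's descriptor
#'   columns, matched by name; defaults to the training data.
#' @param ... unused.
#' @return Numeric vector of predictions \eqn{b_0 + X b}.
#' @export
predict.mlr_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  newdata <- tibble::as_tibble(newdata)
  missing <- setdiff(object$descriptors, names(newdata))
  if (length(missing)) {
    stop("newdata is missing descriptor column(s): ",
         paste(missing, collapse = ", "))
  }
  X <- as.matrix(newdata[object$descriptors])
  drop(cbind(1, X) %*% object$coefficients)
}

#' @method tidy mlr_model
#' @export
tidy.mlr_model <- function(x, ...) {
  s2 <- sum(x$residuals^2) / (x$n - x$p - 1)
  XtXinv <- chol2inv(qr.R(x$qr))
  se <- sqrt(diag(XtXinv) * s2)
  est <- unname(x$coefficients)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = est,
    std.error = se,
    statistic = est / se,
    p.value = 2 * stats::pt(abs(est / se), df = x$n - x$p - 1,
                            lower.tail = FALSE)
  )
}

#' @method glance mlr_model
#' @export
glance.mlr_model <- function(x, ...) {
  st <- fit_statistics(x$y, x$fitted, x$p)
  loo <- q2_loo(x$X, x$y)
  tibble::tibble(
    r.squared = st$R2, adj.r.squared = st$R2_adj, sigma = st$s,
    statistic = st$F, q2.loo = loo$q2, press = loo$press,
    nobs = x$n, df = x$p
  )
}

#' Serialize a model to JSON
#'
#' @param model an `mlr_model`.
#' @param path output path.
#' @param seed,fitness optional provenance fields stored alongside the
#'   coefficients.
#' @return `path` invisibly.
#' @export
write_model_json <- function(model, path, seed = NULL, fitness = NULL) {
  jsonlite::write_json(
    list(
      response = model$response,
      descriptors = model$descriptors,
      coefficients = as.list(model$coefficients),
      n = model$n,
      seed = seed,
      fitness = fitness
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
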