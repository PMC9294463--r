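#' Training-fit statistics
#'
#' The fitting block of the internal-validation suite:
#' \eqn{R^2 = 1 - RSS/TSS}, the adjusted \eqn{R^2}, the regression standard
#' deviation \eqn{s = \sqrt{RSS/(n-p-1)}}, the Fisher ratio
#' \eqn{F = (ESS/p)/(RSS/(n-p-1))}, and the training RMSE / MAE. RMSE and
#' MAE use denominator \eqn{n} while `s` uses the residual degrees of
#' freedom; the two conventions are deliberately kept side by side because
#' QSAR reporting uses both.
#'
#' @param y observed response.
#' @param y_hat fitted values.
#' @param p number of descriptors in the model (excluding the intercept).
#' @return A named list: `R2`, `R2_adj`, `s`, `F`, `RMSE_tr`, `MAE_tr`.
#' @export
fit_statistics <- function(y, y_hat, p) {
  n <- length(y)
  stopifnot(length(y_hat) == n, n >= p + 2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("constant response: R2 undefined")
  rss <- sum((y - y_hat)^2)
  ess <- tss - rss
  r2 <- 1 - rss / tss
  list(
    R2 = r2,
    R2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    s = sqrt(rss / (n - p - 1)),
    F = (ess / p) / (rss / (n - p - 1)),
    RMSE_tr = sqrt(rss / n),
    MAE_tr = mean(abs(y - y_hat))
  )
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between observations and predictions penalising both location
#' and scale shifts:
#' \deqn{CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with population (1/n) variance terms, as in Lin's original definition.
#'
#' @param y,y_hat numeric vectors of equal length (>= 2).
#' @return A number in \[-1, 1\].
#' @export
#' @examples
#' ccc(c(0, 1, 2), c(1, 2, 3))   # 4/7
ccc <- function(y, y_hat) {
  n <- length(y)
  stopifnot(length(y_hat) == n, n >= 2)
  sx <- mean((y - mean(y))^2)
  sy <- mean((y_hat - mean(y_hat))^2)
  if (sx == 0 && sy == 0) stop("both inputs constant: CCC undefined")
  sxy <- mean((y - mean(y)) * (y_hat - mean(y_hat)))
  2 * sxy / (sx + sy + (mean(y) - mean(y_hat))^2)
}

#' Leave-one-out cross-validation (Q2, PRESS)
#'
#' Each observation is predicted by the model refit without it. For OLS the
#' deleted residual has the closed form \eqn{e_i/(1-h_{ii})} with
#' \eqn{h_{ii}} the leverage, which this implementation uses; it is
#' algebraically identical to n explicit refits.
#'
#' @param X descriptor matrix / data frame (no intercept column).
#' @param y numeric response.
#' @return A list: `q2` (\eqn{1 - PRESS/TSS}), `press`, `rmse_cv`, `mae_cv`
#'   and the LOO predictions `pred`.
#' @export
q2_loo <- function(X, y) {
  X <- strip_id(X)
  n <- length(y)
  if (n < ncol(X) + 3L) stop("need n >= p + 3 for leave-one-out validation")
  Xa <- cbind(1, X)
  qx <- qr(Xa)
  if (qx$rank < ncol(Xa)) stop("rank-deficient design")
  h <- rowSums(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]^2)
  if (any(h >= 1 - 1e-10)) {
    stop("leave-one-out refit is rank deficient when omitting row ",
         which(h >= 1 - 1e-10)[1])
  }
  res <- qr.resid(qx, y)
  e_loo <- res / (1 - h)
  press <- sum(e_loo^2)
  tss <- sum((y - mean(y))^2)
  list(q2 = 1 - press / tss, press = press,
       rmse_cv = sqrt(press / n), mae_cv = mean(abs(e_loo)),
       pred = y - e_loo)
}

#' Leave-more-out cross-validation
#'
#' Repeatedly leaves out a random fraction of the observations, refits, and
#' predicts the left-out block. Squared prediction errors and null
#' (training-mean) errors are pooled over all iterations,
#' \eqn{Q^2_{LMO} = 1 - \sum e^2_{out} / \sum (y_{out} - \bar y_{tr})^2},
#' so that with singleton groups and many iterations the statistic
#' approaches \eqn{Q^2_{LOO}}. Reproducible for a fixed seed.
#'
#' @inheritParams q2_loo
#' @param leave_fraction fraction of rows left out per iteration (0, 0.5\].
#' @param iterations number of random splits.
#' @param seed integer seed.
#' @return Pooled \eqn{Q^2} over the iterations.
#' @export
q2_lmo <- function(X, y, leave_fraction = 0.3, iterations = 1000L,
                   seed = 1L) {
  X <- strip_id(X)
  stopifnot(leave_fraction > 0, leave_fraction <= 0.5)
  n <- length(y); p <- ncol(X)
  g <- max(1L, floor(n * leave_fraction))
  if (n - g < p + 2L) {
    stop("leave-more-out group of ", g, " leaves fewer than p + 2 ",
         "training rows")
  }
  set.seed(as.integer(seed))
  press <- 0; null_ss <- 0
  for (it in seq_len(iterations)) {
    out <- sample.int(n, g)
    Xa <- cbind(1, X[-out, , drop = FALSE])
    qx <- qr(Xa)
    if (qx$rank < ncol(Xa)) next
    b <- qr.coef(qx, y[-out])
    pred <- drop(cbind(1, X[out, , drop = FALSE]) %*% b)
    press <- press + sum((y[out] - pred)^2)
    null_ss <- null_ss + sum((y[out] - mean(y[-out]))^2)
  }
  1 - press / null_ss
}

#' Multivariate K correlation index (Kxx, delta K)
#'
#' Todeschini's index of global correlation: with eigenvalues
#' \eqn{\lambda_j} of the correlation matrix of \eqn{m} autoscaled
#' variables,
#' \deqn{K = \frac{\sum_j |\lambda_j/\sum\lambda - 1/m|}{2(m-1)/m},}
#' 0 for mutually orthogonal columns and 1 for perfect collinearity.
#' `Kxx` is computed on the descriptors alone and `Kxy` with the response
#' appended; their difference `delta_k` should be positive for a model whose
#' descriptors correlate more with the response than among themselves.
#'
#' @inheritParams q2_loo
#' @param y optional response; when supplied `Kxy` and `delta_k` are
#'   reported as well.
#' @return A list with `Kxx` and, when `y` is given, `Kxy` and `delta_k`.
#' @export
k_correlation <- function(X, y = NULL) {
  X <- strip_id(X)
  if (ncol(X) < 2L) stop("K index needs at least two descriptor columns")
  if (any(apply(X, 2, sd) == 0)) stop("constant descriptor column")
  k_of <- function(M) {
    lam <- eigen(cor(M), symmetric = TRUE, only.values = TRUE)$values
    m <- ncol(M)
    sum(abs(lam / sum(lam) - 1 / m)) / (2 * (m - 1) / m)
  }
  out <- list(Kxx = k_of(X))
  if (!is.null(y)) {
    out$Kxy <- k_of(cbind(X, y))
    out$delta_k <- out$Kxy - out$Kxx
  }
  out
}

#' Y-scrambling (response randomisation)
#'
#' Refits the model on the fixed design after randomly permuting the
#' response, `n_perm` times, to estimate the chance-correlation level. For a
#' full-rank fixed design the expected scrambled \eqn{R^2} is approximately
#' \eqn{p/(n-1)}; a real model should sit far above its scrambled mean.
#'
#' @inheritParams q2_loo
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return An object of class `y_scramble`: a list with the means
#'   `r2_mean`, `q2_mean`, `rmse_mean` and the per-permutation values.
#' @export
y_scramble <- function(X, y, n_perm = 2000L, seed = 1L) {
  X <- strip_id(X)
  if (n_perm < 100L) stop("use at least 100 permutations")
  n <- length(y)
  Xa <- cbind(1, X)
  qx <- qr(Xa)
  if (qx$rank < ncol(Xa)) stop("rank-deficient design")
  h <- rowSums(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]^2)
  set.seed(as.integer(seed))
  perms <- vapply(seq_len(n_perm), function(k) sample.int(n), integer(n))
  Y <- matrix(y[perms], nrow = n)
  R <- qr.resid(qx, Y)
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  rss <- colSums(R^2)
  press <- colSums((R / (1 - h))^2)
  structure(
    list(
      r2_mean = mean(1 - rss / tss),
      q2_mean = mean(1 - press / tss),
      rmse_mean = mean(sqrt(rss / n)),
      r2 = 1 - rss / tss,
      q2 = 1 - press / tss,
      n_perm = n_perm, n = n, p = ncol(X), seed = seed
    ),
    class = "y_scramble"
  )
}

#' @export
print.y_scramble <- function(x, ...) {
  cat(sprintf(
    "<y_scramble: %d permutations, mean R2 = %.3f, mean Q2 = %.3f>\n",
    x$n_perm, x$r2_mean, x$q2_mean))
  invisible(x)
}

#' Roy's r2m metric
#'
#' \eqn{r^2_m = r^2 (1 - \sqrt{r^2 - r_0^2})}, where \eqn{r^2} is the
#' squared correlation between observed and predicted values with intercept
#' and \eqn{r_0^2} the through-origin determination coefficient. Values
#' above 0.6 are conventionally read as acceptable external agreement. The
#' plain absolute difference \eqn{|r^2 - r_0^2|} is available as
#' `variant = "diff"`.
#'
#' @param y observed values.
#' @param y_hat predicted values (typically LOO predictions).
#' @param variant `"roy"` (default) or `"diff"`.
#' @return A single number.
#' @export
rm2 <- function(y, y_hat, variant = c("roy", "diff")) {
  variant <- match.arg(variant)
  if (sd(y) == 0) stop("constant response")
  r2 <- cor(y, y_hat)^2
  k <- sum(y * y_hat) / sum(y_hat^2)
  r02 <- 1 - sum((y - k * y_hat)^2) / sum((y - mean(y))^2)
  d <- r2 - r02
  if (variant == "diff") return(abs(d))
  if (d < 0) {
    warning("r0^2 exceeded r^2 numerically; difference clamped at 0")
    d <- 0
  }
  r2 * (1 - sqrt(d))
}

#' Descriptor / response correlation matrix
#'
#' Pairwise Pearson correlations among the response (first row/column) and
#' the model descriptors - the collinearity table inspected before accepting
#' a model.
#'
#' @param data data frame holding the columns.
#' @param response response column name, placed first.
#' @param descriptors descriptor column names.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(data, response, descriptors) {
  d <- tibble::as_tibble(data)[c(response, descriptors)]
  if (nrow(d) < 2L) stop("need at least two rows")
  if (any(vapply(d, sd, numeric(1)) == 0)) stop("constant column")
  cor(as.matrix(d))
}

#' Full internal-validation report for a fitted model
#'
#' Assembles the complete statistic set used to judge the lipoxygenase
#' models: the training-fit block, the K correlation indices, leave-one-out
#' and leave-more-out cross-validation, Y-scrambling averages and Roy's
#' \eqn{r^2_m} (computed on the LOO predictions by default).
#'
#' @param model an `mlr_model`.
#' @param lmo_fraction,lmo_iterations leave-more-out settings.
#' @param n_perm Y-scrambling permutation count.
#' @param seed seed for the two randomised blocks.
#' @param rm2_on compute \eqn{r^2_m} on `"loo"` predictions (default) or on
#'   the `"fitted"` values.
#' @return A tibble of class `validation_report` with columns `statistic`
#'   and `value`.
#' @export
validate_model <- function(model, lmo_fraction = 0.3,
                           lmo_iterations = 1000L, n_perm = 2000L,
                           seed = 1L, rm2_on = c("loo", "fitted")) {
  stopifnot(inherits(model, "mlr_model"))
  rm2_on <- match.arg(rm2_on)
  st <- fit_statistics(model$y, model$fitted, model$p)
  loo <- q2_loo(model$X, model$y)
  kk <- k_correlation(model$X, model$y)
  lmo <- q2_lmo(model$X, model$y, leave_fraction = lmo_fraction,
                iterations = lmo_iterations, seed = seed)
  ys <- y_scramble(model$X, model$y, n_perm = n_perm, seed = seed)
  vals <- c(
    n = model$n,
    R2 = st$R2, R2_adj = st$R2_adj, s = st$s, F = st$F,
    Kxx = kk$Kxx, dK = kk$delta_k,
    RMSE_tr = st$RMSE_tr, MAE_tr = st$MAE_tr,
    CCC_tr = ccc(model$y, model$fitted),
    Q2_LOO = loo$q2, Q2_LMO = lmo,
    RMSE_cv = loo$rmse_cv, MAE_cv = loo$mae_cv, PRESS_cv = loo$press,
    CCC_cv = ccc(model$y, loo$pred),
    R2_Yscr = ys$r2_mean, Q2_Yscr = ys$q2_mean, RMSE_Yscr = ys$rmse_mean,
    r2m = rm2(model$y, if (rm2_on == "loo") loo$pred else model$fitted)
  )
  out <- tibble::tibble(statistic = names(vals), value = unname(vals))
  class(out) <- c("validation_report", class(out))
  attr(out, "seed") <- seed
  out
}

report_values <- function(report) {
  if (inherits(report, "data.frame") &&
      all(c("statistic", "value") %in% names(report))) {
    setNames(report$value, report$statistic)
  } else if (is.numeric(report) && !is.null(names(report))) {
    report
  } else if (is.list(report)) {
    unlist(report)
  } else {
    stop("cannot interpret the validation report")
  }
}

#' Evaluate the model-acceptance thresholds
#'
#' Applies the acceptance rules used for the lipoxygenase models: fitting
#' (\eqn{R^2 \ge 0.7}; \eqn{R^2 - R^2_{adj} < 0.3}; \eqn{RMSE_{tr} < 0.3};
#' \eqn{CCC_{tr} > 0.85}), internal stability (\eqn{Q^2_{LOO} \ge 0.5};
#' \eqn{Q^2_{LMO} \ge 0.6}; \eqn{RMSE_{tr} < RMSE_{cv}};
#' \eqn{r^2_m \ge 0.6}; \eqn{CCC_{cv} > 0.85}), chance correlation
#' (\eqn{R^2_{Yscr} < 0.2}; \eqn{Q^2_{Yscr} < 0.2}) and descriptor
#' correlation (\eqn{\Delta K} at or above 0.05; the boundary is inclusive
#' so that reports quoted at two decimals evaluate the way published tables
#' are read).
#'
#' @param report a `validation_report`, or a named numeric vector / list
#'   with the same statistic names.
#' @return A tibble with `criterion`, `value`, `pass`; attribute `"verdict"`
#'   is `TRUE` when every criterion passes.
#' @export
check_thresholds <- function(report) {
  v <- report_values(report)
  need <- function(nm) {
    if (!nm %in% names(v) || is.na(v[[nm]])) {
      stop("validation report is missing `", nm, "`")
    }
    v[[nm]]
  }
  rules <- list(
    list("R2 >= 0.7",            need("R2") >= 0.7,              need("R2")),
    list("R2 - R2_adj < 0.3",    need("R2") - need("R2_adj") < 0.3,
         need("R2") - need("R2_adj")),
    list("RMSE_tr < 0.3",        need("RMSE_tr") < 0.3,          need("RMSE_tr")),
    list("CCC_tr > 0.85",        need("CCC_tr") > 0.85,          need("CCC_tr")),
    list("Q2_LOO >= 0.5",        need("Q2_LOO") >= 0.5,          need("Q2_LOO")),
    list("Q2_LMO >= 0.6",        need("Q2_LMO") >= 0.6,          need("Q2_LMO")),
    list("RMSE_tr < RMSE_cv",    need("RMSE_tr") < need("RMSE_cv"),
         need("RMSE_cv") - need("RMSE_tr")),
    list("r2m >= 0.6",           need("r2m") >= 0.6,             need("r2m")),
    list("CCC_cv > 0.85",        need("CCC_cv") > 0.85,          need("CCC_cv")),
    list("R2_Yscr < 0.2",        need("R2_Yscr") < 0.2,          need("R2_Yscr")),
    list("Q2_Yscr < 0.2",        need("Q2_Yscr") < 0.2,          need("Q2_Yscr")),
    list("dK >= 0.05",           need("dK") >= 0.05,             need("dK"))
  )
  out <- tibble::tibble(
    criterion = vapply(rules, `[[`, character(1), 1),
    value = vapply(rules, `[[`, numeric(1), 3),
    pass = vapply(rules, `[[`, logical(1), 2)
  )
  attr(out, "verdict") <- all(out$pass)
  out
}
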