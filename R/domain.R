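#' Leverages of an intercept-augmented design
#'
#' Diagonal of the hat matrix \eqn{H = X(X'X)^{-1}X'} for the design with an
#' intercept column prepended. Leverages sum to the number of adjustable
#' parameters and lie in \[1/n, 1\].
#'
#' @param X descriptor matrix or data frame (no intercept column).
#' @return Numeric vector of leverages.
#' @export
leverage_values <- function(X) {
  X <- strip_id(X)
  Xa <- cbind(1, X)
  qx <- qr(Xa)
  if (qx$rank < ncol(Xa)) stop("rank-deficient design")
  rowSums(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]^2)
}

#' Warning leverage h*
#'
#' The conventional applicability-domain cut-off \eqn{h^* = 3 p'/n}, with
#' `n` training compounds and `p_prime` model-adjustable parameters
#' (descriptors plus intercept).
#'
#' @param n number of training compounds (> 0).
#' @param p_prime number of adjustable parameters (>= 1).
#' @return \eqn{3 p'/n}.
#' @export
#' @examples
#' warning_leverage(19, 4)   # 0.6316
warning_leverage <- function(n, p_prime) {
  if (!(is.numeric(n) && n > 0) || !(is.numeric(p_prime) && p_prime >= 1)) {
    stop("need n > 0 and p_prime >= 1")
  }
  3 * p_prime / n
}

#' Williams-plot applicability-domain analysis
#'
#' Pairs each compound's leverage with its standardized residual: compounds
#' with \eqn{|std. residual| > 2} are response outliers, compounds with
#' \eqn{h_i > h^* = 3p'/n} are outside the structural domain. By default
#' residuals are standardized by the training RMSE; the leverage-adjusted
#' studentized form \eqn{e_i/(s\sqrt{1-h_i})} is available as an option.
#'
#' @param model a fitted `mlr_model`.
#' @param std_residual `"rmse"` (residual / training RMSE) or
#'   `"studentized"`.
#' @param res_threshold flag threshold on the absolute standardized
#'   residual.
#' @return A tibble of class `ad_report`: `id`, `leverage`, `residual`,
#'   `std_residual`, `outlier`, `high_leverage`; attributes `h_star`, `n`,
#'   `p_prime`.
#' @export
williams_domain <- function(model, std_residual = c("rmse", "studentized"),
                            res_threshold = 2) {
  stopifnot(inherits(model, "mlr_model"))
  std_residual <- match.arg(std_residual)
  h <- leverage_values(model$X)
  res <- model$residuals
  n <- model$n
  rmse <- sqrt(sum(res^2) / n)
  s <- sqrt(sum(res^2) / (n - model$p - 1))
  std <- if (rmse < 1e-12) {
    rep(0, n)            # perfect fit: nothing to standardize
  } else {
    switch(std_residual,
      rmse = res / rmse,
      studentized = res / (s * sqrt(1 - h))
    )
  }
  h_star <- warning_leverage(n, model$p + 1L)
  out <- tibble::tibble(
    id = model$ids,
    leverage = h,
    residual = res,
    std_residual = std,
    outlier = abs(std) > res_threshold,
    high_leverage = h > h_star
  )
  class(out) <- c("ad_report", class(out))
  attr(out, "h_star") <- h_star
  attr(out, "n") <- n
  attr(out, "p_prime") <- model$p + 1L
  attr(out, "res_threshold") <- res_threshold
  out
}
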