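# Printed validation statistics of the two published lipoxygenase models,
# used as check_thresholds fixtures.
model1_report <- c(
  n = 19, R2 = 0.82, R2_adj = 0.79, s = 0.13, F = 23.45, Kxx = 0.27,
  dK = 0.05, RMSE_tr = 0.11, MAE_tr = 0.10, CCC_tr = 0.90, Q2_LOO = 0.70,
  Q2_LMO = 0.66, RMSE_cv = 0.15, MAE_cv = 0.13, PRESS_cv = 0.43,
  CCC_cv = 0.83, R2_Yscr = 0.17, Q2_Yscr = -0.38, RMSE_Yscr = 0.25,
  r2m = 0.67
)
model2_report <- c(
  n = 18, R2 = 0.88, R2_adj = 0.85, s = 0.11, F = 33.69, Kxx = 0.29,
  dK = 0.10, RMSE_tr = 0.10, MAE_tr = 0.09, CCC_tr = 0.94, Q2_LOO = 0.77,
  Q2_LMO = 0.75, RMSE_cv = 0.14, MAE_cv = 0.12, PRESS_cv = 0.33,
  CCC_cv = 0.88, R2_Yscr = 0.17, Q2_Yscr = -0.42, RMSE_Yscr = 0.25,
  r2m = 0.70
)

test_that("training statistics match direct formula evaluation", {
  y <- c(1.2, 0.9, 1.7, 1.4, 0.8)
  y_hat <- c(1.1, 1.0, 1.6, 1.5, 0.9)
  st <- fit_statistics(y, y_hat, p = 2)
  tss <- sum((y - mean(y))^2); rss <- sum((y - y_hat)^2)
  expect_equal(st$R2, 1 - rss / tss)
  expect_equal(st$R2_adj, 1 - (1 - st$R2) * 4 / 2)
  expect_equal(st$s, sqrt(rss / 2))
  expect_equal(st$F, ((tss - rss) / 2) / (rss / 2))
  expect_equal(st$RMSE_tr, sqrt(rss / 5))
  expect_equal(st$MAE_tr, mean(abs(y - y_hat)))
  # perfect fit
  stp <- fit_statistics(y, y, p = 2)
  expect_equal(stp$R2, 1); expect_equal(stp$RMSE_tr, 0)
  expect_error(fit_statistics(rep(1, 5), rep(1, 5), 1), "constant")
})

test_that("concordance correlation matches its definition", {
  expect_equal(ccc(c(0.3, 1.8, 0.5), c(0.3, 1.8, 0.5)), 1)
  expect_equal(ccc(c(0, 1, 2), c(1, 2, 3)), 4 / 7)
  expect_error(ccc(rep(1, 4), rep(2, 4)), "constant")
  # |CCC| never exceeds |Pearson r|
  set.seed(51)
  for (k in 1:20) {
    a <- rnorm(10); b <- rnorm(10) + 0.5 * a
    expect_lte(abs(ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
})

test_that("the leave-one-out shortcut equals explicit refits", {
  set.seed(52)
  X <- matrix(rnorm(20), 10, 2)
  y <- 1 + X[, 1] - 0.5 * X[, 2] + rnorm(10, sd = 0.3)
  loo <- q2_loo(X, y)
  expect_equal(loo$press, brute_press(X, y), tolerance = 1e-9)
  expect_equal(loo$q2, brute_q2(X, y), tolerance = 1e-9)
  expect_error(q2_loo(matrix(rnorm(8), 4, 2), rnorm(4)), "p \\+ 3")
})

test_that("PRESS >= RSS, hence Q2 <= R2, on every fit", {
  set.seed(53)
  for (k in 1:20) {
    n <- sample(10:25, 1); p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n) + X %*% rnorm(p)
    fit <- fit_mlr(tibble::as_tibble(as.data.frame(X)) |>
                     dplyr::mutate(y = drop(y)), "y")
    st <- fit_statistics(fit$y, fit$fitted, fit$p)
    loo <- q2_loo(fit$X, fit$y)
    rss <- sum(fit$residuals^2)
    expect_gte(loo$press, rss - 1e-12)
    expect_lte(loo$q2, st$R2 + 1e-12)
  }
})

test_that("pure-noise responses cross-validate negatively", {
  set.seed(54)
  neg <- 0L
  for (k in 1:50) {
    X <- matrix(rnorm(15 * 3), 15, 3)
    y <- rnorm(15)
    if (q2_loo(X, y)$q2 < 0) neg <- neg + 1L
  }
  expect_gte(neg, 45L)
})

test_that("leave-more-out approaches leave-one-out and is seed-stable", {
  dat <- synth_generate(synth_spec(sigma = 0.1, seed = 55))
  X <- as.matrix(dat$descriptors[dat$truth$subset])
  loo <- q2_loo(X, dat$y)$q2
  lmo <- q2_lmo(X, dat$y, leave_fraction = 0.3, iterations = 500, seed = 1)
  expect_lt(abs(lmo - loo), 0.1)
  # singleton groups pool towards the LOO statistic
  lmo1 <- q2_lmo(X, dat$y, leave_fraction = 0.052, iterations = 3000,
                 seed = 2)
  expect_lt(abs(lmo1 - loo), 0.05)
  expect_identical(q2_lmo(X, dat$y, seed = 9), q2_lmo(X, dat$y, seed = 9))
  expect_error(q2_lmo(X[1:6, ], dat$y[1:6], leave_fraction = 0.5), "p \\+ 2")
})

test_that("the K correlation index hits its closed-form extremes", {
  orth <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_equal(k_correlation(orth)$Kxx, 0)
  dup <- cbind(a = c(1, 2, 3, 5), b = 2 * c(1, 2, 3, 5))
  expect_equal(k_correlation(dup)$Kxx, 1)
  # invariant to column scaling
  set.seed(56)
  X <- matrix(rnorm(40), 10, 4)
  expect_equal(k_correlation(X)$Kxx,
               k_correlation(sweep(X, 2, c(1, 10, 0.1, 5), "*"))$Kxx)
  expect_error(k_correlation(cbind(rep(1, 5), rnorm(5))), "constant")
  # delta_k orientation
  y <- X[, 1] + 0.1 * rnorm(10)
  kk <- k_correlation(X, y)
  expect_equal(kk$delta_k, kk$Kxy - kk$Kxx)
})

test_that("Y-scrambling sits at the chance level p/(n-1) and is seeded", {
  set.seed(57)
  X <- matrix(rnorm(19 * 3), 19, 3)
  y <- rnorm(19, mean = 1.3, sd = 0.3)
  ys <- y_scramble(X, y, n_perm = 2000, seed = 3)
  expect_equal(ys$r2_mean, 3 / 18, tolerance = 0.02)
  expect_lt(ys$q2_mean, 0)
  ys2 <- y_scramble(X, y, n_perm = 2000, seed = 3)
  expect_identical(ys$r2_mean, ys2$r2_mean)
  expect_error(y_scramble(X, y, n_perm = 50), "100")
})

test_that("a strong signal dwarfs its scrambled refits", {
  dat <- synth_generate(synth_spec(sigma = 0.05, beta = c(0.5, 0.4, -0.4),
                                   seed = 58))
  X <- as.matrix(dat$descriptors[dat$truth$subset])
  fit_r2 <- fit_statistics(dat$y,
                           fit_mlr(dat$data, "y", dat$truth$subset)$fitted,
                           3)$R2
  ys <- y_scramble(X, dat$y, n_perm = 500, seed = 4)
  expect_lt(ys$r2_mean, 0.3)
  expect_lt(ys$r2_mean, fit_r2)
})

test_that("Roy's r2m matches hand evaluation and clamps correctly", {
  y <- c(1.0, 1.3, 0.9, 1.8, 1.5)
  y_hat <- c(1.1, 1.2, 1.0, 1.7, 1.4)
  r2 <- cor(y, y_hat)^2
  k <- sum(y * y_hat) / sum(y_hat^2)
  r02 <- 1 - sum((y - k * y_hat)^2) / sum((y - mean(y))^2)
  expect_equal(rm2(y, y_hat), r2 * (1 - sqrt(r2 - r02)))
  expect_equal(rm2(y, y_hat, variant = "diff"), abs(r2 - r02))
  expect_equal(rm2(y, y), 1)
  expect_error(rm2(rep(1, 5), rnorm(5)), "constant")
})

test_that("the correlation matrix is the response-first Pearson table", {
  set.seed(59)
  d <- tibble::tibble(y = rnorm(10), a = rnorm(10))
  d$b <- -d$a
  cm <- correlation_matrix(d, "y", c("a", "b"))
  expect_equal(diag(cm), c(y = 1, a = 1, b = 1))
  expect_equal(cm["a", "b"], -1)
  expect_equal(cm, t(cm))
  expect_error(correlation_matrix(dplyr::mutate(d, cst = 1), "y",
                                  c("a", "cst")), "constant")
})

test_that("acceptance thresholds reproduce the published verdicts", {
  res1 <- check_thresholds(model1_report)
  expect_false(attr(res1, "verdict"))
  failing <- res1$criterion[!res1$pass]
  expect_equal(failing, "CCC_cv > 0.85")    # the one failed parameter

  res2 <- check_thresholds(model2_report)
  expect_true(attr(res2, "verdict"))

  bad <- model2_report; bad["R2"] <- 0.5
  res3 <- check_thresholds(bad)
  expect_true("R2 >= 0.7" %in% res3$criterion[!res3$pass])

  expect_error(check_thresholds(model2_report[-2]), "R2")
})

test_that("validate_model assembles a complete, reproducible report", {
  dat <- synth_generate(synth_spec(seed = 60))
  fit <- fit_mlr(dat$data, "y", dat$truth$subset)
  v1 <- validate_model(fit, lmo_iterations = 100, n_perm = 200, seed = 8)
  v2 <- validate_model(fit, lmo_iterations = 100, n_perm = 200, seed = 8)
  expect_identical(v1$value, v2$value)
  expect_setequal(v1$statistic, names(model1_report))
  vals <- setNames(v1$value, v1$statistic)
  expect_lte(vals["R2_adj"], vals["R2"])
  expect_lte(vals["RMSE_tr"], vals["RMSE_cv"])
  expect_gte(vals["PRESS_cv"], vals["n"] * vals["RMSE_tr"]^2 - 1e-9)
})
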