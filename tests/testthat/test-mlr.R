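test_that("a noiseless linear response is recovered exactly", {
  dat <- synth_generate(synth_spec(sigma = 0, seed = 31))
  fit <- fit_mlr(dat$data, "y", dat$truth$subset)
  expect_equal(unname(fit$coefficients),
               c(dat$truth$intercept, dat$truth$beta), tolerance = 1e-9)
  expect_equal(fit_statistics(fit$y, fit$fitted, fit$p)$R2, 1,
               tolerance = 1e-12)
})

test_that("the fit equals the explicit normal-equations solution", {
  set.seed(32)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("u", "v")))
  y <- rnorm(6)
  fit <- fit_mlr(tibble::tibble(u = X[, 1], v = X[, 2], y = y), "y",
                 c("u", "v"))
  Xa <- cbind(1, X)
  b_oracle <- drop(solve(t(Xa) %*% Xa, t(Xa) %*% y))
  expect_equal(unname(fit$coefficients), unname(b_oracle), tolerance = 1e-9)
  expect_lt(abs(mean(fit$residuals)), 1e-12)      # intercept model
})

test_that("prediction honours names, defaults to fitted values", {
  set.seed(33)
  d <- tibble::tibble(a = rnorm(8), b = rnorm(8))
  d$y <- 1 + d$a - d$b + 0.01 * rnorm(8)
  fit <- fit_mlr(d, "y", c("a", "b"))
  expect_equal(predict(fit), fit$fitted)
  expect_equal(predict(fit, d[c("b", "a")]), fit$fitted)  # order-tolerant
  expect_error(predict(fit, d["a"]), "missing descriptor")
  # zero-coefficient model predicts the constant intercept
  d0 <- tibble::tibble(a = rnorm(8), y = rep(2, 8))
  f0 <- fit_mlr(d0, "y", "a")
  expect_equal(unname(predict(f0, tibble::tibble(a = c(-5, 10)))),
               rep(2, 2), tolerance = 1e-9)
})

test_that("rank deficiency is reported with the collinear column names", {
  set.seed(34)
  d <- tibble::tibble(a = rnorm(10))
  d$b <- 2 * d$a
  d$y <- rnorm(10)
  expect_error(fit_mlr(d, "y", c("a", "b")), "b")
  expect_error(fit_mlr(d[1:2, ], "y", "a"), "n > p")
})

test_that("coefficients are invariant to row permutation", {
  dat <- synth_generate(synth_spec(seed = 35))
  fit <- fit_mlr(dat$data, "y", dat$truth$subset)
  perm <- sample(nrow(dat$data))
  fit_p <- fit_mlr(dat$data[perm, ], "y", dat$truth$subset)
  expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-9)
})

test_that("tidy and glance expose the broom-style summaries", {
  dat <- synth_generate(synth_spec(seed = 36))
  fit <- fit_mlr(dat$data, "y", dat$truth$subset)
  td <- tidy(fit)
  expect_equal(td$estimate, unname(fit$coefficients))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  st <- fit_statistics(fit$y, fit$fitted, fit$p)
  expect_equal(gl$r.squared, st$R2)
  expect_equal(gl$q2.loo, q2_loo(fit$X, fit$y)$q2)
  # t statistics agree with R's own lm summary
  lmfit <- lm(y ~ ., data = dat$data[c(dat$truth$subset, "y")])
  expect_equal(td$statistic, unname(summary(lmfit)$coefficients[, "t value"]),
               tolerance = 1e-9)
})

test_that("models serialize to JSON and back", {
  dat <- synth_generate(synth_spec(seed = 37))
  fit <- fit_mlr(dat$data, "y", dat$truth$subset)
  tf <- tempfile(fileext = ".json")
  write_model_json(fit, tf, seed = 37, fitness = 0.9)
  parsed <- jsonlite::read_json(tf)
  expect_equal(unlist(parsed$coefficients), fit$coefficients)
  expect_equal(parsed$seed, 37)
})
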