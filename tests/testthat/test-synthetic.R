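test_that("generation is reproducible and honours the spec", {
  sp <- synth_spec(seed = 71)
  a <- synth_generate(sp); b <- synth_generate(sp)
  expect_identical(a$descriptors, b$descriptors)
  expect_identical(a$y, b$y)
  expect_equal(dim(a$descriptors), c(19L, 13L))
  expect_error(synth_spec(rho = 1), "rho")
  expect_error(synth_spec(rho = -0.1), "rho")
  expect_error(synth_spec(sigma = -1), "sigma")
  expect_error(synth_spec(subset = 1:4, beta = 1:3), "length")
})

test_that("a noiseless draw is fit exactly", {
  dat <- synth_generate(synth_spec(sigma = 0, seed = 72))
  fit <- fit_mlr(dat$data, "y", dat$truth$subset)
  expect_equal(unname(fit$coefficients),
               c(dat$truth$intercept, dat$truth$beta), tolerance = 1e-9)
})

test_that("rho = 0 pools are empirically uncorrelated at large n", {
  dat <- synth_generate(synth_spec(n = 500L, p_pool = 6L, rho = 0,
                                   subset = 1:3, seed = 73))
  cm <- cor(as.matrix(dat$descriptors[-1]))
  expect_lt(max(abs(cm[upper.tri(cm)])), 3 / sqrt(500))
})

test_that("equicorrelated pools show the requested correlation", {
  dat <- synth_generate(synth_spec(n = 2000L, p_pool = 5L, rho = 0.6,
                                   subset = 1:3, seed = 74))
  cm <- cor(as.matrix(dat$descriptors[-1]))
  expect_equal(mean(cm[upper.tri(cm)]), 0.6, tolerance = 0.05)
})

test_that("predictivity of the true model decays monotonically with noise", {
  sigmas <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  mean_q2 <- vapply(sigmas, function(s) {
    mean(vapply(1:10, function(r) {
      dat <- synth_generate(synth_spec(sigma = s, beta = c(0.5, 0.4, -0.4),
                                       seed = 7000 + r))
      q2_loo(as.matrix(dat$descriptors[dat$truth$subset]), dat$y)$q2
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cor(sigmas, mean_q2, method = "spearman"), -1)
})

test_that("a small recovery experiment finds the planted model", {
  sp <- synth_spec(p_pool = 8L, beta = c(0.5, 0.5, -0.5), sigma = 0.05,
                   seed = 75)
  rec <- recovery_experiment(sp, reps = 10,
                             control = ga_control(pop_size = 50,
                                                  generations = 80,
                                                  stall = 25))
  expect_gte(rec$selection_rate, 0.9)
  expect_true(all(abs(rec$coef_table$bias) <=
                    3 * rec$coef_table$mc_se + 0.05))
})

test_that("a pure-noise scenario warns and reports its chance-level fit", {
  sp <- synth_spec(p_pool = 6L, subset = 1:2, beta = c(0, 0), sigma = 0.3,
                   seed = 76)
  expect_warning(
    rec <- recovery_experiment(sp, reps = 5,
                               control = ga_control(pop_size = 40,
                                                    generations = 40,
                                                    stall = 15)),
    "no signal"
  )
  expect_true(is.finite(rec$mean_q2_best))
})
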