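ga_fast <- function() ga_control(pop_size = 60L, generations = 120L,
                                 stall = 30L)

test_that("a pool no larger than the cap degenerates to the full model", {
  dat <- synth_generate(synth_spec(p_pool = 3L, seed = 41))
  expect_warning(
    r <- ga_select(dat$descriptors, dat$y, max_size = 3),
    "full model"
  )
  expect_setequal(r$subset[[1]], c("D01", "D02", "D03"))
})

test_that("the genetic search finds the exhaustive optimum on a planted pool", {
  for (seed in c(42, 43)) {
    dat <- synth_generate(synth_spec(
      p_pool = 12L, beta = c(0.5, 0.5, -0.5), sigma = 0.1, seed = seed))
    ga <- ga_select(dat$descriptors, dat$y, max_size = 3,
                    control = ga_fast(), seed = seed)
    ex <- exhaustive_select(dat$descriptors, dat$y, max_size = 3)
    expect_setequal(ga$subset[[1]], ex$subset[[1]])
    expect_equal(ga$fitness[1], ex$fitness[1], tolerance = 1e-12)
  }
})

test_that("the genetic search is reproducible per seed", {
  dat <- synth_generate(synth_spec(p_pool = 10L, seed = 44))
  a <- ga_select(dat$descriptors, dat$y, control = ga_fast(), seed = 5)
  b <- ga_select(dat$descriptors, dat$y, control = ga_fast(), seed = 5)
  expect_identical(a$subset, b$subset)
  expect_identical(a$fitness, b$fitness)
})

test_that("the best subset beats random subsets of the same size", {
  dat <- synth_generate(synth_spec(p_pool = 12L, seed = 45))
  ga <- ga_select(dat$descriptors, dat$y, control = ga_fast(), seed = 45)
  X <- as.matrix(dat$descriptors[-1])
  set.seed(46)
  for (k in 1:100) {
    idx <- sort(sample(ncol(X), 3))
    q2 <- tryCatch(q2_loo(X[, idx], dat$y)$q2, error = function(e) -Inf)
    expect_lte(q2, ga$fitness[1] + 1e-12)
  }
})

test_that("exhaustive enumeration covers exactly the subset lattice", {
  dat <- synth_generate(synth_spec(p_pool = 3L, seed = 47))
  ex <- exhaustive_select(dat$descriptors, dat$y, max_size = 3)
  expect_equal(nrow(ex), 7L)    # C(3,1)+C(3,2)+C(3,3)
  expect_error(exhaustive_select(dat$descriptors, dat$y, max_size = 3,
                                 cap = 5), "cap")
})

test_that("subset fitness equals an independent leave-one-out refit oracle", {
  dat <- synth_generate(synth_spec(p_pool = 6L, seed = 48))
  ex <- exhaustive_select(dat$descriptors, dat$y, max_size = 2)
  X <- as.matrix(dat$descriptors[-1])
  for (row in c(1L, 5L, nrow(ex))) {
    idx <- match(ex$subset[[row]], colnames(X))
    expect_equal(ex$fitness[row], brute_q2(X[, idx, drop = FALSE], dat$y),
                 tolerance = 1e-9)
  }
})
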