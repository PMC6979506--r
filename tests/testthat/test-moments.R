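single_stage_model <- function(p, phi, model = "bernoulli") {
  lro_model(matrix(p), fertility_schedule(phi, model = model))
}

test_that("single-stage LRO moments match the lifetime-enumeration oracle", {
  cases <- list(c(0.7, 0.4), c(0.3, 0.9), c(0.95, 0.1))
  for (cs in cases) {
    p <- cs[1]; phi <- cs[2]
    m <- single_stage_model(p, phi)
    rw <- reward_moments(m$fertility, tau = 1)
    mom <- lro_moment_vectors(build_markov_chain(m), rw)
    orc <- single_stage_oracle(p, phi, "bernoulli")
    expect_equal(mom$rho[[1]], orc$m1, tolerance = 1e-12)
    expect_equal(mom$rho[[2]], orc$m2, tolerance = 1e-12)
    expect_equal(mom$rho[[3]], orc$m3, tolerance = 1e-12)
    # closed forms: mean phi/(1-p), variance phi(1-phi)/(1-p) + phi^2 p/(1-p)^2
    expect_equal(mom$rho[[1]], phi / (1 - p), tolerance = 1e-10)
    expect_equal(mom$rho[[2]] - mom$rho[[1]]^2,
                 phi * (1 - phi) / (1 - p) + phi^2 * p / (1 - p)^2,
                 tolerance = 1e-10)
  }
})

test_that("zero rewards give zero moments of every order", {
  m <- generate_synthetic_model(3, seed = 5)
  rw <- reward_moments(fertility_schedule(rep(0, 3), "poisson"), tau = 3)
  mom <- lro_moment_vectors(build_markov_chain(m), rw)
  for (k in 1:3) expect_equal(mom$rho[[k]], rep(0, 3))
})

test_that("mean LRO equals the net reproductive rate f' N e1", {
  for (seed in 1:10) {
    m <- generate_synthetic_model(sample(2:5, 1), seed = seed)
    rw <- reward_moments(m$fertility, tau = m$tau, order = 2)
    mom <- lro_moment_vectors(build_markov_chain(m), rw)
    N <- fundamental_matrix(m)
    expect_equal(mom$rho[[1]][1], sum(m$fertility$f1 * N[, 1]),
                 tolerance = 1e-10)
  }
})

test_that("a zero-fertility pass-through stage leaves upstream mean LRO unchanged", {
  m <- generate_synthetic_model(3, seed = 21)
  rw <- reward_moments(m$fertility, tau = 3, order = 1)
  rho1 <- lro_moment_vectors(build_markov_chain(m), rw, order = 1)$rho[[1]]
  # append a stage with zero fertility whose only transition is certain
  # passage into stage 1 (no one transitions into it from the original stages)
  U2 <- rbind(cbind(m$U, c(1, 0, 0)), 0)
  f2 <- fertility_schedule(c(m$fertility$f1, 0), model = m$fertility$model)
  m2 <- lro_model(U2, f2)
  rw2 <- reward_moments(f2, tau = 4, order = 1)
  rho1b <- lro_moment_vectors(build_markov_chain(m2), rw2, order = 1)$rho[[1]]
  expect_equal(rho1b[1:3], rho1, tolerance = 1e-12)
  expect_equal(rho1b[4], rho1[1], tolerance = 1e-12)
})

test_that("variance is nonnegative and never increased by removing fertility noise", {
  for (seed in 1:8) {
    m <- generate_synthetic_model(4, seed = seed,
                                  fertility_model = "bernoulli")
    rw <- reward_moments(m$fertility, tau = 4, order = 2)
    mom <- lro_moment_vectors(build_markov_chain(m), rw)
    expect_true(all(mom$rho[[2]] - mom$rho[[1]]^2 >= -1e-10))
    fixed <- fertility_schedule(m$fertility$f1, model = "fixed")
    momf <- lro_moment_vectors(build_markov_chain(m),
                               reward_moments(fixed, tau = 4, order = 2))
    expect_equal(momf$rho[[1]], mom$rho[[1]], tolerance = 1e-12)
    expect_true(all(momf$rho[[2]] <= mom$rho[[2]] + 1e-12))
  }
})

test_that("statistics obey their defining identities and flag undefined CVs", {
  tsuga <- tsuga_model()
  rw <- reward_moments(tsuga$fertility, tau = 6, order = 2)
  st <- lro_statistics(lro_moment_vectors(build_markov_chain(tsuga), rw))
  expect_equal(st$crow_i, st$cv^2)
  expect_equal(st$sd^2, st$variance)

  # zero fertility: mean 0 with CV and Crow's index undefined markers
  m0 <- lro_model(matrix(0.5), fertility_schedule(0))
  st0 <- lro_statistics(
    lro_moment_vectors(build_markov_chain(m0),
                       reward_moments(m0$fertility, tau = 1, order = 2)))
  expect_equal(st0$variance, 0)
  expect_true(is.nan(st0$cv))
  expect_true(is.nan(st0$crow_i))
})

test_that("skewness matches known one-step reward distributions", {
  # deterministic 1-step life: LRO is exactly one per-step reward draw
  one_step <- function(fert) {
    m <- lro_model(matrix(0), fert)
    lro_moment_vectors(build_markov_chain(m),
                       reward_moments(fert, tau = 1, order = 3))
  }
  for (lam in c(0.5, 2, 7)) {
    mom <- one_step(fertility_schedule(lam, "poisson"))
    expect_equal(lro_skewness(mom), 1 / sqrt(lam), tolerance = 1e-12)
  }
  # symmetric two-point reward {0, 2} with equal probability
  mom <- one_step(fertility_schedule(1, "empirical", f2 = 2, f3 = 4))
  expect_equal(lro_skewness(mom), 0)
  # degenerate reward: sd = 0, skewness undefined
  momf <- one_step(fertility_schedule(1.5, "fixed"))
  expect_true(is.nan(lro_skewness(momf)))
  # Tsuga LRO is strongly right-skewed
  tsuga <- tsuga_model()
  rw <- reward_moments(tsuga$fertility, tau = 6, order = 3)
  expect_gt(lro_skewness(lro_moment_vectors(build_markov_chain(tsuga), rw))[1], 0)
})

test_that("the variance partition is additive, nonnegative, and exact for single stages", {
  m <- single_stage_model(0.8, 0.35)
  part <- partition_variance(m)
  orc <- single_stage_oracle(0.8, 0.35, "bernoulli")
  expect_equal(part$v_between, orc$v_between, tolerance = 1e-10)
  expect_equal(part$v_within, orc$v_within, tolerance = 1e-10)
  expect_equal(part$v_total, orc$variance, tolerance = 1e-10)

  for (seed in 1:5) {
    ms <- generate_synthetic_model(4, seed = seed)
    p <- partition_variance(ms)
    expect_equal(p$v_within + p$v_between, p$v_total,
                 tolerance = 1e-10)
    expect_true(all(p$v_within >= 0) && all(p$v_between >= 0))
    expect_equal(p$pct_between + p$pct_within, rep(100, 4))
  }

  # a fixed-reward "total" has no within-pathway component at all
  mf <- generate_synthetic_model(3, seed = 9, fertility_model = "fixed")
  pf <- partition_variance(mf)
  expect_equal(pf$v_within, rep(0, 3))
})

test_that("deterministic one-step life with fixed rewards has zero variance and CV", {
  m <- lro_model(matrix(0), fertility_schedule(2, "fixed"))
  st <- lro_statistics(
    lro_moment_vectors(build_markov_chain(m),
                       reward_moments(m$fertility, tau = 1, order = 2)))
  expect_equal(st$variance, 0)
  expect_equal(st$cv, 0)
})
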